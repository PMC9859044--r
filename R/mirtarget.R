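# Canonical miRNA seed matching (TargetScan-style site taxonomy) and the
# multi-source intersection logic that restricts predictions to DE genes.

#' Canonical seed sites of one miRNA on one target
#'
#' Scans the target (DNA, sense strand) for reverse-complement matches of
#' miRNA positions 2-7 (the 6mer core) and classifies each match at its
#' maximal type: 8mer (core + position-8 pair + A opposite position 1),
#' 7mer-m8 (core + position-8 pair), 7mer-A1 (core + A), else 6mer.
#' Windows containing N are skipped. The reported position is the 1-based
#' start of the full site string on the target.
#'
#' @param mirna mature miRNA sequence (DNA alphabet, length >= 8).
#' @param target target sequence (DNA).
#' @param mirna_id,target_id ids carried into the result.
#' @param target_kind "utr3" or "lncrna".
#' @return data.frame with `mirna_id`, `target_id`, `target_kind`,
#'   `site_type`, `position`.
#' @export
seed_sites <- function(mirna, target, mirna_id = "mirna",
                       target_id = "target",
                       target_kind = c("utr3", "lncrna")) {
  target_kind <- match.arg(target_kind)
  if (nchar(mirna) < 8L) stop("mature miRNA must be at least 8 nt")
  core <- revcomp(substr(mirna, 2L, 7L))
  m8c <- chartr("ACGT", "TGCA", substr(mirna, 8L, 8L))
  # lookahead so overlapping core occurrences are all found
  hits <- gregexpr(paste0("(?=", core, ")"), target, perl = TRUE)[[1L]]
  empty <- data.frame(mirna_id = character(), target_id = character(),
                      target_kind = character(), site_type = character(),
                      position = integer(), stringsAsFactors = FALSE)
  if (hits[1L] == -1L) return(empty)
  tlen <- nchar(target)
  rows <- lapply(as.integer(hits), function(p) {
    before <- if (p > 1L) substr(target, p - 1L, p - 1L) else ""
    after <- if (p + 6L <= tlen) substr(target, p + 6L, p + 6L) else ""
    m8 <- identical(before, m8c)
    a1 <- identical(after, "A")
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
            else if (a1) "7mer-A1" else "6mer"
    start <- if (m8) p - 1L else p
    end <- if (a1) p + 6L else p + 5L
    if (grepl("N", substr(target, start, end), fixed = TRUE)) return(NULL)
    data.frame(mirna_id = mirna_id, target_id = target_id,
               target_kind = target_kind, site_type = type,
               position = start, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Seed sites for all miRNA x target combinations
#' @param mirnas named mature miRNA sequences.
#' @param targets named target sequences.
#' @param target_kind "utr3" or "lncrna".
#' @return row-bound [seed_sites()] results.
#' @export
scan_seed_sites <- function(mirnas, targets,
                            target_kind = c("utr3", "lncrna")) {
  target_kind <- match.arg(target_kind)
  out <- list()
  for (m in names(mirnas)) {
    for (tg in names(targets)) {
      out[[length(out) + 1L]] <-
        seed_sites(mirnas[[m]], targets[[tg]], m, tg, target_kind)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.site_rank <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L, "6mer" = 1L)

#' Collapse seed sites to (miRNA, target) pairs with the best site
#' @param sites a [scan_seed_sites()] result.
#' @return data.frame `mirna_id`, `target_id`, `best_site_type`,
#'   `best_position`, `n_sites`.
#' @export
sites_to_pairs <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L) {
    return(data.frame(mirna_id = character(), target_id = character(),
                      best_site_type = character(),
                      best_position = integer(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(sites$mirna_id, sites$target_id, sep = "\r")
  o <- order(-.site_rank[sites$site_type], sites$position)
  sites <- sites[o, , drop = FALSE]
  key <- key[o]
  first <- !duplicated(key)
  out <- data.frame(mirna_id = sites$mirna_id[first],
                    target_id = sites$target_id[first],
                    best_site_type = sites$site_type[first],
                    best_position = sites$position[first],
                    n_sites = as.integer(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect target-prediction sources and restrict to DE genes
#'
#' Keeps (miRNA, target) pairs present in every enabled source, then drops
#' pairs whose target is not differentially expressed. Evidence records the
#' source names.
#'
#' @param source_lists named list of data.frames, each with `mirna_id`,
#'   `target_id` (e.g. the in-repo seed scan plus external prediction
#'   lists).
#' @param degs character vector of DE gene ids.
#' @return data.frame `mirna_id`, `target_id`, `evidence`.
#' @export
intersect_sources <- function(source_lists, degs) {
  if (length(source_lists) == 0L) stop("no target-prediction sources given")
  keysets <- lapply(source_lists, function(d) {
    unique(paste(d$mirna_id, d$target_id, sep = "\r"))
  })
  common <- Reduce(intersect, keysets)
  if (length(common) == 0L) {
    return(data.frame(mirna_id = character(), target_id = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(common, "\r", fixed = TRUE)
  out <- data.frame(mirna_id = vapply(parts, `[[`, "", 1L),
                    target_id = vapply(parts, `[[`, "", 2L),
                    evidence = paste(names(source_lists), collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[out$target_id %in% degs, , drop = FALSE]
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' miRNA sites on differentially expressed lncRNAs
#'
#' Scans DEL sequences for seed sites of the supplied miRNAs and keeps
#' pairs whose miRNA is itself differentially expressed.
#'
#' @param mirna_seqs named mature miRNA sequences.
#' @param del_seqs named DEL sequences.
#' @param dem_ids character vector of DE miRNA ids.
#' @return data.frame `mirna_id`, `lncrna_id`, `best_site_type`,
#'   `best_position`, `n_sites`.
#' @export
lnc_mirna_targets <- function(mirna_seqs, del_seqs, dem_ids) {
  mirna_seqs <- mirna_seqs[names(mirna_seqs) %in% dem_ids]
  empty <- data.frame(mirna_id = character(), lncrna_id = character(),
                      best_site_type = character(),
                      best_position = integer(), n_sites = integer(),
                      stringsAsFactors = FALSE)
  if (length(mirna_seqs) == 0L || length(del_seqs) == 0L) return(empty)
  sites <- scan_seed_sites(mirna_seqs, del_seqs, target_kind = "lncrna")
  pairs <- sites_to_pairs(sites)
  names(pairs)[names(pairs) == "target_id"] <- "lncrna_id"
  pairs
}
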