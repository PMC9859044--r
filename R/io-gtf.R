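#' Read transcript models from a GTF file
#'
#' Strict reader for GTF2.2-style 9-column annotation (Ensembl / StringTie
#' dialect). Exon features are aggregated per `transcript_id`; all
#' coordinates are 1-based inclusive, as in the format itself. A
#' `class_code` attribute (StringTie merge / gffcompare dialect) is carried
#' through when present; unknown attributes are ignored and attribute order
#' is not significant.
#'
#' @param path path to a GTF file.
#' @return A `transcript_models` data.frame with one row per transcript:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `class_code` (NA when
#'   absent), `n_exons`, `spliced_length`, `span_start`, `span_end`, and a
#'   list column `exons` of two-column matrices (start, end) sorted by
#'   start.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_transcript_models())

  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields, got ",
         nf[which(nf != 9L)[1L]])
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1L]]
    stop("malformed GTF line ", bad, ": non-integer coordinates")
  }
  if (any(start > end)) {
    bad <- idx[which(start > end)[1L]]
    stop("malformed GTF line ", bad, ": start > end")
  }
  attr_str <- m[, 9L]
  tx_id <- gtf_attribute(attr_str, "transcript_id")
  gene_id <- gtf_attribute(attr_str, "gene_id")
  class_code <- gtf_attribute(attr_str, "class_code")

  is_exon <- m[, 3L] == "exon"
  if (any(is_exon & is.na(tx_id))) {
    bad <- idx[which(is_exon & is.na(tx_id))[1L]]
    stop("malformed GTF line ", bad, ": exon without transcript_id attribute")
  }
  if (any(is_exon & is.na(gene_id))) {
    bad <- idx[which(is_exon & is.na(gene_id))[1L]]
    stop("malformed GTF line ", bad, ": exon without gene_id attribute")
  }
  if (!any(is_exon)) return(empty_transcript_models())

  # class_code may sit on the transcript line only: index it per transcript
  cc_by_tx <- tapply(class_code, tx_id, function(v) {
    v <- unique(v[!is.na(v)])
    if (length(v) == 0L) NA_character_ else v[1L]
  })

  ex <- data.frame(
    transcript_id = tx_id[is_exon], gene_id = gene_id[is_exon],
    chrom = m[is_exon, 1L], strand = m[is_exon, 7L],
    start = start[is_exon], end = end[is_exon],
    line = idx[is_exon], stringsAsFactors = FALSE
  )
  sp <- split(ex, ex$transcript_id)
  rows <- lapply(sp, function(d) {
    o <- order(d$start, d$end)
    d <- d[o, , drop = FALSE]
    if (length(unique(d$chrom)) != 1L || length(unique(d$strand)) != 1L) {
      stop("transcript ", d$transcript_id[1L],
           " has exons on multiple chromosomes or strands")
    }
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop("transcript ", d$transcript_id[1L], " has overlapping exons")
    }
    list(
      transcript_id = d$transcript_id[1L], gene_id = d$gene_id[1L],
      chrom = d$chrom[1L], strand = d$strand[1L],
      class_code = unname(cc_by_tx[[d$transcript_id[1L]]]),
      n_exons = nrow(d),
      spliced_length = sum(d$end - d$start + 1L),
      span_start = d$start[1L], span_end = max(d$end),
      exons = list(cbind(start = d$start, end = d$end))
    )
  })
  out <- data.frame(
    transcript_id = vapply(rows, `[[`, "", "transcript_id"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    class_code = vapply(rows, `[[`, NA_character_, "class_code"),
    n_exons = vapply(rows, `[[`, 0L, "n_exons"),
    spliced_length = vapply(rows, `[[`, 0L, "spliced_length"),
    span_start = vapply(rows, `[[`, 0L, "span_start"),
    span_end = vapply(rows, `[[`, 0L, "span_end"),
    stringsAsFactors = FALSE
  )
  out$exons <- lapply(rows, function(r) r$exons[[1L]])
  rownames(out) <- NULL
  class(out) <- c("transcript_models", "data.frame")
  out
}

empty_transcript_models <- function() {
  out <- data.frame(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), class_code = character(), n_exons = integer(),
    spliced_length = integer(), span_start = integer(), span_end = integer(),
    stringsAsFactors = FALSE
  )
  out$exons <- list()
  class(out) <- c("transcript_models", "data.frame")
  out
}

gtf_attribute <- function(attr_str, key) {
  pat <- paste0('(^|; ?)', key, ' +"([^"]*)"')
  m <- regmatches(attr_str, regexec(pat, attr_str))
  vapply(m, function(x) if (length(x) >= 3L) x[3L] else NA_character_,
         NA_character_)
}

#' Write transcript models to GTF
#'
#' Emits one `transcript` line plus one `exon` line per exon, with
#' `transcript_id`, `gene_id` and (when present) `class_code` attributes.
#'
#' @param txs a `transcript_models` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(txs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(txs))) {
    cc <- txs$class_code[i]
    attr_tx <- sprintf('transcript_id "%s"; gene_id "%s";%s',
                       txs$transcript_id[i], txs$gene_id[i],
                       if (is.na(cc)) "" else sprintf(' class_code "%s";', cc))
    ex <- txs$exons[[i]]
    writeLines(sprintf("%s\tcernanet\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       txs$chrom[i], txs$span_start[i], txs$span_end[i],
                       txs$strand[i], attr_tx), con)
    writeLines(sprintf("%s\tcernanet\texon\t%d\t%d\t.\t%s\t.\t%s",
                       txs$chrom[i], ex[, "start"], ex[, "end"],
                       txs$strand[i], attr_tx), con)
  }
  invisible(path)
}

#' Genomic spans of transcript or gene models
#'
#' @param txs a `transcript_models` data.frame.
#' @param id_col which id to carry ("transcript_id" or "gene_id"). For
#'   gene spans the per-gene span is the union of its transcripts' spans.
#' @return data.frame with `id`, `chrom`, `start`, `end`.
#' @export
feature_spans <- function(txs, id_col = c("transcript_id", "gene_id")) {
  id_col <- match.arg(id_col)
  d <- data.frame(id = txs[[id_col]], chrom = txs$chrom,
                  start = txs$span_start, end = txs$span_end,
                  stringsAsFactors = FALSE)
  if (id_col == "gene_id") {
    sp <- split(d, d$id)
    d <- do.call(rbind, lapply(sp, function(x) {
      data.frame(id = x$id[1L], chrom = x$chrom[1L], start = min(x$start),
                 end = max(x$end), stringsAsFactors = FALSE)
    }))
    rownames(d) <- NULL
  }
  d
}
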