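# Hypergeometric over-representation against user-provided gene sets, with
# the raw p < 0.05 significance convention (optional BH column for users
# wanting correction).

#' Hypergeometric gene-set over-representation
#'
#' For each set, with N background genes, K set members in the background,
#' n query genes and k hits, the upper-tail p-value is
#' `P(X >= k)` for X hypergeometric(N, K, n). Results are sorted by
#' (p, set id). No multiple-testing correction is applied by default,
#' matching the raw p < 0.05 screening convention; `bh = TRUE` adds an
#' `fdr` column.
#'
#' @param query_genes character vector of query gene ids (must be a subset
#'   of the background).
#' @param gene_sets a `gene_sets` collection ([read_gmt()]).
#' @param background character vector of background gene ids (for count
#'   data, typically all expressed genes).
#' @param config a [pipeline_config()].
#' @param bh add a BH-adjusted column.
#' @return data.frame `set_id`, `name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `significant`, `member_hits` (comma-joined).
#' @export
hypergeom_enrich <- function(query_genes, gene_sets, background,
                             config = pipeline_config(), bh = FALSE) {
  query_genes <- unique(query_genes)
  background <- unique(background)
  if (length(query_genes) == 0L) stop("empty query")
  if (length(background) == 0L) stop("empty background")
  extra <- setdiff(query_genes, background)
  if (length(extra)) {
    stop("query genes missing from background: ",
         paste(head(extra, 3L), collapse = ", "))
  }
  N <- length(background)
  n <- length(query_genes)
  set_names <- attr(gene_sets, "set_names")
  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(gene_sets[[id]], background)
    K <- length(members)
    hits <- intersect(members, query_genes)
    k <- length(hits)
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n,
                                    lower.tail = FALSE)
    data.frame(set_id = id,
               name = if (!is.null(set_names)) set_names[[id]] else id,
               k = k, K = K, n = n, N = N, p_value = p,
               member_hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$significant <- res$p_value < config$enrich_p_max
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  if (bh) res$fdr <- bh_fdr(res$p_value)
  rownames(res) <- NULL
  res
}

#' Format enrichment results as a Term/ID/p/Gene table
#'
#' @param results a [hypergeom_enrich()] result.
#' @param significant_only keep only significant sets.
#' @param path optional TSV output path.
#' @return data.frame with `term`, `id`, `p_value`, `genes`.
#' @export
format_enrichment <- function(results, significant_only = TRUE,
                              path = NULL) {
  if (significant_only) {
    results <- results[results$significant, , drop = FALSE]
  }
  out <- data.frame(term = results$name, id = results$set_id,
                    p_value = results$p_value,
                    genes = results$member_hits,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) data.table::fwrite(out, path, sep = "\t")
  out
}
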