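# lncRNA target inference: cis by +/- 100 kb genomic windows, trans by
# Spearman correlation with a strict |rho| > 0.8 threshold at p < 0.05.

#' Cis target search by genomic window
#'
#' For each lncRNA genomic span (min exon start to max exon end) and each
#' gene span on the same chromosome, the distance is 0 when the spans
#' overlap (`coincide`), otherwise the gap between nearest ends. A pair is
#' emitted iff distance <= `cis_window_bp` (inclusive). Strand is ignored.
#'
#' @param lnc_spans data.frame `id`, `chrom`, `start`, `end` (see
#'   [feature_spans()]).
#' @param gene_spans same layout for genes.
#' @param config a [pipeline_config()].
#' @return data.frame `lncrna_id`, `gene_id`, `distance_bp`, `coincide`.
#' @export
cis_targets <- function(lnc_spans, gene_spans, config = pipeline_config()) {
  out <- list()
  for (chr in intersect(unique(lnc_spans$chrom), unique(gene_spans$chrom))) {
    ls <- lnc_spans[lnc_spans$chrom == chr, , drop = FALSE]
    gs <- gene_spans[gene_spans$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(ls))) {
      gap <- pmax(gs$start - ls$end[i], ls$start[i] - gs$end, 0L)
      keep <- gap <= config$cis_window_bp
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          lncrna_id = ls$id[i], gene_id = gs$id[keep],
          distance_bp = as.integer(gap[keep]),
          coincide = gap[keep] == 0L &
            gs$start[keep] <= ls$end[i] & gs$end[keep] >= ls$start[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance_bp = integer(), coincide = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Spearman correlation (mid-rank Pearson)
#' @param x,y numeric vectors of equal length >= 3.
#' @return rank correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

#' Two-sided Spearman p-value (t approximation)
#'
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` against Student t with n - 2
#' degrees of freedom. For |rho| = 1 the p-value is 0 and the result
#' carries attribute `exact = TRUE`.
#'
#' @param rho Spearman correlation.
#' @param n sample count (>= 4).
#' @return two-sided p-value.
#' @export
spearman_pvalue <- function(rho, n) {
  stopifnot(n >= 4L)
  if (abs(rho) >= 1) {
    p <- 0
    attr(p, "exact") <- TRUE
    return(p)
  }
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Trans target screen over all lncRNA x gene pairs
#'
#' Scores every pair by Spearman correlation of expression across all
#' samples (groups pooled) and retains pairs with |rho| strictly greater
#' than `trans_abs_rho_min` and p < `trans_p_max`.
#'
#' @param lnc_expr `expression_matrix` (or plain matrix) of lncRNA
#'   expression, features x samples.
#' @param gene_expr matching gene expression matrix (same samples).
#' @param config a [pipeline_config()].
#' @param keep_all return all scored pairs (retained flag) instead of the
#'   retained subset.
#' @return data.frame `lncrna_id`, `gene_id`, `rho`, `p_value`, `n`.
#' @export
trans_targets <- function(lnc_expr, gene_expr, config = pipeline_config(),
                          keep_all = FALSE) {
  lv <- if (inherits(lnc_expr, "expression_matrix")) lnc_expr$values
        else lnc_expr
  gv <- if (inherits(gene_expr, "expression_matrix")) gene_expr$values
        else gene_expr
  stopifnot(identical(colnames(lv), colnames(gv)))
  n <- ncol(lv)
  if (nrow(lv) == 0L || nrow(gv) == 0L) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      rho = numeric(), p_value = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  rl <- t(apply(lv, 1L, rank, ties.method = "average"))
  rg <- t(apply(gv, 1L, rank, ties.method = "average"))
  rho <- cor(t(rl), t(rg))
  res <- data.frame(
    lncrna_id = rep(rownames(lv), times = nrow(gv)),
    gene_id = rep(rownames(gv), each = nrow(lv)),
    rho = as.vector(rho), n = n, stringsAsFactors = FALSE)
  res$p_value <- vapply(res$rho, function(r) {
    if (is.na(r)) return(NA_real_)
    as.numeric(spearman_pvalue(r, n))
  }, 0)
  res$retained <- !is.na(res$rho) &
    abs(res$rho) > config$trans_abs_rho_min &
    res$p_value < config$trans_p_max
  res <- res[, c("lncrna_id", "gene_id", "rho", "p_value", "n", "retained")]
  if (!keep_all) {
    res <- res[res$retained, setdiff(names(res), "retained"), drop = FALSE]
  }
  res <- res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge cis and trans targets into per-lncRNA DE target-gene sets
#'
#' Union of the cis and trans gene sets, restricted to DE genes, each gene
#' annotated with its route: cis, trans or both.
#'
#' @param cis_pairs a [cis_targets()] result.
#' @param trans_pairs a [trans_targets()] result.
#' @param degs character vector of DE gene ids.
#' @return data.frame `lncrna_id`, `gene_id`, `mode` in
#'   {cis, trans, both}.
#' @export
merge_lnc_targets <- function(cis_pairs, trans_pairs, degs) {
  ck <- unique(paste(cis_pairs$lncrna_id, cis_pairs$gene_id, sep = "\r"))
  tk <- unique(paste(trans_pairs$lncrna_id, trans_pairs$gene_id,
                     sep = "\r"))
  all_k <- union(ck, tk)
  if (length(all_k) == 0L) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      mode = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(all_k, "\r", fixed = TRUE)
  out <- data.frame(lncrna_id = vapply(parts, `[[`, "", 1L),
                    gene_id = vapply(parts, `[[`, "", 2L),
                    mode = ifelse(all_k %in% ck & all_k %in% tk, "both",
                                  ifelse(all_k %in% ck, "cis", "trans")),
                    stringsAsFactors = FALSE)
  out <- out[out$gene_id %in% degs, , drop = FALSE]
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
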