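#' Pipeline configuration
#'
#' Central container for every threshold the analysis uses. Defaults follow
#' the standard screening conventions for this kind of two-group design:
#' FDR < 0.05 with |fold change| >= 2 for differential expression; class
#' codes i/u/x, >= 2 exons and length > 200 nt for lncRNA candidates; an
#' FPKM floor of 0.1 in at least one sample; Pfam-style domain exclusion at
#' E-value < 1e-5; a +/- 100 kb window for cis target search; |Spearman rho|
#' > 0.8 with p < 0.05 for trans targets; raw p < 0.05 for enrichment; and
#' top-10 degree for PPI hub genes.
#'
#' @param fdr_threshold FDR cutoff for differential-expression calls.
#' @param abs_fc_threshold minimum |fold change| (linear scale) for a call.
#' @param min_exons minimum exon count for a lncRNA candidate.
#' @param min_tx_length minimum spliced transcript length in nt (201 means
#'   "length > 200").
#' @param fpkm_floor minimum FPKM required in at least one sample.
#' @param domain_evalue_max transcripts with a protein-domain hit below this
#'   E-value are discarded as coding.
#' @param cis_window_bp genomic window (bp) for cis target search, applied
#'   upstream and downstream.
#' @param trans_abs_rho_min strict lower bound on |Spearman rho| for a trans
#'   target relationship.
#' @param trans_p_max p-value cutoff for trans target relationships.
#' @param enrich_p_max raw p-value cutoff for enrichment significance.
#' @param hub_top_n number of top-degree PPI genes reported (ties at the
#'   cutoff are all kept).
#' @param class_codes_kept assembler class codes retained as lncRNA
#'   candidates.
#' @param rng_seed integer seed used wherever the pipeline draws random
#'   numbers.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_threshold = 0.05,
                            abs_fc_threshold = 2,
                            min_exons = 2L,
                            min_tx_length = 201L,
                            fpkm_floor = 0.1,
                            domain_evalue_max = 1e-5,
                            cis_window_bp = 100000L,
                            trans_abs_rho_min = 0.8,
                            trans_p_max = 0.05,
                            enrich_p_max = 0.05,
                            hub_top_n = 10L,
                            class_codes_kept = c("i", "u", "x"),
                            rng_seed = 1L) {
  cfg <- list(
    fdr_threshold = fdr_threshold,
    abs_fc_threshold = abs_fc_threshold,
    min_exons = as.integer(min_exons),
    min_tx_length = as.integer(min_tx_length),
    fpkm_floor = fpkm_floor,
    domain_evalue_max = domain_evalue_max,
    cis_window_bp = as.integer(cis_window_bp),
    trans_abs_rho_min = trans_abs_rho_min,
    trans_p_max = trans_p_max,
    enrich_p_max = enrich_p_max,
    hub_top_n = as.integer(hub_top_n),
    class_codes_kept = as.character(class_codes_kept),
    rng_seed = as.integer(rng_seed)
  )
  num <- c("fdr_threshold", "abs_fc_threshold", "min_exons", "min_tx_length",
           "fpkm_floor", "domain_evalue_max", "cis_window_bp",
           "trans_abs_rho_min", "trans_p_max", "enrich_p_max", "hub_top_n")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a single positive number")
    }
  }
  if (length(cfg$class_codes_kept) == 0L) {
    stop("class_codes_kept must be non-empty")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("cernanet pipeline configuration\n")
  for (f in setdiff(names(x), "class_codes_kept")) {
    cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  }
  cat(sprintf("  %-20s %s\n", "class_codes_kept",
              paste(x$class_codes_kept, collapse = ",")))
  invisible(x)
}
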