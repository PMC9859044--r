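# Two-group negative-binomial differential-expression screen: TMM
# normalization, pooled method-of-moments dispersion, conditional exact
# test, Benjamini-Hochberg FDR and the FDR < 0.05 & |FC| >= 2 call rule.

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values against a reference sample: log ratios
#' (M) are trimmed 30% on each side, average log intensities (A) 5% on each
#' side, and the surviving M values are combined with inverse-variance
#' (delta-method binomial) weights. Factors are rescaled so their geometric
#' mean is 1; they multiply library sizes.
#'
#' @param counts integer matrix, features x samples (or an
#'   `expression_matrix`).
#' @param ref_sample reference column name/index; default is the sample
#'   whose 75th percentile of count fractions is closest to the mean.
#' @param logratio_trim,sum_trim two-sided trim fractions for M and A.
#' @return named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05) {
  if (inherits(counts, "expression_matrix")) counts <- counts$values
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample column")
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2L, function(x) stats::quantile(x / sum(x), 0.75))
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  refc <- counts[, ref_sample]
  nref <- lib[ref_sample]
  f <- vapply(seq_len(ncol(counts)), function(k) {
    obsc <- counts[, k]
    nobs <- lib[k]
    keep <- obsc > 0 & refc > 0
    if (!any(keep)) return(1)
    po <- obsc[keep] / nobs
    pr <- refc[keep] / nref
    M <- log2(po / pr)
    A <- 0.5 * log2(po * pr)
    w <- (nobs - obsc[keep]) / (nobs * obsc[keep]) +
      (nref - refc[keep]) / (nref * refc[keep])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1
    hiA <- n + 1 - loA
    keep2 <- rank(M, ties.method = "first") >= loM &
      rank(M, ties.method = "first") <= hiM &
      rank(A, ties.method = "first") >= loA &
      rank(A, ties.method = "first") <= hiA
    if (!any(keep2)) {
      warning("all features trimmed for sample ", k, "; factor set to 1")
      return(1)
    }
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

effective_lib_sizes <- function(counts, factors) {
  colSums(counts) * factors
}

#' Pooled common dispersion (method of moments)
#'
#' On counts scaled to a common effective library size, within-group sample
#' means and variances are pooled across features through the NB relation
#' `Var = mu + phi * mu^2`:
#' `phi = sum(v - m) / sum(m^2)`, floored at 1e-6.
#'
#' @param counts matrix or `expression_matrix` of counts.
#' @param design named group labels per sample (exactly 2 groups).
#' @param factors optional TMM factors (default computed).
#' @return single dispersion estimate `phi`.
#' @export
estimate_dispersion <- function(counts, design, factors = NULL) {
  if (inherits(counts, "expression_matrix")) {
    if (missing(design)) design <- counts$design
    counts <- counts$values
  }
  design <- design[colnames(counts)]
  groups <- unique(design)
  if (length(groups) != 2L) stop("exactly 2 groups required")
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- effective_lib_sizes(counts, factors)
  scaled <- sweep(counts, 2L, mean(eff) / eff, `*`)
  num <- 0
  den <- 0
  for (g in groups) {
    sub <- scaled[, design == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  max(1e-6, num / den)
}

#' Conditional NB exact test for one feature
#'
#' Counts are scaled to the common effective library size and rounded; the
#' group-A sum is tested against its conditional NB distribution given the
#' total (group sums of iid NB(mu, phi) are NB with size n_g / phi). The
#' two-sided p doubles the smaller tail, capped at 1.
#'
#' @param counts_f integer vector of counts for one feature.
#' @param design named group labels (2 groups; names match `counts_f`).
#' @param phi common dispersion.
#' @param factors effective-library scaling: named per-sample factors on
#'   library sizes (lib sizes must be supplied via `lib_sizes`).
#' @param lib_sizes named per-sample library sizes (default: all equal).
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(counts_f, design, phi, factors = NULL,
                          lib_sizes = NULL) {
  design <- design[names(counts_f)]
  groups <- unique(design)
  if (length(groups) != 2L) stop("exactly 2 groups required")
  if (is.null(lib_sizes)) {
    lib_sizes <- setNames(rep(1, length(counts_f)), names(counts_f))
  }
  if (is.null(factors)) {
    factors <- setNames(rep(1, length(counts_f)), names(counts_f))
  }
  eff <- lib_sizes[names(counts_f)] * factors[names(counts_f)]
  y <- round(counts_f * mean(eff) / eff)
  ya <- sum(y[design == groups[1L]])
  yb <- sum(y[design == groups[2L]])
  t <- ya + yb
  if (t == 0) return(1)
  na <- sum(design == groups[1L])
  nb <- sum(design == groups[2L])
  m <- t / (na + nb)
  k <- 0:t
  if (phi < 1e-10) {
    lp <- dpois(k, lambda = na * m, log = TRUE) +
      dpois(t - k, lambda = nb * m, log = TRUE)
  } else {
    lp <- dnbinom(k, size = na / phi, mu = na * m, log = TRUE) +
      dnbinom(t - k, size = nb / phi, mu = nb * m, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  lower <- sum(pr[k <= ya])
  upper <- sum(pr[k >= ya])
  min(1, 2 * min(lower, upper))
}

#' Benjamini-Hochberg step-up FDR
#'
#' `fdr_(i) = min_{j >= i} p_(j) * m / j` over the sorted p-values, capped
#' at 1 and mapped back to input order.
#'
#' @param p_values numeric vector of p-values (no NAs).
#' @return FDR-adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric())
  o <- order(p_values)
  ps <- p_values[o]
  q <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Two-group differential-expression screen
#'
#' TMM normalization, pooled common dispersion, per-feature conditional NB
#' exact test, BH FDR, and the call rule: `up` iff FDR < `fdr_threshold`
#' and log2FC >= log2(`abs_fc_threshold`); `down` symmetrically; otherwise
#' `ns`. log2FC uses normalized group means with pseudocount 0.5, numerator
#' group first. Features with all-zero counts are excluded before testing
#' (they do not enter the BH `m`).
#'
#' @param counts an `expression_matrix` with unit "count".
#' @param config a [pipeline_config()].
#' @param numerator_group group used as fold-change numerator (default the
#'   first group encountered in the design).
#' @return data.frame with `feature_id`, `log2fc`, `p_value`, `fdr`,
#'   `call`.
#' @export
screen_de <- function(counts, config = pipeline_config(),
                      numerator_group = NULL) {
  stopifnot(inherits(counts, "expression_matrix"))
  design <- counts$design
  groups <- unique(design)
  if (length(groups) != 2L) {
    stop("differential expression requires exactly 2 groups, got ",
         length(groups))
  }
  if (is.null(numerator_group)) numerator_group <- groups[1L]
  if (!numerator_group %in% groups) stop("unknown numerator group")
  groups <- c(numerator_group, setdiff(groups, numerator_group))
  vals <- counts$values
  keep <- rowSums(vals) > 0
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) == 0L) {
    return(data.frame(feature_id = character(), log2fc = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  }
  factors <- tmm_factors(vals)
  phi <- estimate_dispersion(vals, design, factors)
  lib <- colSums(vals)
  pvals <- vapply(seq_len(nrow(vals)), function(i) {
    nb_exact_test(vals[i, ], design, phi, factors = factors,
                  lib_sizes = lib)
  }, 0)
  fdr <- bh_fdr(pvals)
  eff <- effective_lib_sizes(vals, factors)
  scaled <- sweep(vals, 2L, mean(eff) / eff, `*`)
  ma <- rowMeans(scaled[, design == groups[1L], drop = FALSE])
  mb <- rowMeans(scaled[, design == groups[2L], drop = FALSE])
  log2fc <- log2((ma + 0.5) / (mb + 0.5))
  lfc_min <- log2(config$abs_fc_threshold)
  call <- rep("ns", nrow(vals))
  call[fdr < config$fdr_threshold & log2fc >= lfc_min] <- "up"
  call[fdr < config$fdr_threshold & log2fc <= -lfc_min] <- "down"
  data.frame(feature_id = rownames(vals), log2fc = log2fc, p_value = pvals,
             fdr = fdr, call = call, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Differentially expressed feature ids from a screen result
#' @param de a [screen_de()] result.
#' @return character vector of features called up or down.
#' @export
de_features <- function(de) de$feature_id[de$call != "ns"]
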