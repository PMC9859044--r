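# Synthetic-data generator: negative-binomial counts with planted fold
# changes, coding/noncoding transcript sequences, canonical miRNA seed
# sites, cis neighbours within the genomic window, rank-correlated trans
# pairs and full ceRNA triangles -- all with recorded ground truth.

#' Simulation parameters
#'
#' The defaults state the world the pipeline is tested in: two groups of 6
#' biological replicates, negative-binomial counts with variance
#' `mu + dispersion * mu^2`, 10% of features differentially expressed at a
#' planted |log2 fold change| of 2 (4-fold, comfortably past the >= 2-fold
#' screening rule), and a log-normal baseline with median 200 counts.
#'
#' @param n_per_group biological replicates per group (>= 3).
#' @param n_genes number of mRNA genes.
#' @param n_mirnas number of miRNAs.
#' @param n_lnc_candidates number of assembled candidate transcripts fed to
#'   the lncRNA identification cascade.
#' @param frac_de fraction of features with a planted fold change.
#' @param planted_log2fc |log2 fold change| planted in DE features.
#' @param nb_dispersion NB dispersion (edgeR convention).
#' @param baseline_log_mean,baseline_log_sd log-normal baseline mean
#'   parameters (natural log scale).
#' @param n_triangles planted ceRNA triangles (DEL, DEM, DEG).
#' @param n_cis_pairs extra planted cis (lncRNA, gene) neighbours.
#' @param n_trans_pairs planted trans pairs with high rank correlation.
#' @param trans_target_rho target Spearman correlation of planted trans
#'   pairs (must lie in (0.8, 1)).
#' @param seed integer RNG seed.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(n_per_group = 6L, n_genes = 500L,
                              n_mirnas = 60L, n_lnc_candidates = 150L,
                              frac_de = 0.1, planted_log2fc = 2.0,
                              nb_dispersion = 0.1,
                              baseline_log_mean = log(200),
                              baseline_log_sd = 1.0,
                              n_triangles = 12L, n_cis_pairs = 10L,
                              n_trans_pairs = 15L, trans_target_rho = 0.9,
                              seed = 1L) {
  p <- list(n_per_group = as.integer(n_per_group),
            n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
            n_lnc_candidates = as.integer(n_lnc_candidates),
            frac_de = frac_de, planted_log2fc = planted_log2fc,
            nb_dispersion = nb_dispersion,
            baseline_log_mean = baseline_log_mean,
            baseline_log_sd = baseline_log_sd,
            n_triangles = as.integer(n_triangles),
            n_cis_pairs = as.integer(n_cis_pairs),
            n_trans_pairs = as.integer(n_trans_pairs),
            trans_target_rho = trans_target_rho,
            seed = as.integer(seed))
  if (p$n_per_group < 3L) stop("n_per_group must be >= 3")
  if (p$frac_de < 0 || p$frac_de >= 1) stop("frac_de must be in [0, 1)")
  if (p$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (p$trans_target_rho <= 0.8 || p$trans_target_rho >= 1) {
    stop("trans_target_rho must be in (0.8, 1)")
  }
  class(p) <- "simulation_params"
  p
}

# Set the RNG to `seed` and return a function restoring the previous state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

.dna <- c("A", "C", "G", "T")

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, "", USE.NAMES = FALSE))
}

random_dna <- function(len) {
  paste(sample(.dna, len, replace = TRUE), collapse = "")
}

# Sense codons weighted to mimic coding bias: third-position G/C preference
# and first-position purine preference. This composition gap is what the
# hexamer and Fickett scores are expected to pick up.
.codon_table <- local({
  b <- c("A", "C", "G", "T")
  cods <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE)[, 3:1], 1L,
                paste, collapse = "")
  cods <- setdiff(cods, c("TAA", "TAG", "TGA"))
  w <- 0.5 + 3 * (substr(cods, 3L, 3L) %in% c("C", "G")) +
    1 * (substr(cods, 1L, 1L) %in% c("A", "G"))
  list(codons = cods, prob = w / sum(w))
})

#' Random coding-like sequence
#'
#' A uniform 5' leader, an ATG..stop ORF of at least `min_orf` nt drawn
#' from a biased codon table, then a uniform 3' trailer.
#'
#' @param total_len total transcript length (>= min_orf + 60).
#' @param min_orf minimum ORF length in nt (multiple-of-3 enforced).
#' @return a DNA character string.
#' @export
random_coding_sequence <- function(total_len = sample(420:1500, 1L),
                                   min_orf = 300L) {
  max_orf <- ((total_len - 60L) %/% 3L) * 3L
  orf_len <- 3L * sample(seq(min_orf %/% 3L, max_orf %/% 3L), 1L)
  ncod <- orf_len %/% 3L - 2L           # minus start and stop codons
  orf <- paste0("ATG",
                paste(sample(.codon_table$codons, ncod, replace = TRUE,
                             prob = .codon_table$prob), collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  rest <- total_len - orf_len
  lead <- sample.int(rest + 1L, 1L) - 1L
  paste0(random_dna(lead), orf, random_dna(rest - lead))
}

#' Random noncoding sequence
#'
#' Uniform composition, rejection-sampled until its longest ORF is shorter
#' than `max_orf` nt (capped attempts, then error).
#'
#' @param total_len total length.
#' @param max_orf longest allowed ORF (nt, exclusive).
#' @param max_attempts rejection-sampling cap.
#' @return a DNA character string.
#' @export
random_noncoding_sequence <- function(total_len = sample(250:1200, 1L),
                                      max_orf = 150L,
                                      max_attempts = 1000L) {
  for (i in seq_len(max_attempts)) {
    s <- random_dna(total_len)
    if (longest_orf(s)$length_nt < max_orf) return(s)
  }
  stop("could not sample a noncoding sequence with max ORF < ", max_orf)
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Counts are NB with mean `exp(N(baseline_log_mean, baseline_log_sd))`
#' times a group fold factor and variance `mu + dispersion * mu^2`. Planted
#' DE features get a multiplicative `2^planted_log2fc` in one group
#' (direction "up" means higher in the first group).
#'
#' @param params a [simulation_params()].
#' @param n_features number of features (default `params$n_genes`).
#' @param prefix feature id prefix.
#' @param feature_ids explicit feature ids (overrides prefix).
#' @param de_idx explicit indices of DE features; default samples
#'   `frac_de * n_features` of them.
#' @param groups two group labels; the first is the fold-change numerator.
#' @return list with `matrix` (an `expression_matrix`) and `truth`
#'   (data.frame `feature_id`, `true_log2fc`, `direction`).
#' @export
simulate_counts <- function(params = simulation_params(),
                            n_features = params$n_genes, prefix = "G",
                            feature_ids = NULL, de_idx = NULL,
                            groups = c("SL", "L")) {
  n <- params$n_per_group
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("%s%04d", prefix, seq_len(n_features))
  }
  n_features <- length(feature_ids)
  samples <- c(sprintf("%s_%d", groups[1L], seq_len(n)),
               sprintf("%s_%d", groups[2L], seq_len(n)))
  design <- setNames(rep(groups, each = n), samples)
  mu0 <- rlnorm(n_features, params$baseline_log_mean, params$baseline_log_sd)
  if (is.null(de_idx)) {
    n_de <- round(params$frac_de * n_features)
    de_idx <- if (n_de > 0L) sort(sample.int(n_features, n_de)) else integer()
  }
  lfc <- numeric(n_features)
  if (length(de_idx)) {
    dirs <- rep_len(c(1, -1), length(de_idx))
    lfc[de_idx] <- dirs * params$planted_log2fc
  }
  mu <- cbind(matrix(mu0 * 2^pmax(lfc, 0), n_features, n),
              matrix(mu0 * 2^pmax(-lfc, 0), n_features, n))
  size <- 1 / params$nb_dispersion
  vals <- matrix(rnbinom(length(mu), size = size, mu = mu),
                 nrow = n_features, dimnames = list(feature_ids, samples))
  truth <- data.frame(
    feature_id = feature_ids[de_idx],
    true_log2fc = lfc[de_idx],
    direction = ifelse(lfc[de_idx] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals, design, unit = "count"),
       truth = truth)
}

#' Simulate candidate transcripts for the identification cascade
#'
#' Generates coding and noncoding transcripts whose exon counts, lengths
#' and class codes deliberately span both sides of every structural filter:
#' coding transcripts contain a biased-composition ORF of >= 300 nt,
#' noncoding ones have uniform composition and longest ORF < 150 nt; class
#' codes are drawn from {i, u, x, =, c} with known truth.
#'
#' @param params a [simulation_params()].
#' @return list with `models` (a `transcript_models` data.frame), `seqs`
#'   (named sequences) and `truth` (`coding_tx`, `noncoding_tx`,
#'   `eligible_tx`: true noncoding transcripts that also pass the class
#'   code and structure filters).
#' @export
simulate_transcripts <- function(params = simulation_params()) {
  n <- params$n_lnc_candidates
  n_coding <- n %/% 2L
  n_nc <- n - n_coding
  # among noncoding: ~80% "eligible" (class iux, >=2 exons, length > 200),
  # the rest deliberately fail one structural criterion
  n_fail <- max(1L, round(0.2 * n_nc))
  ids <- sprintf("TX%04d", seq_len(n))
  is_coding <- c(rep(TRUE, n_coding), rep(FALSE, n_nc))
  seqs <- character(n)
  class_code <- character(n)
  n_exons <- integer(n)
  eligible <- logical(n)
  fail_pick <- sample(which(!is_coding), n_fail)
  for (i in seq_len(n)) {
    if (is_coding[i]) {
      seqs[i] <- random_coding_sequence()
      class_code[i] <- sample(c("i", "u", "x", "=", "c"), 1L,
                              prob = c(0.2, 0.3, 0.1, 0.3, 0.1))
      n_exons[i] <- sample(2:5, 1L)
    } else if (i %in% fail_pick) {
      mode <- sample(c("short", "monoexonic", "class"), 1L)
      seqs[i] <- random_noncoding_sequence(
        total_len = if (mode == "short") sample(60:200, 1L)
                    else sample(250:1200, 1L))
      class_code[i] <- if (mode == "class") sample(c("=", "c"), 1L)
                       else sample(c("i", "u", "x"), 1L)
      n_exons[i] <- if (mode == "monoexonic") 1L else sample(2:4, 1L)
    } else {
      seqs[i] <- random_noncoding_sequence()
      class_code[i] <- sample(c("i", "u", "x"), 1L, prob = c(0.3, 0.5, 0.2))
      n_exons[i] <- sample(2:4, 1L)
      eligible[i] <- TRUE
    }
  }
  len <- nchar(seqs)
  eligible <- eligible & n_exons >= 2L & len > 200L
  models <- build_transcript_models(ids, gene_id = paste0("XLOC_", ids),
                                    chrom = "chrU",
                                    start = 1L + (seq_len(n) - 1L) * 50000L,
                                    lengths = len, n_exons = n_exons,
                                    class_code = class_code)
  list(models = models, seqs = setNames(seqs, ids),
       truth = list(coding_tx = ids[is_coding],
                    noncoding_tx = ids[!is_coding],
                    eligible_tx = ids[eligible]))
}

# Lay n_exons exons of total spliced length `lengths` from `start`, with
# 100-2000 bp introns, and assemble a transcript_models data.frame.
build_transcript_models <- function(ids, gene_id, chrom, start, lengths,
                                    n_exons, class_code) {
  n <- length(ids)
  chrom <- rep_len(chrom, n)
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_exons[i]
    cuts <- sort(sample.int(lengths[i] - 1L, k - 1L))
    sizes <- diff(c(0L, cuts, lengths[i]))
    introns <- if (k > 1L) sample(100:2000, k - 1L, replace = TRUE)
               else integer()
    s <- start[i] + c(0L, cumsum(sizes[-k] + introns))
    exons[[i]] <- cbind(start = as.integer(s),
                        end = as.integer(s + sizes - 1L))
  }
  out <- data.frame(
    transcript_id = ids, gene_id = gene_id, chrom = chrom,
    strand = rep_len("+", n), class_code = class_code,
    n_exons = as.integer(n_exons), spliced_length = as.integer(lengths),
    span_start = vapply(exons, function(e) e[1L, 1L], 0L),
    span_end = vapply(exons, function(e) e[nrow(e), 2L], 0L),
    stringsAsFactors = FALSE)
  out$exons <- exons
  class(out) <- c("transcript_models", "data.frame")
  out
}

seed_core6 <- function(mirna_seq) revcomp(substr(mirna_seq, 2L, 7L))

# Gaussian-copula Pearson r whose *sample* Spearman expectation at size n
# equals rho: E[r_s] = 6 / (pi (n+1)) * (asin r + (n-2) asin(r/2))
# (exact for bivariate normal), inverted numerically. The asymptotic
# 2 sin(pi rho / 6) under-shoots noticeably at n = 12.
copula_r_for_spearman <- function(rho, n) {
  if (rho >= 1) return(1)
  f <- function(r) {
    6 / (pi * (n + 1)) * (asin(r) + (n - 2) * asin(r / 2)) - rho
  }
  if (f(1) < 0) return(1)
  stats::uniroot(f, c(0, 1), tol = 1e-9)$root
}

# Replace every occurrence of any core with fresh random bases until the
# sequence carries none (window-level rejection sampling, capped).
scrub_seed_cores <- function(seq, cores, max_attempts = 1000L) {
  for (att in seq_len(max_attempts)) {
    hit <- FALSE
    for (core in cores) {
      m <- gregexpr(core, seq, fixed = TRUE)[[1L]]
      if (m[1L] != -1L) {
        hit <- TRUE
        for (p in as.integer(m)) {
          substr(seq, p, p + 5L) <- random_dna(6L)
        }
      }
    }
    if (!hit) return(seq)
  }
  stop("could not scrub seed cores from a target sequence")
}

#' Plant canonical miRNA seed sites into target sequences
#'
#' Background hygiene first: every target is scrubbed of 6mer seed cores of
#' all supplied miRNAs by rejection-resampling each offending 6-base
#' window (uniform composition) until the sequence is clean -- window-level
#' rather than whole-sequence resampling so hygiene converges for long
#' sequences against many miRNAs. Then, for each planned (miRNA, target,
#' site type), the exact canonical site string -- with flanking bases
#' chosen so the site is of exactly the planned type -- is written at a
#' random recorded position.
#'
#' @param targets named character vector of target sequences.
#' @param mirnas named character vector of mature miRNA sequences (DNA
#'   alphabet).
#' @param site_plan data.frame with `mirna_id`, `target_id`, `site_type`
#'   in {8mer, 7mer-m8, 7mer-A1, 6mer}.
#' @param max_attempts rejection-sampling cap per sequence / per site.
#' @return list with `seqs` (mutated targets) and `truth` (data.frame
#'   `mirna_id`, `target_id`, `site_type`, `position`).
#' @export
plant_seed_sites <- function(targets, mirnas, site_plan,
                             max_attempts = 1000L) {
  stopifnot(all(site_plan$mirna_id %in% names(mirnas)),
            all(site_plan$target_id %in% names(targets)))
  cores <- vapply(mirnas, seed_core6, "")
  for (id in names(targets)) {
    targets[[id]] <- scrub_seed_cores(targets[[id]], cores, max_attempts)
  }
  truth <- data.frame(mirna_id = character(), target_id = character(),
                      site_type = character(), position = integer(),
                      stringsAsFactors = FALSE)
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  for (i in seq_len(nrow(site_plan))) {
    m <- site_plan$mirna_id[i]
    tg <- site_plan$target_id[i]
    type <- site_plan$site_type[i]
    core <- cores[[m]]
    m8c <- comp1(substr(mirnas[[m]], 8L, 8L))
    tlen <- nchar(targets[[tg]])
    if (tlen < 10L) stop("target ", tg, " shorter than a seed site window")
    flank1 <- switch(type,
      "8mer" = , "7mer-m8" = m8c,
      sample(setdiff(.dna, m8c), 1L))
    flank2 <- switch(type,
      "8mer" = , "7mer-A1" = "A",
      sample(setdiff(.dna, "A"), 1L))
    window <- paste0(flank1, core, flank2)
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      q <- sample(2:(tlen - 8L), 1L)
      cand <- paste0(substr(targets[[tg]], 1L, q - 1L), window,
                     substr(targets[[tg]], q + 8L, tlen))
      # junction-spanning cores of other miRNAs force a retry; a core that
      # sits entirely inside the fixed site window cannot be avoided by
      # repositioning and is accepted as an incidental site
      ts <- max(1L, q - 6L)
      touched <- substr(cand, ts, min(tlen, q + 13L))
      stray <- FALSE
      for (oc in cores[setdiff(names(cores), m)]) {
        mm <- gregexpr(oc, touched, fixed = TRUE)[[1L]]
        if (mm[1L] == -1L) next
        gp <- ts + as.integer(mm) - 1L
        if (any(gp < q | gp + 5L > q + 7L)) {
          stray <- TRUE
          break
        }
      }
      extra <- length(gregexpr(core, cand, fixed = TRUE)[[1L]]) >
        sum(truth$mirna_id == m & truth$target_id == tg) + 1L
      if (!stray && !extra) {
        targets[[tg]] <- cand
        pos <- if (type %in% c("8mer", "7mer-m8")) q else q + 1L
        truth <- rbind(truth, data.frame(
          mirna_id = m, target_id = tg, site_type = type,
          position = as.integer(pos), stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place seed site for ", m, " in ", tg)
  }
  list(seqs = targets, truth = truth)
}

#' Plant a target Spearman correlation between feature pairs
#'
#' For each pair, the gene's counts across samples are permuted (a Gaussian
#' copula on ranks) so that the sample Spearman correlation with the
#' reference lncRNA's expression has expectation close to `target_rho`.
#' Because only the order of the existing values changes, each gene's
#' marginal count distribution -- and hence its DE status when the lncRNA
#' shares its direction -- is preserved.
#'
#' @param expr `expression_matrix` whose rows get reordered (genes).
#' @param pairs data.frame with `lncrna`, `gene`, `target_rho`.
#' @param ref_expr `expression_matrix` holding the lncRNA rows (defaults
#'   to `expr`).
#' @return the modified `expr`.
#' @export
plant_trans_correlation <- function(expr, pairs, ref_expr = expr) {
  stopifnot(identical(colnames(expr$values), colnames(ref_expr$values)))
  n <- ncol(expr$values)
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$lncrna[i]
    g <- pairs$gene[i]
    rho <- pairs$target_rho[i]
    if (!l %in% rownames(ref_expr$values)) stop("unknown lncRNA: ", l)
    if (!g %in% rownames(expr$values)) stop("unknown gene: ", g)
    r <- copula_r_for_spearman(rho, n)
    x <- ref_expr$values[l, ]
    z1 <- qnorm(rank(x, ties.method = "average") / (n + 1))
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * rnorm(n)
    y <- sort(expr$values[g, ])
    expr$values[g, ] <- y[rank(z2, ties.method = "first")]
  }
  expr
}

#' Simulate every input of the full pipeline, with recorded truth
#'
#' Generates gene models and counts, miRNA sequences and counts, candidate
#' transcripts for lncRNA identification with counts, 3'UTR sequences with
#' planted seed sites, cis neighbours within the genomic window, trans
#' pairs with planted rank correlation, full ceRNA triangles (DEL, DEM,
#' DEG with a seed site in both the lncRNA and the gene UTR and a cis
#' placement of the lncRNA next to the gene), a PPI edge list with planted
#' hubs, and a gene-set collection with one DE-enriched set.
#'
#' @param params a [simulation_params()].
#' @return a `simulation` list: `params`, `genes` (spans, models, utrs,
#'   counts), `mirnas` (seqs, counts), `lncs` (models, seqs, counts),
#'   `ppi_edges`, `gene_sets`, `truth`.
#' @export
simulate_all <- function(params = simulation_params()) {
  restore <- local_seed(params$seed)
  on.exit(restore())

  # --- genes: spans on a 1 Mb grid, counts, UTRs -------------------------
  gene_ids <- sprintf("G%04d", seq_len(params$n_genes))
  gene_start <- seq_len(params$n_genes) * 1000000L
  gene_len <- sample(5000:20000, params$n_genes, replace = TRUE)
  gene_spans <- data.frame(id = gene_ids, chrom = "chr1",
                           start = gene_start,
                           end = gene_start + gene_len - 1L,
                           stringsAsFactors = FALSE)
  gc <- simulate_counts(params, n_features = params$n_genes, prefix = "G")
  utrs <- setNames(vapply(seq_along(gene_ids),
                          function(i) random_dna(300L), ""), gene_ids)

  # --- miRNAs ------------------------------------------------------------
  mirna_ids <- sprintf("miR%03d", seq_len(params$n_mirnas))
  mirna_seqs <- setNames(vapply(mirna_ids, function(i) random_dna(22L), ""),
                         mirna_ids)
  mc <- simulate_counts(params, n_features = params$n_mirnas,
                        prefix = "miR", feature_ids = mirna_ids)

  # --- lncRNA candidates -------------------------------------------------
  txs <- simulate_transcripts(params)
  elig <- txs$truth$eligible_tx
  n_lnc_de <- max(params$n_triangles,
                  round(params$frac_de * params$n_lnc_candidates))
  if (n_lnc_de > length(elig)) stop("too few eligible lncRNA candidates")
  lnc_de_ids <- sort(sample(elig, n_lnc_de))
  lc <- simulate_counts(params, feature_ids = txs$models$transcript_id,
                        de_idx = match(lnc_de_ids,
                                       txs$models$transcript_id))

  de_gene <- gc$truth
  de_mir <- mc$truth
  de_lnc <- lc$truth

  # --- triangles: distinct DEL and DEG per triangle, DEMs round-robin ----
  k <- params$n_triangles
  if (k > nrow(de_gene) || k > length(lnc_de_ids) || nrow(de_mir) == 0L) {
    stop("not enough DE features to plant the requested triangles")
  }
  tri_lnc <- sample(lnc_de_ids, k)
  tri_gene <- sample(de_gene$feature_id, k)
  tri_mir <- rep_len(sample(de_mir$feature_id), k)
  triangles <- data.frame(lncrna = tri_lnc, mirna = tri_mir,
                          gene = tri_gene, stringsAsFactors = FALSE)

  # seed sites: miRNA site in the gene UTR and in the lncRNA sequence
  utr_plan <- data.frame(mirna_id = tri_mir, target_id = tri_gene,
                         site_type = "8mer", stringsAsFactors = FALSE)
  utr_planted <- plant_seed_sites(utrs, mirna_seqs, utr_plan)
  utrs <- utr_planted$seqs
  lnc_plan <- data.frame(
    mirna_id = tri_mir, target_id = tri_lnc,
    site_type = sample(c("8mer", "7mer-m8", "7mer-A1"), k, replace = TRUE),
    stringsAsFactors = FALSE)
  # hygiene and planting only on the identifiable noncoding candidates:
  # coding transcripts never enter the DEL seed scan downstream
  lnc_planted <- plant_seed_sites(txs$seqs[elig], mirna_seqs, lnc_plan)
  lnc_seqs <- txs$seqs
  lnc_seqs[names(lnc_planted$seqs)] <- lnc_planted$seqs

  # --- genomic placement: triangle/cis lncRNAs near their gene -----------
  cis_extra_lnc <- sample(setdiff(elig, tri_lnc),
                          min(params$n_cis_pairs,
                              length(setdiff(elig, tri_lnc))))
  cis_extra_gene <- sample(setdiff(gene_ids, tri_gene),
                           length(cis_extra_lnc))
  cis_lnc <- c(tri_lnc, cis_extra_lnc)
  cis_gene <- c(tri_gene, cis_extra_gene)
  cis_dist <- sample(1000:90000, length(cis_lnc), replace = TRUE)
  models <- txs$models
  place_at <- function(models, tx_id, new_start) {
    j <- match(tx_id, models$transcript_id)
    ex <- models$exons[[j]]
    ex <- ex + (new_start - ex[1L, 1L])
    models$exons[[j]] <- ex
    models$span_start[j] <- ex[1L, 1L]
    models$span_end[j] <- ex[nrow(ex), 2L]
    models$chrom[j] <- "chr1"
    models
  }
  for (i in seq_along(cis_lnc)) {
    g_end <- gene_spans$end[gene_spans$id == cis_gene[i]]
    models <- place_at(models, cis_lnc[i], g_end + cis_dist[i])
  }
  far <- setdiff(models$transcript_id, cis_lnc)
  far_start <- (params$n_genes + 10L + seq_along(far)) * 1000000L
  for (i in seq_along(far)) {
    models <- place_at(models, far[i], far_start[i])
  }
  rownames(models) <- NULL
  planted_cis <- data.frame(lncrna = cis_lnc, gene = cis_gene,
                            distance_bp = cis_dist,
                            stringsAsFactors = FALSE)

  # --- trans pairs: DE-concordant (lncRNA, gene), copula-planted ---------
  n_tp <- params$n_trans_pairs
  pool_lnc <- de_lnc[de_lnc$feature_id %in% lnc_de_ids, ]
  pairs <- list()
  used_genes <- tri_gene
  for (d in c("up", "down")) {
    lp <- pool_lnc$feature_id[pool_lnc$direction == d]
    gp <- setdiff(de_gene$feature_id[de_gene$direction == d], used_genes)
    m <- min(length(gp), ceiling(n_tp / 2))
    if (m > 0L && length(lp) > 0L) {
      pairs[[d]] <- data.frame(
        lncrna = sample(lp, m, replace = TRUE),
        gene = sample(gp, m), target_rho = params$trans_target_rho,
        stringsAsFactors = FALSE)
      used_genes <- c(used_genes, pairs[[d]]$gene)
    }
  }
  planted_trans <- do.call(rbind, pairs)
  planted_trans <- head(planted_trans, n_tp)
  rownames(planted_trans) <- NULL
  gc$matrix <- plant_trans_correlation(gc$matrix, planted_trans,
                                       ref_expr = lc$matrix)

  # --- PPI: planted hubs + background noise ------------------------------
  hubs <- sample(de_gene$feature_id, 5L)
  hub_edges <- do.call(rbind, lapply(hubs, function(h) {
    data.frame(a = h, b = sample(setdiff(gene_ids, h), 15L),
               stringsAsFactors = FALSE)
  }))
  n_bg <- 200L
  bg <- data.frame(a = sample(gene_ids, n_bg, replace = TRUE),
                   b = sample(gene_ids, n_bg, replace = TRUE),
                   stringsAsFactors = FALSE)
  ppi <- rbind(hub_edges, bg[bg$a != bg$b, ])
  rownames(ppi) <- NULL

  # --- gene sets: random partition + one DE-enriched set -----------------
  shuffled <- sample(gene_ids)
  sets <- split(shuffled, ceiling(seq_along(shuffled) / 25L))
  names(sets) <- sprintf("SET%02d", seq_along(sets))
  enriched_members <- unique(c(sample(de_gene$feature_id,
                                      min(15L, nrow(de_gene))),
                               sample(gene_ids, 10L)))
  sets[["SET_DE"]] <- enriched_members
  gene_sets <- structure(sets,
                         set_names = setNames(paste("pathway", names(sets)),
                                              names(sets)),
                         class = "gene_sets")

  structure(list(
    params = params,
    genes = list(spans = gene_spans, utrs = utrs, counts = gc$matrix),
    mirnas = list(seqs = mirna_seqs, counts = mc$matrix),
    lncs = list(models = models, seqs = lnc_seqs, counts = lc$matrix),
    ppi_edges = ppi,
    gene_sets = gene_sets,
    truth = list(
      de_genes = de_gene, de_mirnas = de_mir, de_lncs = de_lnc,
      coding_tx = txs$truth$coding_tx,
      noncoding_tx = txs$truth$noncoding_tx,
      eligible_tx = txs$truth$eligible_tx,
      planted_seed_sites = rbind(utr_planted$truth, lnc_planted$truth),
      planted_cis_pairs = planted_cis,
      planted_trans_pairs = planted_trans,
      planted_triangles = triangles,
      hub_genes = hubs,
      enriched_set = "SET_DE")
  ), class = "simulation")
}

#' Write a simulation to disk as plain-text pipeline inputs
#'
#' @param sim a [simulate_all()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  gene_models <- build_gene_models(sim$genes$spans)
  write_gtf(gene_models, p("genes.gtf"))
  write_gtf(sim$lncs$models, p("lnc_candidates.gtf"))
  write_fasta(sim$lncs$seqs, p("lnc_candidates.fa"))
  write_fasta(sim$mirnas$seqs, p("mirnas.fa"))
  write_fasta(sim$genes$utrs, p("utr3.fa"))
  write_counts(sim$genes$counts, p("counts_genes.tsv"), p("design.tsv"))
  write_counts(sim$mirnas$counts, p("counts_mirnas.tsv"))
  write_counts(sim$lncs$counts, p("counts_lnc.tsv"))
  write_edge_list(sim$ppi_edges, p("ppi_edges.tsv"))
  write_gmt(sim$gene_sets, p("gene_sets.gmt"))
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

# One single-exon transcript per gene so gene spans survive a GTF round trip.
build_gene_models <- function(gene_spans) {
  n <- nrow(gene_spans)
  out <- data.frame(
    transcript_id = paste0(gene_spans$id, ".t1"), gene_id = gene_spans$id,
    chrom = gene_spans$chrom, strand = rep_len("+", n),
    class_code = rep(NA_character_, n), n_exons = rep(1L, n),
    spliced_length = gene_spans$end - gene_spans$start + 1L,
    span_start = gene_spans$start, span_end = gene_spans$end,
    stringsAsFactors = FALSE)
  out$exons <- lapply(seq_len(n), function(i) {
    cbind(start = gene_spans$start[i], end = gene_spans$end[i])
  })
  class(out) <- c("transcript_models", "data.frame")
  out
}
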