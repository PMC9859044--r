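test_that("simulate_counts is reproducible and respects frac_de = 0", {
  p0 <- simulation_params(frac_de = 0, n_genes = 50L, seed = 11L)
  restore <- cernanet:::local_seed(11L)
  a <- simulate_counts(p0, n_features = 50L)
  restore()
  restore <- cernanet:::local_seed(11L)
  b <- simulate_counts(p0, n_features = 50L)
  restore()
  expect_identical(a$matrix$values, b$matrix$values)
  expect_equal(nrow(a$truth), 0L)
})

test_that("planted log2fc = 2 gives ~4-fold group mean ratio", {
  # Monte-Carlo check: many replicate features, one high fixed baseline
  p <- simulation_params(n_per_group = 6L, planted_log2fc = 2,
                         nb_dispersion = 0.1,
                         baseline_log_mean = log(5000),
                         baseline_log_sd = 0, seed = 21L)
  restore <- cernanet:::local_seed(21L)
  on.exit(restore())
  n_rep <- 5000L
  sim <- simulate_counts(p, n_features = n_rep,
                         de_idx = seq_len(n_rep))
  up <- sim$truth$direction == "up"
  v <- sim$matrix$values
  ratio <- rowMeans(v[, 1:6]) / rowMeans(v[, 7:12])
  obs <- mean(ratio[up])
  se <- sd(ratio[up]) / sqrt(sum(up))
  expect_lt(abs(obs - 4), 3 * se + 0.05)
  # down-planted features are ~4-fold the other way
  obs_dn <- mean(1 / ratio[!up])
  expect_lt(abs(obs_dn - 4), 3 * sd(1 / ratio[!up]) / sqrt(sum(!up)) + 0.05)
})

test_that("NB dispersion follows the mu + phi mu^2 convention", {
  p <- simulation_params(nb_dispersion = 0.2, baseline_log_mean = log(500),
                         baseline_log_sd = 0, frac_de = 0, seed = 31L)
  restore <- cernanet:::local_seed(31L)
  on.exit(restore())
  sim <- simulate_counts(p, n_features = 4000L)
  v <- as.numeric(sim$matrix$values)
  mu <- mean(v)
  expect_lt(abs(var(v) - (mu + 0.2 * mu^2)) / (mu + 0.2 * mu^2), 0.1)
})

test_that("simulate_transcripts generates both sides of every filter", {
  restore <- cernanet:::local_seed(41L)
  on.exit(restore())
  p <- simulation_params(n_lnc_candidates = 100L, seed = 41L)
  sim <- simulate_transcripts(p)
  m <- sim$models
  expect_true(any(m$n_exons == 1L))
  expect_true(any(m$spliced_length <= 200L))
  expect_true(any(!m$class_code %in% c("i", "u", "x")))
  # generator postconditions on coding/noncoding composition
  cod <- sim$seqs[sim$truth$coding_tx]
  ncd <- sim$seqs[sim$truth$noncoding_tx]
  expect_true(all(vapply(cod, function(s) longest_orf(s)$length_nt, 0L)
                  >= 300L))
  expect_true(all(vapply(ncd, function(s) longest_orf(s)$length_nt, 0L)
                  < 150L))
  # eligible truth matches the structural predicates
  elig <- m$transcript_id %in% sim$truth$eligible_tx
  expect_true(all(m$n_exons[elig] >= 2L))
  expect_true(all(m$spliced_length[elig] > 200L))
  expect_true(all(m$class_code[elig] %in% c("i", "u", "x")))
})

test_that("planted seed sites are found at the recorded position and type", {
  restore <- cernanet:::local_seed(51L)
  on.exit(restore())
  mirnas <- setNames(vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
          collapse = ""), ""), paste0("m", 1:5))
  targets <- setNames(vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
          collapse = ""), ""), paste0("t", 1:6))
  plan <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m4"),
    target_id = c("t1", "t2", "t3", "t4"),
    site_type = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
    stringsAsFactors = FALSE)
  out <- plant_seed_sites(targets, mirnas, plan)
  for (i in seq_len(nrow(plan))) {
    tr <- out$truth[i, ]
    hits <- seed_sites(mirnas[[tr$mirna_id]], out$seqs[[tr$target_id]],
                       tr$mirna_id, tr$target_id)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$site_type, tr$site_type)
    expect_equal(hits$position, tr$position)
    # cross-check with the brute-force scanner
    orc <- oracle_seed_scan(mirnas[[tr$mirna_id]], out$seqs[[tr$target_id]])
    expect_equal(orc$site_type, tr$site_type)
    expect_equal(orc$position, tr$position)
  }
  # hygienic background: unplanted targets carry no site for any miRNA
  for (tg in c("t5", "t6")) {
    for (m in names(mirnas)) {
      expect_equal(nrow(seed_sites(mirnas[[m]], out$seqs[[tg]], m, tg)), 0L)
    }
  }
  expect_error(plant_seed_sites(setNames("ACGTAC", "short"), mirnas,
                                data.frame(mirna_id = "m1",
                                           target_id = "short",
                                           site_type = "8mer")),
               "shorter")
})

test_that("plant_trans_correlation hits the target Spearman rho", {
  restore <- cernanet:::local_seed(61L)
  on.exit(restore())
  n <- 12L
  n_pairs <- 1000L
  vals <- matrix(rnbinom(2L * n_pairs * n, size = 10, mu = 200),
                 nrow = 2L * n_pairs,
                 dimnames = list(sprintf("f%04d", seq_len(2L * n_pairs)),
                                 sprintf("s%02d", seq_len(n))))
  em <- expression_matrix(vals, setNames(rep(c("A", "B"), each = n / 2L),
                                         colnames(vals)))
  lncs <- rownames(vals)[seq_len(n_pairs)]
  genes <- rownames(vals)[n_pairs + seq_len(n_pairs)]
  pairs <- data.frame(lncrna = lncs, gene = genes, target_rho = 0.9,
                      stringsAsFactors = FALSE)
  out <- plant_trans_correlation(em, pairs)
  rhos <- vapply(seq_len(n_pairs), function(i) {
    spearman_rho(out$values[lncs[i], ], out$values[genes[i], ])
  }, 0)
  expect_gt(mean(rhos), 0.85)
  expect_lt(mean(rhos), 0.95)
  # marginal count values untouched (pure reordering)
  expect_equal(sort(out$values[genes[1L], ]),
               sort(vals[genes[1L], ]), ignore_attr = TRUE)
  # exactness at target_rho = 1: zero copula noise, pure monotone reorder
  small <- expression_matrix(
    matrix(c(sample(100:200, 8L), sample(300:400, 8L)), nrow = 2L,
           byrow = TRUE, dimnames = list(c("l", "g"), paste0("s", 1:8))),
    setNames(rep(c("A", "B"), each = 4L), paste0("s", 1:8)))
  one <- plant_trans_correlation(small, data.frame(
    lncrna = "l", gene = "g", target_rho = 1))
  expect_equal(spearman_rho(one$values["l", ], one$values["g", ]), 1)
  expect_error(plant_trans_correlation(em, data.frame(
    lncrna = "nope", gene = genes[1L], target_rho = 0.9)), "unknown")
})

test_that("unplanted pairs stay null: |rho| > 0.8 rate within binomial bounds", {
  restore <- cernanet:::local_seed(71L)
  on.exit(restore())
  n <- 12L
  n_pairs <- 2000L
  rhos <- vapply(seq_len(n_pairs), function(i) {
    spearman_rho(rnorm(n), rnorm(n))
  }, 0)
  rate <- mean(abs(rhos) > 0.8)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_pairs))
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(n_pairs) + 0.01)
})

test_that("simulation truth tables are internally consistent", {
  params <- simulation_params(seed = 81L)
  sim <- simulate_all(params)
  tr <- sim$truth
  # every planted triangle's three relations appear in the planted lists
  for (i in seq_len(nrow(tr$planted_triangles))) {
    t3 <- tr$planted_triangles[i, ]
    expect_true(any(tr$planted_seed_sites$mirna_id == t3$mirna &
                    tr$planted_seed_sites$target_id == t3$gene))
    expect_true(any(tr$planted_seed_sites$mirna_id == t3$mirna &
                    tr$planted_seed_sites$target_id == t3$lncrna))
    expect_true(any(tr$planted_cis_pairs$lncrna == t3$lncrna &
                    tr$planted_cis_pairs$gene == t3$gene))
    # triangle members are all planted DE
    expect_true(t3$lncrna %in% tr$de_lncs$feature_id)
    expect_true(t3$mirna %in% tr$de_mirnas$feature_id)
    expect_true(t3$gene %in% tr$de_genes$feature_id)
  }
  expect_true(all(tr$planted_cis_pairs$distance_bp <= 100000L))
  expect_true(all(tr$planted_trans_pairs$target_rho > 0.8 &
                  tr$planted_trans_pairs$target_rho < 1))
  # planted ids reference generated features only
  expect_true(all(tr$planted_seed_sites$target_id %in%
                  c(names(sim$genes$utrs), names(sim$lncs$seqs))))
})

test_that("simulate_all and write_simulation are byte-deterministic", {
  params <- simulation_params(n_genes = 80L, n_mirnas = 12L,
                              n_lnc_candidates = 40L, n_triangles = 3L,
                              n_cis_pairs = 2L, n_trans_pairs = 3L,
                              seed = 91L)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  write_simulation(simulate_all(params), d1)
  write_simulation(simulate_all(params), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
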