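test_that("class-code filter keeps exactly i/u/x and drops absent codes", {
  txs <- bind_tx(make_tx("a", "u"), make_tx("b", "i"), make_tx("c", "x"),
                 make_tx("d", "="), make_tx("e", "c"),
                 make_tx("f", NA_character_))
  kept <- filter_class_code(txs)
  expect_setequal(kept$transcript_id, c("a", "b", "c"))
  expect_equal(nrow(filter_class_code(txs[0, ])), 0L)
  expect_equal(nrow(filter_class_code(bind_tx(make_tx("a", "=")))), 0L)
})

test_that("structural filter enforces >= 2 exons and length > 200", {
  txs <- bind_tx(make_tx("ok", n_exons = 2L, len = 201L),
                 make_tx("short", n_exons = 2L, len = 200L),
                 make_tx("mono", n_exons = 1L, len = 5000L))
  expect_identical(filter_structure(txs)$transcript_id, "ok")
})

test_that("longest_orf matches closed forms and the brute-force oracle", {
  expect_equal(longest_orf("ATGAAATAA")$length_nt, 9L)
  expect_equal(longest_orf("CCCCCCCCCCCC")$length_nt, 0L)
  # unterminated ORF does not count
  expect_equal(longest_orf("ATGAAAAAAAAA")$length_nt, 0L)
  # two ORFs in different frames: the longer wins
  s <- paste0("ATGAAATAA", "C", "ATG", strrep("GCA", 8), "TGA")
  res <- longest_orf(s)
  expect_equal(res$length_nt, 30L)
  expect_equal(substr(s, res$start, res$start + 2L), "ATG")
  set.seed(7)
  for (i in 1:40) {
    r <- paste(sample(c("A", "C", "G", "T"), sample(20:300, 1),
                      replace = TRUE), collapse = "")
    expect_equal(longest_orf(r)$length_nt, oracle_longest_orf(r),
                 label = r)
  }
})

test_that("fickett_score matches a hand lookup and is scale invariant", {
  # independent evaluation of the lookup tables on a degenerate input
  tabs <- cernanet:::.fickett
  hand_fickett <- function(seq) {
    ch <- strsplit(seq, "")[[1L]]
    total <- 0
    for (b in c("A", "C", "G", "T")) {
      cnt <- c(sum(ch[seq(1, length(ch), 3)] == b),
               sum(ch[seq(2, length(ch), 3)] == b),
               sum(ch[seq(3, length(ch), 3)] == b))
      posp <- max(cnt) / (min(cnt) + 1)
      cont <- sum(cnt) / length(ch)
      pi <- which(posp >= tabs$position_para)[1L]
      ci <- which(cont >= tabs$content_para)[1L]
      total <- total + tabs$position_prob[[b]][pi] * tabs$position_weight[[b]] +
        tabs$content_prob[[b]][ci] * tabs$content_weight[[b]]
    }
    total
  }
  per <- strrep("ACGT", 100L)
  expect_equal(as.numeric(fickett_score(per)), hand_fickett(per))
  # AAC repeats: maximal positional asymmetry for A and C
  aac <- strrep("AAC", 100L)
  expect_equal(as.numeric(fickett_score(aac)), hand_fickett(aac))
  # duplicate concatenation leaves composition and phase unchanged
  # (sequence length a multiple of 3)
  s <- strrep("ATGGCATTACCA", 6L)
  expect_equal(as.numeric(fickett_score(paste0(s, s))),
               as.numeric(fickett_score(s)))
  expect_true(isTRUE(attr(fickett_score("ACGTACGT"), "low_confidence")))
})

test_that("fickett separates coding-biased from uniform sequences", {
  restore <- cernanet:::local_seed(101L)
  on.exit(restore())
  cod <- replicate(200, random_coding_sequence(1000L))
  ncd <- replicate(200, paste(sample(c("A", "C", "G", "T"), 1000L,
                                     replace = TRUE), collapse = ""))
  fc <- vapply(cod, function(s) as.numeric(fickett_score(s)), 0)
  fn <- vapply(ncd, function(s) as.numeric(fickett_score(s)), 0)
  expect_gt(mean(fc), mean(fn))
})

test_that("hexamer score: identity table gives 0, single-hexamer closed form", {
  u <- cernanet:::hexamer_universe()
  flat <- structure(list(
    f_coding = setNames(rep(1 / 4096, 4096), u),
    f_noncoding = setNames(rep(1 / 4096, 4096), u)),
    class = "hexamer_table")
  expect_equal(hexamer_score("ACGTACGTACGTACG", flat), 0)
  # a repeated hexamer seen at step 3 alternates between its two frame
  # rotations; enrich both so every scanned hexamer has the same log ratio
  tab <- flat
  tab$f_coding[c("GGGCCC", "CCCGGG")] <-
    tab$f_coding[c("GGGCCC", "CCCGGG")] * 8
  expect_equal(hexamer_score(strrep("GGGCCC", 10L), tab), log(8))
  expect_equal(hexamer_score("ACGTA", flat), 0)  # shorter than 6
})

test_that("hexamer score discriminates simulated coding vs noncoding", {
  restore <- cernanet:::local_seed(111L)
  on.exit(restore())
  train_c <- replicate(100, random_coding_sequence())
  train_n <- replicate(100, random_noncoding_sequence())
  tab <- train_hexamer_table(train_c, train_n)
  test_c <- replicate(100, random_coding_sequence())
  test_n <- replicate(100, random_noncoding_sequence())
  sc <- vapply(test_c, hexamer_score, 0, hexamer_table = tab)
  sn <- vapply(test_n, hexamer_score, 0, hexamer_table = tab)
  r <- rank(c(sc, sn))
  auroc <- (sum(r[1:100]) - 100 * 101 / 2) / (100 * 100)
  expect_gt(auroc, 0.9)
})

test_that("consensus_call is the intersection minus domain hits", {
  v <- expand.grid(transcript_id = c("t1", "t2", "t3"),
                   source = c("s1", "s2", "s3", "s4"),
                   stringsAsFactors = FALSE)
  v$call <- "noncoding"
  v$call[v$transcript_id == "t3" & v$source == "s2"] <- "coding"
  hits <- data.frame(transcript_id = "t2", evalue = 1e-6)
  # t1: 4/4 noncoding, clean -> noncoding; t2: domain hit -> discarded;
  # t3: 3/4 -> coding
  expect_identical(consensus_call(v, hits), "t1")
  # an E-value at/above the threshold does not discard
  weak <- data.frame(transcript_id = "t2", evalue = 1e-5)
  expect_identical(consensus_call(v, weak), c("t1", "t2"))
  expect_error(consensus_call(v[-1L, ], NULL), "missing a verdict")

  # brute-force equivalence on random verdict tables
  set.seed(5)
  for (rep in 1:10) {
    txs <- sprintf("x%02d", 1:12)
    srcs <- c("a", "b", "c")
    vv <- expand.grid(transcript_id = txs, source = srcs,
                      stringsAsFactors = FALSE)
    vv$call <- sample(c("coding", "noncoding"), nrow(vv), replace = TRUE)
    dh <- data.frame(transcript_id = sample(txs, 3L),
                     evalue = 10^runif(3L, -9, -3))
    got <- consensus_call(vv, dh)
    per_source <- lapply(srcs, function(s) {
      vv$transcript_id[vv$source == s & vv$call == "noncoding"]
    })
    want <- setdiff(Reduce(intersect, per_source),
                    dh$transcript_id[dh$evalue < 1e-5])
    expect_setequal(got, want)
  }
})

test_that("fpkm formula, inclusive floor and zero-library error", {
  vals <- matrix(c(10L, 0L, 999990L, 10L, 5L, 999985L), ncol = 2L,
                 dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  em <- expression_matrix(vals, setNames(c("A", "B"), c("s1", "s2")))
  fm <- fpkm(em, setNames(c(1000L, 2000L, 1000L), rownames(vals)))
  expect_equal(fm$values["f1", "s1"], 10)   # 10*1e9/(1e6*1000)
  expect_equal(fm$values["f2", "s1"], 0)
  # FPKM exactly at the floor (0.1) in one sample is kept
  floor_em <- expression_matrix(
    matrix(c(1L, 99999999L, 0L, 1L), ncol = 2L,
           dimnames = list(c("low", "high"), c("s1", "s2"))),
    setNames(c("A", "B"), c("s1", "s2")))
  fm2 <- fpkm(floor_em, setNames(c(100L, 1000L), c("low", "high")))
  expect_equal(fm2$values["low", "s1"], 0.1)  # 1e9 / (1e8 * 100)
  expect_true("low" %in% filter_expression(fm2))
  # all-zero row dropped
  z <- expression_matrix(
    matrix(c(0L, 5L, 0L, 5L), ncol = 2L,
           dimnames = list(c("zero", "ok"), c("s1", "s2"))),
    setNames(c("A", "B"), c("s1", "s2")))
  fz <- fpkm(z, setNames(c(100L, 100L), c("zero", "ok")))
  expect_false("zero" %in% filter_expression(fz))
  bad <- expression_matrix(
    matrix(c(0L, 0L, 1L, 1L), ncol = 2L,
           dimnames = list(c("a", "b"), c("s1", "s2"))),
    setNames(c("A", "B"), c("s1", "s2")))
  expect_error(fpkm(bad, setNames(c(10L, 10L), c("a", "b"))), "library")
})

test_that("cascade short-circuits and stages 1-2 commute", {
  restore <- cernanet:::local_seed(121L)
  on.exit(restore())
  p <- simulation_params(n_lnc_candidates = 60L, seed = 121L)
  sim <- simulate_transcripts(p)
  counts <- simulate_counts(p, feature_ids = sim$models$transcript_id)
  audit <- run_lnc_pipeline(sim$models, sim$seqs, counts$matrix)
  # short-circuit: stage-1 failures leave later stages unassessed
  f1 <- !audit$pass_class_code
  expect_true(all(is.na(audit$pass_structure[f1])))
  expect_true(all(is.na(audit$pass_consensus[f1])))
  expect_true(all(!audit$final[f1]))
  # final = conjunction of all assessed stages
  ok <- audit$final
  expect_true(all(audit$pass_class_code[ok] & audit$pass_structure[ok] &
                  audit$pass_consensus[ok] & audit$pass_domain[ok] &
                  audit$pass_expression[ok]))
  # stages 1-2 are pure predicates: outcome is permutation-invariant
  s12 <- filter_structure(filter_class_code(sim$models))
  s21 <- filter_class_code(filter_structure(sim$models))
  expect_setequal(s12$transcript_id, s21$transcript_id)
})

test_that("cascade recovers noncoding truth with sens/spec >= 0.9", {
  # full-size recovery experiment lives in test-acceptance.R; this is a
  # smaller smoke version
  restore <- cernanet:::local_seed(131L)
  on.exit(restore())
  ref <- cernanet:::reference_training_sets(1L, n_per_class = 100L)
  tab <- train_hexamer_table(ref$coding, ref$noncoding)
  cod <- replicate(60, random_coding_sequence())
  ncd <- replicate(60, random_noncoding_sequence())
  seqs <- setNames(c(cod, ncd), sprintf("q%03d", 1:120))
  v <- coding_verdicts(seqs, tab)
  nc <- consensus_call(v)
  expect_gte(mean(names(seqs)[61:120] %in% nc), 0.9)
  expect_gte(mean(!(names(seqs)[1:60] %in% nc)), 0.9)
})
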