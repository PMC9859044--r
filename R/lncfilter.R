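#' Class-code filter for lncRNA candidates
#'
#' Keeps transcripts whose assembler class code is one of the retained
#' codes (default i/u/x: intronic, intergenic, antisense-overlapping).
#' Transcripts with no class code are dropped.
#'
#' @param txs `transcript_models` data.frame.
#' @param config a [pipeline_config()].
#' @return the retained subset of `txs`.
#' @export
filter_class_code <- function(txs, config = pipeline_config()) {
  keep <- !is.na(txs$class_code) & txs$class_code %in% config$class_codes_kept
  txs[keep, , drop = FALSE]
}

#' Structural filter for lncRNA candidates
#'
#' Keeps transcripts with exon count >= `min_exons` and spliced length
#' strictly greater than 200 nt (i.e. >= `min_tx_length`).
#'
#' @inheritParams filter_class_code
#' @return the retained subset of `txs`.
#' @export
filter_structure <- function(txs, config = pipeline_config()) {
  keep <- txs$n_exons >= config$min_exons &
    txs$spliced_length >= config$min_tx_length
  txs[keep, , drop = FALSE]
}

#' Longest open reading frame on the sense strand
#'
#' Scans the three forward frames for ATG..stop ORFs (stop codon included
#' in the length). Unterminated ORFs do not count.
#'
#' @param seq a DNA character string.
#' @return list with `start`, `end` (1-based nucleotide coordinates, NA if
#'   none) and `length_nt` (0 if none).
#' @export
longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- list(start = NA_integer_, end = NA_integer_, length_nt = 0L)
  if (n < 6L) return(best)
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    pos <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(seq, pos, pos + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    if (!any(is_start) || !any(is_stop)) next
    stop_idx <- which(is_stop)
    prev_stop <- 0L
    for (s in stop_idx) {
      cand <- which(is_start[(prev_stop + 1L):(s - 1L)])
      if (length(cand)) {
        a <- prev_stop + cand[1L]
        len <- (s - a + 1L) * 3L
        if (len > best$length_nt) {
          best <- list(start = pos[a], end = pos[s] + 2L, length_nt = len)
        }
      }
      prev_stop <- s
    }
  }
  best
}

# Classic TESTCODE lookup tables (position/content probabilities and
# weights) as bundled by standard coding-potential tools.
.fickett <- list(
  position_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
  position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  position_para = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.26, 0.33, 0.26, 0.24, 0.27, 0.32, 0.58, 0.30)),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
  content_para = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
)

#' Fickett TESTCODE statistic
#'
#' Combines base-composition and codon-position asymmetry parameters of
#' A/C/G/T through the classic published lookup and weight tables. Higher
#' is more coding-like; the conventional coding cutoff is 0.95.
#'
#' @param seq a DNA character string (N counts toward length only).
#' @return numeric score; for sequences shorter than 200 nt the result
#'   carries attribute `low_confidence = TRUE`.
#' @export
fickett_score <- function(seq) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  phase <- rep_len(1:3, n)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    cnt <- tabulate(phase[chars == b], nbins = 3L)
    pos_param <- max(cnt) / (min(cnt) + 1)
    content <- sum(cnt) / n
    pi <- which(pos_param >= .fickett$position_para)[1L]
    ci <- which(content >= .fickett$content_para)[1L]
    score <- score +
      .fickett$position_prob[[b]][pi] * .fickett$position_weight[[b]] +
      .fickett$content_prob[[b]][ci] * .fickett$content_weight[[b]]
  }
  if (n < 200L) attr(score, "low_confidence") <- TRUE
  score
}

#' Train a hexamer usage table
#'
#' Counts in-frame hexamers (step 3) in coding sequences -- in the frame of
#' each sequence's longest ORF -- and in noncoding sequences (frame of the
#' sequence start), returning pseudocount-smoothed frequencies.
#'
#' @param coding_seqs,noncoding_seqs character vectors of DNA sequences.
#' @param pseudocount added to every hexamer count before normalization.
#' @return A `hexamer_table`: list with `f_coding`, `f_noncoding` (named
#'   frequency vectors over the 4096 hexamers).
#' @export
train_hexamer_table <- function(coding_seqs, noncoding_seqs,
                                pseudocount = 1) {
  all_hex <- hexamer_universe()
  count_set <- function(seqs, use_orf_frame) {
    cnt <- setNames(numeric(length(all_hex)), all_hex)
    for (s in seqs) {
      h <- inframe_hexamers(s, use_orf_frame)
      if (length(h)) {
        tb <- table(h)
        cnt[names(tb)] <- cnt[names(tb)] + as.numeric(tb)
      }
    }
    cnt <- cnt + pseudocount
    cnt / sum(cnt)
  }
  structure(list(f_coding = count_set(coding_seqs, TRUE),
                 f_noncoding = count_set(noncoding_seqs, FALSE)),
            class = "hexamer_table")
}

hexamer_universe <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g[, 6:1], 1L, paste, collapse = "")
}

inframe_hexamers <- function(seq, use_orf_frame = TRUE) {
  offset <- 0L
  if (use_orf_frame) {
    orf <- longest_orf(seq)
    if (orf$length_nt > 0L) offset <- (orf$start - 1L) %% 3L
  }
  n <- nchar(seq)
  if (n - offset < 6L) return(character())
  starts <- seq.int(offset + 1L, n - 5L, by = 3L)
  h <- substring(seq, starts, starts + 5L)
  h[!grepl("N", h, fixed = TRUE)]
}

#' Hexamer usage log-likelihood-ratio score
#'
#' Mean over in-frame hexamers (frame of the longest ORF when one exists)
#' of `log(f_coding / f_noncoding)`. Positive means coding-like; 0 for
#' sequences shorter than 6 nt.
#'
#' @param seq DNA character string.
#' @param hexamer_table a table from [train_hexamer_table()].
#' @return numeric score.
#' @export
hexamer_score <- function(seq, hexamer_table) {
  h <- inframe_hexamers(seq, use_orf_frame = TRUE)
  if (length(h) == 0L) return(0)
  lr <- log(hexamer_table$f_coding[h] / hexamer_table$f_noncoding[h])
  mean(lr)
}

# Logistic coding model over (ORF length, ORF coverage, Fickett, hexamer).
# Default coefficients were fit once on the package simulator's stated
# coding/noncoding composition (see train_coding_model) and frozen.
.default_orf_logit_coef <- c(intercept = -50.0, orf_len = 0.2,
                             orf_cov = 5.0, fickett = 2.0, hexamer = 3.0)

#' Feature vector for the ORF logistic coding score
#' @param seq DNA character string.
#' @param hexamer_table a [train_hexamer_table()] table.
#' @return named numeric vector: orf_len, orf_cov, fickett, hexamer.
#' @export
coding_features <- function(seq, hexamer_table) {
  orf <- longest_orf(seq)
  c(orf_len = orf$length_nt,
    orf_cov = orf$length_nt / nchar(seq),
    fickett = as.numeric(fickett_score(seq)),
    hexamer = hexamer_score(seq, hexamer_table))
}

#' Train the ORF logistic coding model
#'
#' Logistic regression of coding status on ORF length, ORF coverage,
#' Fickett score and hexamer score. Perfect separation (common when ORF
#' length alone separates the classes) is tolerated: the fitted
#' probabilities simply saturate.
#'
#' @param coding_seqs,noncoding_seqs training sequences.
#' @param hexamer_table a [train_hexamer_table()] table.
#' @return named coefficient vector usable as `coef` in [orf_logit_score()].
#' @export
train_coding_model <- function(coding_seqs, noncoding_seqs, hexamer_table) {
  X <- t(vapply(c(coding_seqs, noncoding_seqs), coding_features,
                numeric(4L), hexamer_table = hexamer_table))
  y <- rep(c(1L, 0L), c(length(coding_seqs), length(noncoding_seqs)))
  fit <- suppressWarnings(glm(y ~ ., data = as.data.frame(X),
                              family = binomial()))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  setNames(co, c("intercept", "orf_len", "orf_cov", "fickett", "hexamer"))
}

#' ORF logistic coding probability
#' @param seq DNA character string.
#' @param hexamer_table a [train_hexamer_table()] table.
#' @param coef model coefficients; defaults to the frozen simulator fit.
#' @return probability that the sequence is coding.
#' @export
orf_logit_score <- function(seq, hexamer_table,
                            coef = .default_orf_logit_coef) {
  f <- coding_features(seq, hexamer_table)
  plogis(coef[["intercept"]] + sum(coef[-1L] * f))
}

#' In-repo coding-potential verdicts
#'
#' Scores every sequence with the three bundled predictors and applies
#' their decision rules: Fickett coding iff score >= 0.95, hexamer coding
#' iff score > 0, orf_logit coding iff probability >= 0.5.
#'
#' @param seqs named character vector of transcript sequences.
#' @param hexamer_table a [train_hexamer_table()] table.
#' @param logit_coef coefficients for the logistic model.
#' @param fickett_cutoff,hexamer_cutoff,logit_cutoff decision thresholds.
#' @return data.frame with `transcript_id`, `source`, `score`, `call`.
#' @export
coding_verdicts <- function(seqs, hexamer_table,
                            logit_coef = .default_orf_logit_coef,
                            fickett_cutoff = 0.95, hexamer_cutoff = 0,
                            logit_cutoff = 0.5) {
  ids <- names(seqs)
  fick <- vapply(seqs, function(s) as.numeric(fickett_score(s)), 0)
  hex <- vapply(seqs, hexamer_score, 0, hexamer_table = hexamer_table)
  logit <- vapply(seqs, orf_logit_score, 0, hexamer_table = hexamer_table,
                  coef = logit_coef)
  rbind(
    data.frame(transcript_id = ids, source = "fickett", score = fick,
               call = ifelse(fick >= fickett_cutoff, "coding", "noncoding"),
               stringsAsFactors = FALSE, row.names = NULL),
    data.frame(transcript_id = ids, source = "hexamer", score = hex,
               call = ifelse(hex > hexamer_cutoff, "coding", "noncoding"),
               stringsAsFactors = FALSE, row.names = NULL),
    data.frame(transcript_id = ids, source = "orf_logit", score = logit,
               call = ifelse(logit >= logit_cutoff, "coding", "noncoding"),
               stringsAsFactors = FALSE, row.names = NULL)
  )
}

#' Consensus noncoding call
#'
#' A transcript is called noncoding iff every enabled source calls it
#' noncoding AND it has no protein-domain hit with E-value below
#' `domain_evalue_max` (the intersection rule).
#'
#' @param verdicts data.frame with `transcript_id`, `source`, `call`.
#' @param domain_hits data.frame with `transcript_id`, `evalue`, or NULL.
#' @param config a [pipeline_config()].
#' @return character vector of noncoding transcript ids.
#' @export
consensus_call <- function(verdicts, domain_hits = NULL,
                           config = pipeline_config()) {
  txs <- unique(verdicts$transcript_id)
  sources <- unique(verdicts$source)
  key <- table(verdicts$transcript_id, verdicts$source) > 0L
  miss <- which(!key, arr.ind = TRUE)
  if (nrow(miss)) {
    stop("transcript ", rownames(key)[miss[1L, 1L]],
         " is missing a verdict from source ", colnames(key)[miss[1L, 2L]])
  }
  nc_by_source <- lapply(sources, function(s) {
    v <- verdicts[verdicts$source == s, ]
    v$transcript_id[v$call == "noncoding"]
  })
  nc <- Reduce(intersect, nc_by_source, accumulate = FALSE)
  if (!is.null(domain_hits) && nrow(domain_hits)) {
    hit <- unique(domain_hits$transcript_id[
      domain_hits$evalue < config$domain_evalue_max])
    nc <- setdiff(nc, hit)
  }
  sort(intersect(txs, nc))
}

#' FPKM from counts and transcript lengths
#'
#' `FPKM(f, s) = count(f, s) * 1e9 / (lib_size(s) * length(f))`, with
#' library size the column sum of the count matrix and length the spliced
#' exon-union length.
#'
#' @param counts an `expression_matrix` with unit "count".
#' @param lengths named vector of feature lengths (nt), covering all rows.
#' @return an `expression_matrix` with unit "fpkm".
#' @export
fpkm <- function(counts, lengths) {
  stopifnot(inherits(counts, "expression_matrix"), counts$unit == "count")
  lib <- colSums(counts$values)
  if (any(lib == 0)) stop("zero library size in sample ",
                          colnames(counts$values)[lib == 0][1L])
  len <- lengths[rownames(counts$values)]
  if (anyNA(len)) stop("missing length for some features")
  vals <- counts$values * 1e9 /
    (rep(lib, each = nrow(counts$values)) * as.numeric(len))
  expression_matrix(vals, counts$design, unit = "fpkm")
}

#' Expression floor filter
#'
#' Keeps features with FPKM >= `fpkm_floor` in at least one sample
#' (inclusive bound).
#'
#' @param fpkm_matrix an `expression_matrix` with unit "fpkm".
#' @param config a [pipeline_config()].
#' @return character vector of retained feature ids.
#' @export
filter_expression <- function(fpkm_matrix, config = pipeline_config()) {
  stopifnot(fpkm_matrix$unit == "fpkm")
  keep <- apply(fpkm_matrix$values >= config$fpkm_floor, 1L, any)
  rownames(fpkm_matrix$values)[keep]
}

#' Full lncRNA identification cascade
#'
#' Applies, in order: (1) class-code filter, (2) structural filter,
#' (3) coding-potential consensus, (4) protein-domain exclusion,
#' (5) FPKM floor. Each transcript gets an audit row; stages after the
#' first failure are not assessed (NA).
#'
#' @param txs `transcript_models` for all candidate transcripts.
#' @param seqs named character vector of transcript sequences.
#' @param counts `expression_matrix` of transcript counts (may include
#'   more features than `txs`).
#' @param verdicts optional external verdict table; when NULL the three
#'   in-repo scores are computed (the hexamer table and logistic model are
#'   trained on a reference simulation derived from `config$rng_seed`).
#' @param domain_hits optional domain hit table.
#' @param config a [pipeline_config()].
#' @return data.frame with per-stage logical flags (`pass_class_code`,
#'   `pass_structure`, `pass_consensus`, `pass_domain`, `pass_expression`)
#'   and `final`.
#' @export
run_lnc_pipeline <- function(txs, seqs, counts, verdicts = NULL,
                             domain_hits = NULL,
                             config = pipeline_config()) {
  ids <- txs$transcript_id
  audit <- data.frame(transcript_id = ids,
                      pass_class_code = NA, pass_structure = NA,
                      pass_consensus = NA, pass_domain = NA,
                      pass_expression = NA, final = FALSE,
                      stringsAsFactors = FALSE)
  rownames(audit) <- ids

  s1 <- filter_class_code(txs, config)$transcript_id
  audit$pass_class_code <- ids %in% s1

  s2 <- filter_structure(txs[txs$transcript_id %in% s1, , drop = FALSE],
                         config)$transcript_id
  audit[s1, "pass_structure"] <- s1 %in% s2

  if (length(s2)) {
    if (is.null(verdicts)) {
      ref <- reference_training_sets(config$rng_seed)
      htab <- train_hexamer_table(ref$coding, ref$noncoding)
      verdicts <- coding_verdicts(seqs[s2], htab)
    } else {
      verdicts <- verdicts[verdicts$transcript_id %in% s2, , drop = FALSE]
    }
    nc_all <- consensus_call(verdicts, domain_hits = NULL, config = config)
    audit[s2, "pass_consensus"] <- s2 %in% nc_all
    s3 <- intersect(s2, nc_all)

    if (length(s3)) {
      hit <- character()
      if (!is.null(domain_hits) && nrow(domain_hits)) {
        hit <- unique(domain_hits$transcript_id[
          domain_hits$evalue < config$domain_evalue_max])
      }
      audit[s3, "pass_domain"] <- !(s3 %in% hit)
      s4 <- setdiff(s3, hit)

      if (length(s4)) {
        present <- intersect(s4, rownames(counts$values))
        lens <- setNames(txs$spliced_length, txs$transcript_id)
        fm <- fpkm(counts, setNames(
          lens[rownames(counts$values)], rownames(counts$values)))
        expr_ok <- filter_expression(fm, config)
        audit[s4, "pass_expression"] <- s4 %in% intersect(present, expr_ok)
      }
    }
  }
  audit$final <- !is.na(audit$pass_expression) & audit$pass_expression &
    audit$pass_class_code & audit$pass_structure &
    audit$pass_consensus & audit$pass_domain
  rownames(audit) <- NULL
  audit
}

# Small fixed-composition training sets for the in-repo coding scores,
# regenerated deterministically from a seed (no binary model shipped).
reference_training_sets <- function(seed = 1L, n_per_class = 150L) {
  withr_seed <- local_seed(seed + 777L)
  on.exit(withr_seed())
  list(coding = replicate(n_per_class, random_coding_sequence()),
       noncoding = replicate(n_per_class, random_noncoding_sequence()))
}
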