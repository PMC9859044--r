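# Fixtures are built in code at test time; nothing binary is stored.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A two-transcript GTF: T1 with exons 100-200 and 300-400 (+, class "u"),
# T2 single exon 1000-1500 (-, no class code).
tiny_gtf <- function() {
  write_tmp(c(
    'chr1\tsim\ttranscript\t100\t400\t.\t+\t.\ttranscript_id "T1"; gene_id "GA"; class_code "u";',
    'chr1\tsim\texon\t100\t200\t.\t+\t.\ttranscript_id "T1"; gene_id "GA"; class_code "u";',
    'chr1\tsim\texon\t300\t400\t.\t+\t.\ttranscript_id "T1"; gene_id "GA"; class_code "u";',
    'chr2\tsim\texon\t1000\t1500\t.\t-\t.\tgene_id "GB"; transcript_id "T2";'
  ), ext = ".gtf")
}

# Minimal transcript_models row constructor for filter tests.
make_tx <- function(id, class_code = "u", n_exons = 2L, len = 500L,
                    chrom = "chr1", start = 1000L) {
  df <- data.frame(transcript_id = id, gene_id = paste0("g_", id),
                   chrom = chrom, strand = "+", class_code = class_code,
                   n_exons = as.integer(n_exons),
                   spliced_length = as.integer(len),
                   span_start = as.integer(start),
                   span_end = as.integer(start + len - 1L),
                   stringsAsFactors = FALSE)
  df$exons <- list(cbind(start = start, end = start + len - 1L))
  class(df) <- c("transcript_models", "data.frame")
  df
}

bind_tx <- function(...) {
  out <- do.call(rbind, lapply(list(...), function(x) {
    class(x) <- "data.frame"
    x
  }))
  class(out) <- c("transcript_models", "data.frame")
  out
}

# Small two-group count matrix with named dims.
tiny_counts <- function(n_features = 20L, n = 3L, seed = 1L,
                        mu = 100, phi = 0.1) {
  set.seed(seed)
  vals <- matrix(rnbinom(n_features * 2 * n, size = 1 / phi, mu = mu),
                 nrow = n_features,
                 dimnames = list(sprintf("f%02d", seq_len(n_features)),
                                 c(sprintf("A_%d", seq_len(n)),
                                   sprintf("B_%d", seq_len(n)))))
  design <- setNames(rep(c("A", "B"), each = n), colnames(vals))
  expression_matrix(vals, design)
}

# Independent brute-force oracles ----------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    ri <- sum(p <= p[i])  # rank with ties sharing the max rank
    cand <- Inf
    for (j in seq_len(m)) {
      rj <- sum(p <= p[j])
      if (rj >= ri) cand <- min(cand, p[j] * m / rj)
    }
    out[i] <- min(1, cand)
  }
  out
}

# Naive per-position seed-site scan, classifying each core hit.
oracle_seed_scan <- function(mirna, target) {
  rc <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  core <- rc(substr(mirna, 2, 7))
  m8c <- chartr("ACGT", "TGCA", substr(mirna, 8, 8))
  tl <- nchar(target)
  out <- NULL
  for (p in seq_len(tl - 5L)) {
    if (substr(target, p, p + 5L) != core) next
    m8 <- p > 1L && substr(target, p - 1L, p - 1L) == m8c
    a1 <- p + 6L <= tl && substr(target, p + 6L, p + 6L) == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
            else if (a1) "7mer-A1" else "6mer"
    start <- if (m8) p - 1L else p
    end <- if (a1) p + 6L else p + 5L
    if (grepl("N", substr(target, start, end))) next
    out <- rbind(out, data.frame(site_type = type, position = start,
                                 stringsAsFactors = FALSE))
  }
  out
}

oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (a in seq_len(max(0L, n - 5L))) {
    if (substr(seq, a, a + 2L) != "ATG") next
    b <- a + 3L
    while (b + 2L <= n) {
      if (substr(seq, b, b + 2L) %in% stops) {
        best <- max(best, b + 2L - a + 1L)
        break
      }
      b <- b + 3L
    }
  }
  best
}

# All-pairs span distance (0 on overlap) within a window.
oracle_cis <- function(lnc, genes, window) {
  out <- NULL
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(genes))) {
      if (lnc$chrom[i] != genes$chrom[j]) next
      ov <- lnc$start[i] <= genes$end[j] && genes$start[j] <= lnc$end[i]
      d <- if (ov) 0L else max(genes$start[j] - lnc$end[i],
                               lnc$start[i] - genes$end[j])
      if (d <= window) {
        out <- rbind(out, data.frame(
          lncrna_id = lnc$id[i], gene_id = genes$id[j],
          distance_bp = as.integer(d), coincide = ov,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) return(out)
  out <- out[order(out$lncrna_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

oracle_triangles <- function(lm, mt, lt) {
  out <- NULL
  for (i in seq_len(nrow(lm))) {
    l <- lm$lncrna_id[i]
    m <- lm$mirna_id[i]
    gs <- unique(lt$gene_id[lt$lncrna_id == l])
    ms <- unique(mt$target_id[mt$mirna_id == m])
    for (g in gs) {
      if (g %in% ms) {
        out <- rbind(out, data.frame(lncrna_id = l, mirna_id = m,
                                     mrna_id = g,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) return(out)
  out <- unique(out)
  out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), ]
  rownames(out) <- NULL
  out
}

oracle_hypergeom <- function(k, K, n, N) {
  # exhaustive sum of C(K,i) C(N-K,n-i) / C(N,n) over i >= k
  tot <- 0
  for (i in k:min(K, n)) {
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  }
  tot / choose(N, n)
}
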