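test_that("extract_triangles takes per-pair target intersections", {
  lm <- data.frame(lncrna_id = "DEL1", mirna_id = "DEM1")
  mt <- data.frame(mirna_id = c("DEM1", "DEM1"),
                   target_id = c("g2", "g3"))
  lt <- data.frame(lncrna_id = c("DEL1", "DEL1"),
                   gene_id = c("g1", "g2"))
  out <- extract_triangles(lm, mt, lt)
  expect_equal(out,
               data.frame(lncrna_id = "DEL1", mirna_id = "DEM1",
                          mrna_id = "g2", stringsAsFactors = FALSE))
  # unpaired DEL/DEM share targets but yield no triangle
  lm2 <- data.frame(lncrna_id = "DEL2", mirna_id = "DEM2")
  expect_equal(nrow(extract_triangles(lm2, mt, lt)), 0L)
  expect_equal(nrow(extract_triangles(lm[0, ], mt, lt)), 0L)
})

test_that("extract_triangles equals brute force and ignores input order", {
  set.seed(79)
  for (rep in 1:8) {
    lm <- unique(data.frame(
      lncrna_id = sample(paste0("l", 1:6), 10L, replace = TRUE),
      mirna_id = sample(paste0("m", 1:5), 10L, replace = TRUE)))
    mt <- unique(data.frame(
      mirna_id = sample(paste0("m", 1:5), 25L, replace = TRUE),
      target_id = sample(paste0("g", 1:12), 25L, replace = TRUE)))
    lt <- unique(data.frame(
      lncrna_id = sample(paste0("l", 1:6), 25L, replace = TRUE),
      gene_id = sample(paste0("g", 1:12), 25L, replace = TRUE)))
    got <- extract_triangles(lm, mt, lt)
    want <- oracle_triangles(lm, mt, lt)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got, want)
    }
    shuffled <- extract_triangles(lm[sample(nrow(lm)), ],
                                  mt[sample(nrow(mt)), ],
                                  lt[sample(nrow(lt)), ])
    expect_equal(got, shuffled)
  }
})

test_that("assemble_network types nodes, dedups edges, merges evidence", {
  tri <- data.frame(lncrna_id = "l1", mirna_id = "m1", mrna_id = "g1")
  lm <- data.frame(lncrna_id = c("l1", "l2"), mirna_id = c("m1", "m1"))
  mt <- data.frame(mirna_id = "m1", target_id = "g1")
  lt <- data.frame(lncrna_id = c("l1", "l1"), gene_id = c("g1", "g1"),
                   mode = c("cis", "trans"))
  dirs <- c(l1 = "up", l2 = "down", m1 = "down", g1 = "up")
  net <- assemble_network(tri, lm, mt, lt, dirs)
  expect_s3_class(net, "cerna_network")
  # only triangle relationships retained; duplicate lnc-mrna edge merged
  expect_equal(nrow(net$edges), 3L)
  ev <- net$edges$evidence[net$edges$relation == "lnc-mrna"]
  expect_equal(ev, "cis,trans")
  expect_false("l2" %in% net$nodes$id)
  expect_equal(net$nodes$de_direction[net$nodes$id == "m1"], "down")
  # every triangle edge exists and node kinds respect the relation typing
  kinds <- setNames(net$nodes$kind, net$nodes$id)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    want <- switch(e$relation, "lnc-mir" = c("lncrna", "mirna"),
                   "mir-mrna" = c("mirna", "mrna"),
                   "lnc-mrna" = c("lncrna", "mrna"))
    expect_equal(unname(kinds[c(e$from, e$to)]), want)
  }
  # pairs_only mode keeps everything
  net2 <- assemble_network(tri[0, ], lm, mt, lt, dirs, pairs_only = TRUE)
  expect_true("l2" %in% net2$nodes$id)
  # empty triangles without pairs_only -> empty network
  net3 <- assemble_network(tri[0, ], lm, mt, lt, dirs)
  expect_equal(nrow(net3$edges), 0L)
  expect_equal(nrow(net3$nodes), 0L)
})

test_that("network serialization round-trips", {
  tri <- data.frame(lncrna_id = "l1", mirna_id = "m1", mrna_id = "g1",
                    stringsAsFactors = FALSE)
  lm <- data.frame(lncrna_id = "l1", mirna_id = "m1")
  mt <- data.frame(mirna_id = "m1", target_id = "g1")
  lt <- data.frame(lncrna_id = "l1", gene_id = "g1", mode = "cis")
  net <- assemble_network(tri, lm, mt, lt,
                          c(l1 = "up", m1 = "down", g1 = "up"))
  d <- tempfile()
  write_network(net, d)
  back <- read_network(d)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges[order(back$edges$relation), ],
               net$edges[order(net$edges$relation),
                         c("from", "to", "relation", "evidence")],
               ignore_attr = TRUE)
  expect_equal(back$triangles, net$triangles)
})

test_that("ppi_hubs: star, dedup, ties at the cutoff, oracle", {
  cfg <- pipeline_config()
  star <- data.frame(a = "hub", b = paste0("leaf", 1:9))
  out <- ppi_hubs(star, c("hub", paste0("leaf", 1:9)), cfg)
  expect_equal(out$gene_id[1L], "hub")
  expect_equal(out$degree[1L], 9L)
  expect_equal(out$rank[1L], 1L)
  # duplicate edges (either orientation) count once; self-loops dropped
  dup <- data.frame(a = c("A", "B", "A", "A"), b = c("B", "A", "B", "A"))
  out2 <- ppi_hubs(dup, c("A", "B"), cfg)
  expect_equal(out2$degree, c(1L, 1L))
  # random instances vs brute-force degree count
  set.seed(83)
  for (rep in 1:5) {
    nodes <- sprintf("n%02d", 1:30)
    e <- unique(data.frame(a = sample(nodes, 80L, replace = TRUE),
                           b = sample(nodes, 80L, replace = TRUE)))
    got <- ppi_hubs(e, nodes, cfg)
    e2 <- e[e$a != e$b, ]
    key <- ifelse(e2$a < e2$b, paste(e2$a, e2$b), paste(e2$b, e2$a))
    e2 <- e2[!duplicated(key), ]
    deg <- table(factor(c(e2$a, e2$b), levels = nodes))
    deg <- sort(deg[deg > 0], decreasing = TRUE)
    cutoff <- sort(as.integer(deg), decreasing = TRUE)[
      min(10L, length(deg))]
    want_ids <- names(deg)[deg >= cutoff]
    expect_setequal(got$gene_id, want_ids)
    expect_equal(got$degree,
                 as.integer(deg[got$gene_id]), ignore_attr = TRUE)
    # igraph agreement when available
    if (requireNamespace("igraph", quietly = TRUE)) {
      g <- igraph::simplify(igraph::graph_from_data_frame(e2,
                                                          directed = FALSE))
      ideg <- igraph::degree(g)
      expect_equal(got$degree, unname(ideg[got$gene_id]))
    }
  }
  # ties at the cutoff are all reported and flagged
  tie <- data.frame(a = rep(paste0("h", 1:12), each = 2L),
                    b = paste0("x", 1:24))
  out3 <- ppi_hubs(tie, unique(c(tie$a, tie$b)), cfg)
  expect_equal(sum(out3$degree == 2L), 12L)
  expect_true(all(out3$tie_at_cutoff[out3$degree == 2L]))
})

test_that("direction_consistency tabulates the canonical ceRNA pattern", {
  tri <- data.frame(lncrna_id = c("l1", "l2", "l3"),
                    mirna_id = c("m1", "m2", "m3"),
                    mrna_id = c("g1", "g2", "g3"))
  lm <- data.frame(lncrna_id = tri$lncrna_id, mirna_id = tri$mirna_id)
  mt <- data.frame(mirna_id = tri$mirna_id, target_id = tri$mrna_id)
  lt <- data.frame(lncrna_id = tri$lncrna_id, gene_id = tri$mrna_id,
                   mode = "cis")
  dirs <- c(l1 = "up", m1 = "down", g1 = "up",     # consistent
            l2 = "up", m2 = "up", g2 = "up",       # inconsistent
            l3 = "down", m3 = "up", g3 = "down")   # consistent
  net <- assemble_network(tri, lm, mt, lt, dirs)
  rep <- direction_consistency(net)
  expect_equal(rep$consistent, c(TRUE, FALSE, TRUE))
  expect_equal(attr(rep, "counts"),
               c(consistent = 2L, inconsistent = 1L))
})
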