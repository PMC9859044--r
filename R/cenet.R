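# ceRNA network assembly: triangle extraction over the three pair types,
# tripartite graph construction, PPI degree hub ranking and an optional
# direction-consistency diagnostic.

#' Extract ceRNA triangles
#'
#' For every retained (DEL, DEM) pair, emits one triangle per gene in the
#' intersection of the DEL's and the DEM's DE target-gene sets; genes
#' targeted by only one of the two are removed from that pair's context.
#'
#' @param lnc_mir_pairs data.frame with `lncrna_id`, `mirna_id`.
#' @param mir_targets data.frame with `mirna_id`, `target_id`.
#' @param lnc_targets data.frame with `lncrna_id`, `gene_id`.
#' @return data.frame `lncrna_id`, `mirna_id`, `mrna_id`, sorted.
#' @export
extract_triangles <- function(lnc_mir_pairs, mir_targets, lnc_targets) {
  empty <- data.frame(lncrna_id = character(), mirna_id = character(),
                      mrna_id = character(), stringsAsFactors = FALSE)
  if (nrow(lnc_mir_pairs) == 0L) return(empty)
  mt <- split(mir_targets$target_id, mir_targets$mirna_id)
  lt <- split(lnc_targets$gene_id, lnc_targets$lncrna_id)
  out <- list()
  for (i in seq_len(nrow(lnc_mir_pairs))) {
    l <- lnc_mir_pairs$lncrna_id[i]
    m <- lnc_mir_pairs$mirna_id[i]
    shared <- intersect(lt[[l]], mt[[m]])
    if (length(shared)) {
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = l, mirna_id = m, mrna_id = shared,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- unique(do.call(rbind, out))
  res <- res[order(res$lncrna_id, res$mirna_id, res$mrna_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble the tripartite ceRNA network
#'
#' Nodes are the features of the retained relationships, annotated with DE
#' direction; edges are typed (lnc-mir, mir-mrna, lnc-mrna), de-duplicated
#' with merged evidence. By default only relationships participating in at
#' least one triangle are kept; `pairs_only = TRUE` keeps all pairs even
#' without triangles.
#'
#' @param triangles an [extract_triangles()] result.
#' @param lnc_mir_pairs,mir_targets,lnc_targets the three pair lists;
#'   `lnc_targets` may carry a `mode` column used as edge evidence.
#' @param directions named character vector feature id -> "up"/"down".
#' @param pairs_only keep all pairs as edges when there are no triangles.
#' @return a `cerna_network`: list with `nodes`, `edges`, `triangles`.
#' @export
assemble_network <- function(triangles, lnc_mir_pairs, mir_targets,
                             lnc_targets, directions,
                             pairs_only = FALSE) {
  in_tri <- function(kind, a, b) {
    switch(kind,
      lnc_mir = paste(a, b) %in% paste(triangles$lncrna_id,
                                       triangles$mirna_id),
      mir_mrna = paste(a, b) %in% paste(triangles$mirna_id,
                                        triangles$mrna_id),
      lnc_mrna = paste(a, b) %in% paste(triangles$lncrna_id,
                                        triangles$mrna_id))
  }
  e1 <- data.frame(from = lnc_mir_pairs$lncrna_id,
                   to = lnc_mir_pairs$mirna_id, relation = "lnc-mir",
                   evidence = "seed_site", stringsAsFactors = FALSE)
  e2 <- data.frame(from = mir_targets$mirna_id,
                   to = mir_targets$target_id, relation = "mir-mrna",
                   evidence = "seed_site", stringsAsFactors = FALSE)
  e3 <- data.frame(from = lnc_targets$lncrna_id,
                   to = lnc_targets$gene_id, relation = "lnc-mrna",
                   evidence = if (!is.null(lnc_targets$mode))
                     lnc_targets$mode else "cis_or_trans",
                   stringsAsFactors = FALSE)
  if (!pairs_only) {
    e1 <- e1[in_tri("lnc_mir", e1$from, e1$to), , drop = FALSE]
    e2 <- e2[in_tri("mir_mrna", e2$from, e2$to), , drop = FALSE]
    e3 <- e3[in_tri("lnc_mrna", e3$from, e3$to), , drop = FALSE]
  }
  edges <- rbind(e1, e2, e3)
  # de-duplicate, merging evidence strings
  key <- paste(edges$from, edges$to, edges$relation, sep = "\r")
  ev <- tapply(edges$evidence, key, function(x) {
    paste(sort(unique(unlist(strsplit(x, ",", fixed = TRUE)))),
          collapse = ",")
  })
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges$evidence <- unname(ev[paste(edges$from, edges$to, edges$relation,
                                    sep = "\r")])
  edges <- edges[order(edges$relation, edges$from, edges$to), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  kind_of <- c(setNames(rep("lncrna", nrow(e1)), e1$from),
               setNames(rep("mirna", nrow(e1)), e1$to),
               setNames(rep("mirna", nrow(e2)), e2$from),
               setNames(rep("mrna", nrow(e2)), e2$to),
               setNames(rep("lncrna", nrow(e3)), e3$from),
               setNames(rep("mrna", nrow(e3)), e3$to))
  ids <- unique(c(edges$from, edges$to))
  nodes <- data.frame(
    id = ids, kind = unname(kind_of[ids]),
    de_direction = unname(directions[ids]),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, triangles = triangles),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  k <- table(factor(x$nodes$kind, levels = c("lncrna", "mirna", "mrna")))
  cat(sprintf(
    "cerna_network: %d lncRNA, %d miRNA, %d mRNA nodes; %d edges; %d triangles\n",
    k[["lncrna"]], k[["mirna"]], k[["mrna"]], nrow(x$edges),
    nrow(x$triangles)))
  invisible(x)
}

#' Write / read a ceRNA network as TSV (SIF-compatible edges)
#' @param net a `cerna_network`.
#' @param dir output directory.
#' @return `dir` invisibly; `read_network` returns the network.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(net$nodes, file.path(dir, "nodes.tsv"), sep = "\t")
  data.table::fwrite(net$edges[, c("from", "relation", "to", "evidence")],
                     file.path(dir, "edges.tsv"), sep = "\t")
  data.table::fwrite(net$triangles, file.path(dir, "triangles.tsv"),
                     sep = "\t")
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  nodes <- as.data.frame(data.table::fread(
    file.path(dir, "nodes.tsv"), sep = "\t", colClasses = "character"))
  edges <- as.data.frame(data.table::fread(
    file.path(dir, "edges.tsv"), sep = "\t", colClasses = "character"))
  edges <- edges[, c("from", "to", "relation", "evidence")]
  triangles <- as.data.frame(data.table::fread(
    file.path(dir, "triangles.tsv"), sep = "\t",
    colClasses = "character"))
  structure(list(nodes = nodes, edges = edges, triangles = triangles),
            class = "cerna_network")
}

#' PPI hub ranking by degree
#'
#' Restricts an undirected edge list to a gene universe, removes
#' self-loops and duplicate edges, counts degree per node and returns the
#' top-`hub_top_n` genes; ties at the cutoff are all reported and flagged.
#' Secondary order is lexicographic for determinism.
#'
#' @param edge_list data.frame with columns `a`, `b`.
#' @param gene_universe restrict nodes (and their edges) to these ids.
#' @param config a [pipeline_config()].
#' @return data.frame `gene_id`, `degree`, `rank`, `tie_at_cutoff`.
#' @export
ppi_hubs <- function(edge_list, gene_universe,
                     config = pipeline_config()) {
  e <- edge_list[edge_list$a %in% gene_universe &
                 edge_list$b %in% gene_universe &
                 edge_list$a != edge_list$b, c("a", "b"), drop = FALSE]
  if (nrow(e)) {
    key <- ifelse(e$a < e$b, paste(e$a, e$b, sep = "\r"),
                  paste(e$b, e$a, sep = "\r"))
    e <- e[!duplicated(key), , drop = FALSE]
  }
  deg <- table(c(e$a, e$b))
  if (length(deg) == 0L) {
    return(data.frame(gene_id = character(), degree = integer(),
                      rank = integer(), tie_at_cutoff = logical(),
                      stringsAsFactors = FALSE))
  }
  d <- data.frame(gene_id = names(deg), degree = as.integer(deg),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$degree, d$gene_id), , drop = FALSE]
  d$rank <- rank(-d$degree, ties.method = "min")
  n <- config$hub_top_n
  if (nrow(d) > n) {
    cutoff <- d$degree[n]
    keep <- d$degree >= cutoff
    d <- d[keep, , drop = FALSE]
    d$tie_at_cutoff <- d$degree == cutoff & sum(d$degree >= cutoff) > n
  } else {
    d$tie_at_cutoff <- FALSE
  }
  rownames(d) <- NULL
  d
}

#' Direction-consistency diagnostic for ceRNA triangles
#'
#' Flags, per triangle, whether the lncRNA and mRNA share DE direction
#' while the miRNA is opposite (the canonical ceRNA expectation). Reporting
#' only; no triangles are filtered.
#'
#' @param network a `cerna_network`.
#' @return data.frame of triangles with their three directions and
#'   `consistent`, plus attribute `counts` (consistent / inconsistent).
#' @export
direction_consistency <- function(network) {
  dirs <- setNames(network$nodes$de_direction, network$nodes$id)
  tr <- network$triangles
  out <- data.frame(
    tr,
    lnc_dir = unname(dirs[tr$lncrna_id]),
    mir_dir = unname(dirs[tr$mirna_id]),
    mrna_dir = unname(dirs[tr$mrna_id]),
    stringsAsFactors = FALSE)
  out$consistent <- out$lnc_dir == out$mrna_dir &
    out$mir_dir != out$mrna_dir
  attr(out, "counts") <- c(consistent = sum(out$consistent, na.rm = TRUE),
                           inconsistent = sum(!out$consistent,
                                              na.rm = TRUE))
  out
}
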