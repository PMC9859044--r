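# End-to-end orchestration: identification -> DE screens -> target
# prediction -> ceRNA network -> enrichment, with a JSON run manifest.

#' Read pipeline inputs from a directory
#'
#' Expects the file layout produced by [write_simulation()]: `genes.gtf`,
#' `lnc_candidates.gtf`, `lnc_candidates.fa`, `mirnas.fa`, `utr3.fa`,
#' `counts_genes.tsv`, `counts_mirnas.tsv`, `counts_lnc.tsv`,
#' `design.tsv`, `ppi_edges.tsv`, `gene_sets.gmt`.
#'
#' @param dir input directory.
#' @return list of parsed inputs.
#' @export
read_pipeline_inputs <- function(dir) {
  p <- function(f) file.path(dir, f)
  gene_models <- read_gtf(p("genes.gtf"))
  list(
    gene_models = gene_models,
    gene_spans = feature_spans(gene_models, "gene_id"),
    lnc_models = read_gtf(p("lnc_candidates.gtf")),
    lnc_seqs = read_fasta(p("lnc_candidates.fa"), "transcript"),
    mirna_seqs = read_fasta(p("mirnas.fa"), "mirna_mature"),
    utrs = read_fasta(p("utr3.fa"), "utr3"),
    gene_counts = read_counts(p("counts_genes.tsv"), p("design.tsv")),
    mirna_counts = read_counts(p("counts_mirnas.tsv"), p("design.tsv")),
    lnc_counts = read_counts(p("counts_lnc.tsv"), p("design.tsv")),
    ppi_edges = read_edge_list(p("ppi_edges.tsv")),
    gene_sets = read_gmt(p("gene_sets.gmt"))
  )
}

#' Run the full analysis end-to-end
#'
#' Stages, in order: lncRNA identification cascade; differential-expression
#' screens for mRNA, miRNA and identified lncRNA; miRNA target prediction
#' (seed scan restricted to DE genes) and DEL-borne miRNA sites; lncRNA
#' cis/trans target inference restricted to DE genes; ceRNA triangle
#' extraction and network assembly with PPI hub ranking; gene-set
#' enrichment of the DE potential target genes. All stage outputs are
#' written as TSV under `out_dir` together with a JSON manifest.
#'
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param input_dir optional directory of existing inputs (layout of
#'   [write_simulation()]); when NULL, inputs are simulated from `params`
#'   and written under `out_dir/inputs`.
#' @param params a [simulation_params()] used when simulating (its seed
#'   defaults to `config$rng_seed`).
#' @param numerator_group fold-change numerator group label.
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_all <- function(out_dir, config = pipeline_config(),
                    input_dir = NULL,
                    params = simulation_params(seed = config$rng_seed),
                    numerator_group = "SL") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_counts <- list()
  if (is.null(input_dir)) {
    sim <- simulate_all(params)
    input_dir <- file.path(out_dir, "inputs")
    write_simulation(sim, input_dir)
  }
  inputs <- read_pipeline_inputs(input_dir)
  pth <- function(f) file.path(out_dir, f)

  # --- stage 1: lncRNA identification -----------------------------------
  lnc_audit <- run_lnc_pipeline(inputs$lnc_models, inputs$lnc_seqs,
                                inputs$lnc_counts, config = config)
  data.table::fwrite(lnc_audit, pth("lnc_identification.tsv"), sep = "\t")
  lnc_ids <- lnc_audit$transcript_id[lnc_audit$final]
  stage_counts$lnc_candidates <- nrow(lnc_audit)
  stage_counts$lnc_identified <- length(lnc_ids)

  # --- stage 2: differential expression ---------------------------------
  de_genes <- screen_de(inputs$gene_counts, config, numerator_group)
  de_mirnas <- screen_de(inputs$mirna_counts, config, numerator_group)
  lnc_counts_id <- expression_matrix(
    inputs$lnc_counts$values[lnc_ids, , drop = FALSE],
    inputs$lnc_counts$design, unit = "count")
  de_lncs <- screen_de(lnc_counts_id, config, numerator_group)
  data.table::fwrite(de_genes, pth("de_genes.tsv"), sep = "\t")
  data.table::fwrite(de_mirnas, pth("de_mirnas.tsv"), sep = "\t")
  data.table::fwrite(de_lncs, pth("de_lncs.tsv"), sep = "\t")
  degs <- de_features(de_genes)
  dems <- de_features(de_mirnas)
  dels <- de_features(de_lncs)
  stage_counts$degs <- length(degs)
  stage_counts$degs_up <- sum(de_genes$call == "up")
  stage_counts$degs_down <- sum(de_genes$call == "down")
  stage_counts$dems <- length(dems)
  stage_counts$dels <- length(dels)

  # --- stage 3: miRNA targets -------------------------------------------
  sites <- scan_seed_sites(inputs$mirna_seqs[dems], inputs$utrs, "utr3")
  seed_pairs <- sites_to_pairs(sites)
  mir_targets <- intersect_sources(list(seed_scan = seed_pairs), degs)
  data.table::fwrite(mir_targets, pth("mir_targets.tsv"), sep = "\t")
  lnc_mir <- lnc_mirna_targets(inputs$mirna_seqs,
                               inputs$lnc_seqs[dels], dems)
  data.table::fwrite(lnc_mir, pth("lnc_mir_pairs.tsv"), sep = "\t")
  stage_counts$mir_target_pairs <- nrow(mir_targets)
  stage_counts$lnc_mir_pairs <- nrow(lnc_mir)

  # --- stage 4: lncRNA targets ------------------------------------------
  del_models <- inputs$lnc_models[
    inputs$lnc_models$transcript_id %in% dels, , drop = FALSE]
  cis <- cis_targets(feature_spans(del_models), inputs$gene_spans, config)
  lnc_lengths <- setNames(inputs$lnc_models$spliced_length,
                          inputs$lnc_models$transcript_id)
  gene_lengths <- setNames(
    inputs$gene_spans$end - inputs$gene_spans$start + 1L,
    inputs$gene_spans$id)
  lnc_fpkm <- fpkm(inputs$lnc_counts, lnc_lengths)
  gene_fpkm <- fpkm(inputs$gene_counts, gene_lengths)
  trans <- trans_targets(
    lnc_fpkm$values[intersect(dels, rownames(lnc_fpkm$values)), ,
                    drop = FALSE],
    gene_fpkm$values[intersect(degs, rownames(gene_fpkm$values)), ,
                     drop = FALSE],
    config)
  lnc_targets <- merge_lnc_targets(cis, trans, degs)
  data.table::fwrite(cis, pth("cis_pairs.tsv"), sep = "\t")
  data.table::fwrite(trans, pth("trans_pairs.tsv"), sep = "\t")
  data.table::fwrite(lnc_targets, pth("lnc_targets.tsv"), sep = "\t")
  stage_counts$cis_pairs <- nrow(cis)
  stage_counts$trans_pairs <- nrow(trans)
  stage_counts$lnc_target_pairs <- nrow(lnc_targets)

  # --- stage 5: ceRNA network -------------------------------------------
  lnc_mir_pairs <- unique(lnc_mir[, c("lncrna_id", "mirna_id")])
  triangles <- extract_triangles(lnc_mir_pairs, mir_targets, lnc_targets)
  directions <- c(setNames(de_genes$call, de_genes$feature_id),
                  setNames(de_mirnas$call, de_mirnas$feature_id),
                  setNames(de_lncs$call, de_lncs$feature_id))
  directions <- directions[directions != "ns"]
  network <- assemble_network(triangles, lnc_mir_pairs, mir_targets,
                              lnc_targets, directions)
  write_network(network, file.path(out_dir, "network"))
  deptgs <- union(mir_targets$target_id, lnc_targets$gene_id)
  hubs <- ppi_hubs(inputs$ppi_edges, deptgs, config)
  data.table::fwrite(hubs, pth("ppi_hubs.tsv"), sep = "\t")
  stage_counts$triangles <- nrow(triangles)
  stage_counts$deptgs <- length(deptgs)
  stage_counts$hubs <- nrow(hubs)

  # --- stage 6: enrichment ----------------------------------------------
  background <- rownames(inputs$gene_counts$values)
  enr <- if (length(deptgs)) {
    hypergeom_enrich(intersect(deptgs, background), inputs$gene_sets,
                     background, config)
  } else NULL
  if (!is.null(enr)) {
    format_enrichment(enr, significant_only = FALSE,
                      path = pth("enrichment.tsv"))
    stage_counts$enriched_sets <- sum(enr$significant)
  } else {
    stage_counts$enriched_sets <- 0L
  }

  manifest <- list(
    config = unclass(config),
    seed = config$rng_seed,
    input_dir = normalizePath(input_dir),
    input_hashes = {
      h <- tools::md5sum(list.files(input_dir, full.names = TRUE))
      as.list(setNames(h, basename(names(h))))
    },
    stage_counts = stage_counts,
    outputs = list.files(out_dir, recursive = TRUE),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(report(manifest), pth("report.txt"))
  invisible(manifest)
}

#' Human-readable summary of a run manifest
#'
#' @param manifest a [run_all()] manifest (or path to `manifest.json`).
#' @return character vector of report lines.
#' @export
report <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  sc <- manifest$stage_counts
  g <- function(x) if (is.null(sc[[x]])) 0L else sc[[x]]
  c("cernanet run summary",
    sprintf("seed: %s", manifest$seed),
    sprintf("lncRNA identification: %d candidates -> %d identified",
            g("lnc_candidates"), g("lnc_identified")),
    sprintf("differential expression: %d DEGs (%d up / %d down), %d DEMs, %d DELs",
            g("degs"), g("degs_up"), g("degs_down"), g("dems"), g("dels")),
    sprintf("miRNA targets: %d DEM-DEG pairs; DEL-borne miRNA sites: %d pairs",
            g("mir_target_pairs"), g("lnc_mir_pairs")),
    sprintf("lncRNA targets: %d cis pairs, %d trans pairs, %d DE target-gene pairs",
            g("cis_pairs"), g("trans_pairs"), g("lnc_target_pairs")),
    sprintf("ceRNA network: %d triangles over %d DEPTGs; %d hub genes",
            g("triangles"), g("deptgs"), g("hubs")),
    sprintf("enrichment: %d significant gene sets", g("enriched_sets")))
}
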