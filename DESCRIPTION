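Package: cernanet
Title: lncRNA Identification, Differential Expression and ceRNA Network
    Assembly for Two-Group RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative transcriptomics toolkit for two-group bulk
    RNA-seq designs. Identifies long non-coding RNAs from assembled
    transcript models through a staged cascade (class-code and structural
    filters, coding-potential consensus over Fickett TESTCODE, hexamer
    usage and an ORF-based logistic score, protein-domain exclusion and
    an FPKM expression floor), screens differentially expressed mRNA,
    miRNA and lncRNA with a negative-binomial exact test under TMM
    normalization and Benjamini-Hochberg FDR control, predicts miRNA
    targets by canonical seed matching (8mer, 7mer-m8, 7mer-A1, 6mer),
    infers lncRNA targets in cis (genomic windows) and in trans
    (Spearman correlation), extracts competing-endogenous-RNA
    lncRNA-miRNA-mRNA triangles into a tripartite network with PPI
    degree hub ranking and hypergeometric gene-set enrichment. A
    synthetic-data module plants every structure the analysis assumes so
    the whole pipeline can be exercised end-to-end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer,
    igraph
Config/testthat/edition: 3
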