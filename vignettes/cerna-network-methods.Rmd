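---
title: "Methods: lncRNA identification, NB differential expression and ceRNA network assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA identification, NB differential expression and ceRNA network assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernanet)
```

# The analysis and its assumptions

`cernanet` implements the integrative analysis used in two-group livestock
transcriptomics: identify lncRNAs among assembled transcripts, screen
mRNA/miRNA/lncRNA for differential expression between the groups, predict
miRNA and lncRNA targets, and assemble the competing-endogenous-RNA
(ceRNA) triangles — lncRNA and mRNA sharing a miRNA that targets both —
into a tripartite network with hub-gene ranking and gene-set enrichment.

The design assumptions baked into the defaults:

* **Two groups of exchangeable biological replicates** (default n = 6 + 6,
  the usual scale of such slaughter experiments). No batch terms, no
  covariates: the exact test conditions on group totals only.
* **Counts are negative binomial** with the edgeR-style parameterization
  Var = μ + φμ². A single pooled (common) dispersion is shared across
  features; tagwise/trended dispersion is deliberately out of scope.
* **Correlation is computed across all samples pooled over groups.** The
  published worked values this package reconstructs (the four labelled
  ρ → p rows at n = 12) are consistent with a Student-t approximation at
  df = 10, i.e. pooled samples and no group regression — so that is the
  default, verified in `test-acceptance.R`.

# Parameters that matter

All thresholds live in one object, `pipeline_config()`:

| field | default | meaning |
|---|---|---|
| `fdr_threshold`, `abs_fc_threshold` | 0.05, 2 | DE call: BH FDR < 0.05 and |fold change| ≥ 2 |
| `class_codes_kept` | i, u, x | intronic / intergenic / antisense assembler codes retained |
| `min_exons`, `min_tx_length` | 2, 201 nt | structural lncRNA filter (length strictly > 200) |
| `fpkm_floor` | 0.1 | FPKM required in ≥ 1 sample (inclusive) |
| `domain_evalue_max` | 1e-5 | protein-domain hit exclusion |
| `cis_window_bp` | 100,000 | cis window up- and downstream, inclusive |
| `trans_abs_rho_min`, `trans_p_max` | 0.8, 0.05 | trans rule, strict on the rho bound |
| `enrich_p_max` | 0.05 | raw enrichment significance |
| `hub_top_n` | 10 | PPI degree ranking cutoff, ties kept |

Decisions worth spelling out:

* **"Exceeded 0.8" is strict** (`|rho| > 0.8`). The worked table rows
  support this: a pair at ρ = 0.777584 with p = 0.00291 is *not* among
  the retained trans relationships, so the rho bound — not the p-value —
  is the binding constraint, and 0.8 itself must not pass.
* **Distances are between genomic spans**, TSS-agnostic, strand ignored,
  with overlap reported as distance 0 ("coincide"), matching
  window-search semantics of interval tools; the boundary is inclusive
  (exactly 100,000 bp is cis; 100,001 is not).
* **The DE call orientation** takes the first group (or
  `numerator_group`) as fold-change numerator; the log2 fold change uses
  normalized group means with pseudocount 0.5 (the source analyses are
  silent here; 0.5 is the common convention and avoids 0/0).
* **All-zero features are excluded before testing**, so they do not
  inflate the BH denominator.
* **Enrichment is uncorrected by default** (raw p < 0.05), mirroring the
  screening convention this analysis family uses; `bh = TRUE` adds an FDR
  column for users who want rigor over fidelity.

# Coding-potential consensus

External predictors (CPC2/CNCI/CPAT/PLEK-class tools) are not
reimplemented as trained models. The package provides three in-repo
scores — Fickett TESTCODE (classic lookup/weight tables; coding cutoff
0.95), an in-frame hexamer usage log-likelihood ratio (cutoff 0; the
frame is that of the longest ORF when one exists), and a logistic model
on ORF length, ORF coverage, Fickett and hexamer scores (cutoff 0.5) —
and accepts external verdict tables, all intersected identically: a
transcript is noncoding only if **every** enabled source says noncoding
and no protein-domain hit falls below the E-value bound. The logistic
model's frozen default coefficients were calibrated once on the
simulator's stated composition (biased-codon ORFs ≥ 300 nt vs uniform
sequences with ORFs < 150 nt); `train_coding_model()` refits them for
other worlds. Hexamer tables are likewise trained at run time from a
seed-derived reference simulation rather than shipped as data.

# What the simulator states, and what a green test does not establish

`simulation_params()` *is* the stated world: n = 6 + 6 replicates;
NB counts with φ = 0.1 and a log-normal baseline with median 200; 10% of
features differentially expressed at |log2FC| = 2 (4-fold, comfortably
past the ≥ 2-fold rule); coding transcripts with biased-codon ORFs
≥ 300 nt vs noncoding transcripts of uniform composition and ORFs
< 150 nt, with exon counts, lengths and class codes spanning both sides
of every structural filter; canonical seed sites written at recorded
positions into rejection-scrubbed backgrounds (scrubbing resamples each
offending 6mer window — whole-sequence resampling cannot converge for
kb-scale sequences against dozens of miRNA cores); cis partners placed
1–90 kb from their gene on a 1 Mb gene grid, non-cis lncRNAs ≥ several
hundred kb from any gene; trans pairs planted by a Gaussian copula on
ranks whose Pearson parameter is chosen by inverting the exact
finite-n bivariate-normal expectation of the *sample* Spearman
coefficient (the asymptotic 2·sin(πρ/6) under-shoots visibly at n = 12).
Copula planting permutes a gene's existing counts, so its marginal
distribution — and hence its DE status when paired DE-concordantly — is
untouched.

What the simulator does **not** emulate: within-group expression
heterogeneity (replicates are exchangeable), read-level artifacts
(alignment, positional bias, library prep), overdispersion trends in μ,
isoform structure in coding genes, miRNA site context (the scanner is
presence/absence, as is the intersection logic it feeds), and real
genome geometry. A green recovery test therefore establishes that the
pipeline's logic is faithful to its stated rules, not that those rules
have power on any particular real dataset; in particular the published
headline counts (hundreds of DEGs from > 10⁶ assembled transcripts)
depend on raw sequencing data that is not publicly deposited and are not
reproduction targets at desk scale.

# Numerical choices and degenerate inputs

* NB exact test: counts are scaled to the common effective library size
  (TMM-adjusted) and rounded; group sums of iid NB(μ, φ) are NB with
  size n_g/φ; p doubles the smaller conditional tail, capped at 1; a
  zero total gives p = 1; φ below 1e-10 falls back to the Poisson
  (conditional binomial) limit. Dispersion is floored at 1e-6.
* BH: step-up with ties sharing the maximal rank; verified against a
  double-loop oracle for every m ≤ 50.
* Spearman: mid-ranks (average ties), Pearson on ranks; |ρ| = 1 returns
  p = 0 flagged `exact`; ρ = 0 returns p = 1.
* Seed scan: overlapping core matches are all found (lookahead scan) and
  each reported at its maximal type; windows containing N are skipped.
* Hub ranking: ties at rank `hub_top_n` are all reported and flagged;
  secondary order is lexicographic, so output is deterministic.
* TMM: two-sided 30%/5% trims on M and A with inverse-variance weights;
  an all-trimmed sample falls back to factor 1 with a warning; factors
  are rescaled to geometric mean 1.

# Known limitations

Common dispersion only; no GLM designs; no thermodynamic or
conservation-aware target scoring; no GO-graph propagation in
enrichment; the external predictors and databases (Pfam scans, STRING,
target databases) are ingested as files, never queried. The
`direction_consistency()` diagnostic (lncRNA and mRNA co-directional,
miRNA opposite) is reported but never filtered on, since the upstream
analysis convention plots directions without stating a filter.
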