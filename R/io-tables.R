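#' Expression matrix container
#'
#' Features x samples matrix of non-negative counts or FPKM, with a sample
#' design (group labels). Two groups are required only at
#' differential-expression time; storage accepts any design.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   dimnames.
#' @param design named character vector mapping sample id -> group label.
#' @param unit "count" or "fpkm".
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, design, unit = c("count", "fpkm")) {
  unit <- match.arg(unit)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0)) stop("expression values must be non-negative")
  missing <- setdiff(colnames(values), names(design))
  if (length(missing)) {
    stop("samples missing from design: ", paste(missing, collapse = ", "))
  }
  design <- design[colnames(values)]
  if (unit == "count") {
    storage.mode(values) <- "integer"
  }
  structure(list(values = values, design = design, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat("groups:", paste(sprintf("%s(n=%d)", names(table(x$design)),
                               table(x$design)), collapse = " "), "\n")
  invisible(x)
}

#' Read a count matrix and its sample design
#'
#' The matrix is a TSV whose header holds sample ids and whose first column
#' holds feature ids; the design TSV has columns `sample` and `group`.
#' Values are coerced to integer counts (rounding is an error: counts must
#' already be whole numbers).
#'
#' @param path count matrix TSV.
#' @param design_path design TSV.
#' @return An `expression_matrix` with `unit = "count"`.
#' @export
read_counts <- function(path, design_path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2L) stop("count matrix needs a feature column and samples")
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  }
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric values in count matrix")
  if (any(vals < 0)) stop("negative value in count matrix")
  if (any(vals != round(vals))) stop("non-integer value in count matrix")
  rownames(vals) <- ids
  design <- read_design(design_path)
  expression_matrix(vals, design, unit = "count")
}

#' Read a sample design table (columns `sample`, `group`)
#' @param path design TSV.
#' @return named character vector sample -> group.
#' @export
read_design <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t",
                  colClasses = "character")
  if (!all(c("sample", "group") %in% names(d))) {
    stop("design table must have 'sample' and 'group' columns")
  }
  if (anyDuplicated(d$sample)) stop("duplicate sample in design")
  setNames(d$group, d$sample)
}

#' Write a count/FPKM matrix and design to TSV
#' @param x an `expression_matrix`.
#' @param path matrix TSV path.
#' @param design_path optional design TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, design_path = NULL) {
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  if (!is.null(design_path)) {
    data.table::fwrite(data.frame(sample = names(x$design),
                                  group = unname(x$design)),
                       design_path, sep = "\t")
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: id, description/name, then member gene ids. Members
#' are de-duplicated within a set; empty sets are rejected.
#'
#' @param path GMT file.
#' @return A `gene_sets` object: named list of member vectors with a
#'   `set_names` attribute (set id -> display name).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set id in GMT")
  nms <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", "")
  members <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    mem <- unique(p[-(1:2)][nzchar(p[-(1:2)])])
    if (length(mem) == 0L) stop("empty gene set in GMT: ", ids[i])
    mem
  })
  structure(setNames(members, ids), set_names = setNames(nms, ids),
            class = "gene_sets")
}

#' Write gene sets to GMT
#' @param sets a `gene_sets` object or named list of member vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  nms <- attr(sets, "set_names")
  if (is.null(nms)) nms <- setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(id) {
    paste(c(id, nms[[id]], sets[[id]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read an undirected edge list (e.g. a STRING export)
#'
#' Two or more tab-separated columns; the first two are node ids, an
#' optional third numeric column is kept as `score`. Self-loops are dropped
#' with a message.
#'
#' @param path edge list TSV (a header line is auto-detected by non-numeric
#'   third column named/valued).
#' @param header whether the file has a header line.
#' @return data.frame with columns `a`, `b` (and `score` when present).
#' @export
read_edge_list <- function(path, header = FALSE) {
  d <- read.delim(path, header = header, sep = "\t",
                  stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("edge list needs at least 2 columns")
  out <- data.frame(a = as.character(d[[1L]]), b = as.character(d[[2L]]),
                    stringsAsFactors = FALSE)
  if (ncol(d) >= 3L && is.numeric(d[[3L]])) out$score <- d[[3L]]
  loops <- out$a == out$b
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop edge(s)")
    out <- out[!loops, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write an edge list to TSV
#' @param edges data.frame with columns `a`, `b` (optionally `score`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  data.table::fwrite(edges, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a protein-domain hit table
#'
#' Expected columns: `transcript_id`, `evalue` (e.g. exported hmmer hits
#' against Pfam). Non-numeric E-values are rejected.
#'
#' @param path TSV with a header.
#' @return data.frame with `transcript_id`, `evalue`.
#' @export
read_domain_hits <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "evalue") %in% names(d))) {
    stop("domain hit table must have 'transcript_id' and 'evalue' columns")
  }
  ev <- suppressWarnings(as.numeric(d$evalue))
  if (anyNA(ev)) stop("non-numeric E-value in domain hit table")
  data.frame(transcript_id = as.character(d$transcript_id), evalue = ev,
             stringsAsFactors = FALSE)
}

#' Read an external coding-potential verdict table
#'
#' Expected columns: `transcript_id`, `source`, `call` in
#' {coding, noncoding}. Used to plug external predictor outputs (CPC2,
#' CNCI, CPAT, PLEK style) into the consensus.
#'
#' @param path TSV with a header.
#' @return data.frame with `transcript_id`, `source`, `call`.
#' @export
read_verdicts <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("transcript_id", "source", "call")
  if (!all(need %in% names(d))) {
    stop("verdict table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(d$call %in% c("coding", "noncoding"))) {
    stop("verdict call must be 'coding' or 'noncoding'")
  }
  d[, need]
}

#' Read an external (miRNA, target) prediction list
#' @param path TSV with a header containing `mirna_id` and `target_id`.
#' @return data.frame with `mirna_id`, `target_id`.
#' @export
read_target_list <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "target_id") %in% names(d))) {
    stop("target list must have 'mirna_id' and 'target_id' columns")
  }
  unique(d[, c("mirna_id", "target_id")])
}
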