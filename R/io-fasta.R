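#' Read sequences from a FASTA file
#'
#' Backed by Biostrings. Sequences are uppercased and RNA `U` is mapped to
#' `T` at ingest so one DNA alphabet serves both target scanning and
#' coding-potential scoring (miRBase mature files are RNA-alphabet). The
#' allowed alphabet after mapping is A/C/G/T/N.
#'
#' @param path FASTA file.
#' @param moltype what the sequences are: "transcript", "utr3" or
#'   "mirna_mature". Mature miRNAs must be 18-26 nt.
#' @return named character vector of sequences (DNA alphabet), in file
#'   order, with a `moltype` attribute.
#' @export
read_fasta <- function(path, moltype = c("transcript", "utr3",
                                         "mirna_mature")) {
  moltype <- match.arg(moltype)
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  seqs <- chartr("uU", "tT", as.character(ss))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence: ", ids[nchar(seqs) == 0L][1L])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence ", ids[bad][1L],
         " contains characters outside the A/C/G/T/U/N alphabet")
  }
  if (moltype == "mirna_mature") {
    n <- nchar(seqs)
    if (any(n < 18L | n > 26L)) {
      stop("mature miRNA length outside [18, 26]: ", ids[n < 18L | n > 26L][1L])
    }
  }
  structure(setNames(seqs, ids), moltype = moltype)
}

#' Write named sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
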