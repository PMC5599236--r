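#' @importFrom methods new validObject is slot
#' @importFrom stats cor rnorm rpois runif pnorm sd setNames
#' @importFrom utils write.table read.table combn
NULL

# Canonical internal alphabet is DNA (ACGT); U on input is mapped to T.

#' Normalise a nucleotide string to the internal DNA alphabet
#'
#' Upper-cases the sequence and maps U to T. Any residue outside ACGT(N)
#' raises an error.
#'
#' @param x character vector of sequences (or a \code{XStringSet}).
#' @param allowN allow ambiguous N residues (default FALSE).
#' @return character vector over the ACGT alphabet.
#' @export
normalizeSeq <- function(x, allowN = FALSE) {
  if (is(x, "XStringSet") || is(x, "XString")) x <- as.character(x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  ok <- if (allowN) grepl("^[ACGTN]*$", x) else grepl("^[ACGT]*$", x)
  if (!all(ok)) {
    bad <- x[!ok][1L]
    stop("sequence contains characters outside the ACGT/ACGU alphabet: ",
         substr(bad, 1L, 40L))
  }
  x
}

# reverse complement on plain character vectors
revComp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

# split a sequence string into a character vector of single bases
seqChars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Read transcript or miRNA sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} that accepts RNA
#' (U) input and returns sequences over the canonical DNA alphabet.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (ACGT alphabet).
#' @export
readSeqFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  out <- normalizeSeq(as.character(raw), allowN = TRUE)
  names(out) <- sub("\\s.*$", "", names(raw))
  out
}

# deterministic FASTA writer (60-column wrap, LF endings)
writeFasta <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

# deterministic TSV writer: LF, tab separator, no quoting
writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

readTsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# seed window / penalty defaults shared by scorer and scanner
duplexDefaults <- function() {
  list(mismatch = 1.0, wobble = 0.5, gap = 2.0,
       seed_window = c(2L, 13L), seed_factor = 2.0,
       max_bulge = 3L, cutoff = 3.0, central_window = c(9L, 12L))
}
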