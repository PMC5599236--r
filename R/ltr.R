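#' LTR divergence (p-distance)
#'
#' Proportion of differing positions among aligned non-gap columns. Equal
#' length inputs are compared column by column; unequal-length inputs are
#' first globally aligned (Needleman-Wunsch, match +1, mismatch -1, -2 per
#' gapped position). Columns containing a gap or an N are excluded from
#' both numerator and denominator. An optional Jukes-Cantor correction
#' D_JC = -(3/4) ln(1 - 4p/3) is applied behind a flag.
#'
#' @param seq_a,seq_b sequences (character or \code{DNAString}); may
#'   contain \code{-} if pre-aligned.
#' @param jc apply the Jukes-Cantor correction (default FALSE, matching
#'   the raw-divergence dating formula).
#' @return list with \code{D} (divergence) and \code{aligned_sites}
#'   (number of compared positions).
#' @export
ltrDivergence <- function(seq_a, seq_b, jc = FALSE) {
  norm <- function(x) {
    if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
    toupper(chartr("U", "T", x))
  }
  a <- norm(seq_a); b <- norm(seq_b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  if (nchar(a) != nchar(b)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 0, gapExtension = 2)
    a <- as.character(Biostrings::alignedPattern(al))
    b <- as.character(Biostrings::alignedSubject(al))
  }
  ca <- seqChars(a); cb <- seqChars(b)
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(keep)
  if (n == 0L) stop("alignment has no comparable (non-gap) columns")
  p <- sum(ca[keep] != cb[keep]) / n
  D <- p
  if (jc) {
    if (p >= 0.75)
      stop("Jukes-Cantor correction undefined for p-distance >= 0.75")
    D <- -0.75 * log(1 - 4 * p / 3)
  }
  list(D = D, aligned_sites = n)
}

#' LTR insertion age from divergence
#'
#' Molecular-clock dating of an LTR retrotransposon insertion. The two
#' LTRs of an element are identical at insertion, so for a paired
#' comparison each accumulates substitutions independently and
#' T = D/(2t). A solo LTR is dated against the family consensus, taken to
#' represent the youngest copy, giving T = D/t.
#'
#' @param D divergence in [0, 1] (p-distance, or Jukes-Cantor corrected).
#' @param rate substitution rate t per site per year (> 0); the rice rate
#'   1.3e-8 is the conventional default.
#' @param mode \code{"paired"} or \code{"solo"}.
#' @param aligned_sites number of compared positions (bookkeeping only).
#' @return an \linkS4class{LTRAgeEstimate}.
#' @examples
#' ageYears(estimateAge(0.0962, 1.3e-8, "paired")) / 1e6  # 3.7 Mya
#' @export
estimateAge <- function(D, rate = 1.3e-8, mode = c("paired", "solo"),
                        aligned_sites = NA_integer_) {
  mode <- match.arg(mode)
  if (rate <= 0) stop("substitution rate must be positive")
  if (D < 0 || D > 1) stop("divergence must lie in [0, 1]")
  age <- if (mode == "paired") D / (2 * rate) else D / rate
  new("LTRAgeEstimate", mode = mode, D = D, rate = rate, age = age,
      alignedSites = as.integer(aligned_sites))
}

#' Date an LTR insertion from sequences
#'
#' Convenience wrapper: computes divergence with
#' \code{\link{ltrDivergence}} then the age with
#' \code{\link{estimateAge}}.
#'
#' @inheritParams ltrDivergence
#' @inheritParams estimateAge
#' @return an \linkS4class{LTRAgeEstimate}.
#' @export
ltrAge <- function(seq_a, seq_b, rate = 1.3e-8,
                   mode = c("paired", "solo"), jc = FALSE) {
  dv <- ltrDivergence(seq_a, seq_b, jc = jc)
  estimateAge(dv$D, rate, mode, aligned_sites = dv$aligned_sites)
}

#' Majority-rule consensus of aligned LTR sequences
#'
#' Per-column majority base over aligned, equal-length sequences; ties are
#' broken by the fixed base order A < C < G < T, and columns whose strict
#' majority is a gap are dropped. Unaligned input must be aligned first
#' (e.g. with an external multiple aligner).
#'
#' @param sequences character vector (or \code{DNAStringSet}) of >= 2
#'   aligned sequences; \code{-} marks gaps.
#' @return consensus sequence (character).
#' @export
ltrConsensus <- function(sequences) {
  if (is(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  sequences <- toupper(chartr("U", "T", sequences))
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences must be aligned to equal length")
  mat <- do.call(rbind, lapply(sequences, seqChars))
  bases <- c("A", "C", "G", "T")
  cons <- apply(mat, 2L, function(col) {
    nGap <- sum(col == "-")
    cnt <- vapply(bases, function(b) sum(col == b), integer(1L))
    if (nGap > max(cnt)) return(NA_character_)    # gap-majority: drop
    bases[which.max(cnt)]                          # ties: A < C < G < T
  })
  paste(cons[!is.na(cons)], collapse = "")
}
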