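#' Length-corrected miRNA-binding-site density
#'
#' Sites per kilobase of transcript, the length correction used when
#' comparing site counts between transcript groups. Transcripts with no
#' sites are included with density 0.
#'
#' @param sites list of \linkS4class{TargetSite} or a
#'   \code{\link{sitesTable}} data.frame.
#' @param transcripts named character vector (or \code{DNAStringSet}) of
#'   the scanned transcripts; their lengths define the correction.
#' @return data.frame (transcript_id, n_sites, length, density).
#' @export
siteDensity <- function(sites, transcripts) {
  tab <- if (is.data.frame(sites)) sites else sitesTable(sites)
  lens <- nchar(normalizeSeq(transcripts, allowN = TRUE))
  if (any(lens == 0L)) stop("zero-length transcript")
  if (nrow(tab) && !all(tab$transcript_id %in% names(transcripts)))
    stop("site refers to a transcript not in the transcript set")
  n <- vapply(names(transcripts), function(id)
    sum(tab$transcript_id == id), integer(1L))
  data.frame(transcript_id = names(transcripts), n_sites = unname(n),
             length = unname(lens),
             density = unname(n / (lens / 1000)),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test (first principles)
#'
#' Two-sample rank-sum test on W, the rank sum of the first group, with
#' mid-ranks for ties. For small samples (n1 + n2 <= \code{exact_limit})
#' the null distribution of W is enumerated exactly over all
#' choose(n1+n2, n1) group assignments of the observed ranks; otherwise a
#' normal approximation with tie-corrected variance and a continuity
#' correction of 0.5 is used. Two-sided p doubles the smaller tail, capped
#' at 1.
#'
#' @param a,b numeric vectors (n >= 1 each).
#' @param exact_limit pooled-size bound for the exact branch (default 12).
#' @return list (n1, n2, W, z, p_two_sided, method = "exact"|"normal").
#' @export
rankSumTest <- function(a, b, exact_limit = 12L) {
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    stop("degenerate test: all values identical across both groups")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(pooled)  # mid-ranks for ties
  W <- sum(r[seq_len(n1)])
  if (n <= exact_limit) {
    sets <- combn(n, n1)
    sums <- colSums(matrix(r[sets], nrow = n1))
    pLo <- mean(sums <= W + 1e-9)
    pHi <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(pLo, pHi))
    return(list(n1 = n1, n2 = n2, W = W, z = NA_real_, p_two_sided = p,
                method = "exact"))
  }
  muW <- n1 * (n + 1) / 2
  ties <- table(r)
  tieAdj <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tieAdj)
  if (sigma2 <= 0) stop("degenerate test: zero variance")
  dev <- W - muW
  cc <- if (dev > 0) -0.5 else if (dev < 0) 0.5 else 0
  z <- (dev + cc) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(n1 = n1, n2 = n2, W = W, z = z, p_two_sided = p, method = "normal")
}
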