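#' Read degradome profiles from TSV
#'
#' Expects columns transcript_id, position (1-based) and count; positions
#' absent from the file carry count 0. Transcript lengths determine the
#' profile lengths.
#'
#' @param path degradome TSV.
#' @param lengths named integer vector of transcript lengths (every
#'   transcript in the file must be present).
#' @return named list of \linkS4class{DegradomeProfile}, one per transcript
#'   in \code{lengths}.
#' @export
readDegradomeTsv <- function(path, lengths) {
  df <- readTsv(path)
  need <- c("transcript_id", "position", "count")
  if (!all(need %in% colnames(df)))
    stop("degradome TSV must have columns transcript_id, position, count")
  if (!all(df$transcript_id %in% names(lengths)))
    stop("degradome TSV refers to transcripts without a known length")
  out <- lapply(names(lengths), function(id) {
    cnt <- integer(lengths[[id]])
    sub <- df[df$transcript_id == id, , drop = FALSE]
    if (nrow(sub)) {
      if (any(sub$position < 1L | sub$position > lengths[[id]]))
        stop("degradome position outside transcript bounds for ", id)
      cnt[sub$position] <- as.integer(sub$count)
    }
    new("DegradomeProfile", transcriptId = id, counts = cnt)
  })
  setNames(out, names(lengths))
}

#' Expected cleavage position of a target site
#'
#' Plant miRNA-guided cleavage cuts the target between the bases paired to
#' miRNA positions 10 and 11; the reported position is the transcript base
#' paired to miRNA position 10 (the 5' side of the scissile register on the
#' miRNA). When a bulge spans the register the point is ambiguous and an
#' interval of candidate positions is returned instead (the bulged bases
#' plus the register base for a target bulge; the flanking paired bases for
#' a miRNA bulge covering position 10).
#'
#' @param site a \linkS4class{TargetSite} (or
#'   \linkS4class{DuplexAlignment}).
#' @return integer vector of transcript positions: length 1 for the
#'   unambiguous case, an interval otherwise.
#' @export
expectedCleavagePosition <- function(site) {
  d <- if (is(site, "TargetSite")) site@duplex else site
  stopifnot(is(d, "DuplexAlignment"))
  # transcript position consumed per alignment column, walking the site
  # 3' -> 5' as the miRNA is read 5' -> 3'
  consumes <- d@states != "mirna_bulge"
  tpos <- d@siteEnd - (cumsum(consumes) - as.integer(consumes))
  paired <- d@states %in% c("match", "wobble", "mismatch")
  reg <- which(paired & d@positions == 10L)
  tb11 <- which(d@states == "target_bulge" & d@positions == 11L)
  if (length(tb11)) {
    # bulged target bases sit 5' of the register base: interval of width
    # 1 + bulge length
    cand <- sort(c(tpos[tb11], if (length(reg)) tpos[reg]))
    return(as.integer(seq(min(cand), max(cand))))
  }
  if (length(reg) == 0L) {
    # miRNA bulge covers position 10: the register falls between the bases
    # paired to the nearest flanking paired positions
    lo <- which(paired & d@positions < 10L)
    hi <- which(paired & d@positions > 10L)
    if (length(lo) == 0L || length(hi) == 0L)
      stop("cannot locate the cleavage register in this duplex")
    return(as.integer(sort(c(tpos[min(hi)], tpos[max(lo)]))))
  }
  as.integer(tpos[reg])
}

#' Call degradome support for cleavage at a predicted site
#'
#' CleaveLand-style categories for the degradome signal within the site
#' window: 0 = the peak is the unique transcript-wide maximum with more
#' than one read; 1 = a tied transcript-wide maximum with more than one
#' read; 2 = above the transcript's mean count, more than one read; 3 = at
#' or below the mean, more than one read; 4 = at most one read. A site
#' supports cleavage iff its category is at most 2 and the peak lies within
#' \code{tolerance} nt of the expected cleavage position.
#'
#' @param profile a \linkS4class{DegradomeProfile} on the site's
#'   transcript.
#' @param site a \linkS4class{TargetSite}.
#' @param tolerance allowed distance (nt) between peak and expected
#'   position (default 1).
#' @return a \linkS4class{CleavageCall}.
#' @export
callCleavage <- function(profile, site, tolerance = 1L) {
  stopifnot(is(profile, "DegradomeProfile"), is(site, "TargetSite"))
  d <- site@duplex
  if (profile@transcriptId != d@transcriptId)
    stop("profile and site are on different transcripts")
  cnt <- profile@counts
  if (sum(cnt) == 0L) stop("empty degradome profile: no reads")
  win <- seq(max(1L, d@siteStart), min(length(cnt), d@siteEnd))
  expPos <- expectedCleavagePosition(site)
  peakPos <- win[which.max(cnt[win])]  # ties: leftmost
  peakCount <- cnt[peakPos]
  txMax <- max(cnt)
  category <- if (peakCount <= 1L) 4L
    else if (peakCount == txMax && sum(cnt == txMax) == 1L) 0L
    else if (peakCount == txMax) 1L
    else if (peakCount > mean(cnt)) 2L
    else 3L
  supports <- category <= 2L && min(abs(peakPos - expPos)) <= tolerance
  new("CleavageCall", transcriptId = d@transcriptId, mirnaId = d@mirnaId,
      expectedPos = expPos, peakPos = as.integer(peakPos),
      peakCount = as.integer(peakCount), category = category,
      supportsCleavage = supports)
}

#' Tabulate cleavage calls
#'
#' @param calls list of \linkS4class{CleavageCall}.
#' @return data.frame (transcript_id, mirna_id, expected_pos, peak_pos,
#'   category, supports_cleavage); interval expectations are reported as
#'   "lo-hi".
#' @export
cleavageTable <- function(calls) {
  if (length(calls) == 0L)
    return(data.frame(transcript_id = character(), mirna_id = character(),
                      expected_pos = character(), peak_pos = integer(),
                      category = integer(), supports_cleavage = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(calls, function(cc) data.frame(
    transcript_id = cc@transcriptId, mirna_id = cc@mirnaId,
    expected_pos = if (length(cc@expectedPos) == 1L)
      as.character(cc@expectedPos) else
      paste0(min(cc@expectedPos), "-", max(cc@expectedPos)),
    peak_pos = cc@peakPos, category = cc@category,
    supports_cleavage = cc@supportsCleavage, stringsAsFactors = FALSE)))
}
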