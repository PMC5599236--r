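#' @useDynLib TEmimic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

seqToInt <- function(s) {
  m <- match(seqChars(s), c("A", "C", "G", "T")) - 1L
  if (anyNA(m)) stop("sequence contains non-ACGT residues after normalisation")
  m
}

checkMirna <- function(mirna) {
  mirna <- normalizeSeq(mirna)
  if (nchar(mirna) < 19L || nchar(mirna) > 24L)
    stop("mature miRNA must be 19-24 nt, got ", nchar(mirna))
  mirna
}

# per-column penalty under the expectation scheme
colPenalty <- function(state, mpos, p) {
  base <- switch(state, match = 0, wobble = p$wobble, mismatch = p$mismatch,
                 target_bulge = p$gap, mirna_bulge = p$gap)
  if (base > 0 && mpos >= p$seed_window[1L] && mpos <= p$seed_window[2L])
    base <- base * p$seed_factor
  base
}

pairState <- function(m, s) {
  if (s == 3L - m) return("match")
  if ((m == 2L && s == 3L) || (m == 3L && s == 2L)) return("wobble")
  "mismatch"
}

# build the column table (states, positions, penalties) for one
# configuration; site/mir are integer-encoded, d = length(site) - length(mir),
# j the bulge anchor (see scoreDuplex)
duplexColumns <- function(site, mir, d, j, p) {
  M <- length(mir); L <- length(site)
  states <- character(0); positions <- integer(0)
  if (d == 0L) {
    for (i in seq_len(M)) {
      states <- c(states, pairState(mir[i], site[L - i + 1L]))
      positions <- c(positions, i)
    }
  } else if (d > 0L) {
    for (i in seq_len(M)) {
      if (i == j) {
        states <- c(states, rep("target_bulge", d))
        positions <- c(positions, rep(j, d))
      }
      sidx <- if (i < j) L - i + 1L else L - i + 1L - d
      states <- c(states, pairState(mir[i], site[sidx]))
      positions <- c(positions, i)
    }
  } else {
    bl <- -d
    for (i in seq_len(M)) {
      if (i >= j && i < j + bl) {
        states <- c(states, "mirna_bulge"); positions <- c(positions, i)
      } else {
        sidx <- if (i < j) L - i + 1L else L - i + 1L + bl
        states <- c(states, pairState(mir[i], site[sidx]))
        positions <- c(positions, i)
      }
    }
  }
  penalties <- mapply(colPenalty, states, positions,
                      MoreArgs = list(p = p), USE.NAMES = FALSE)
  list(states = states, positions = positions, penalties = as.numeric(penalties))
}

#' Score a miRNA-site duplex
#'
#' Aligns a mature miRNA against a candidate site subsequence in the
#' reverse-complement register and returns the best-scoring
#' \linkS4class{DuplexAlignment}. The expectation score sums per-column
#' penalties: match 0, G:U wobble 0.5, mismatch 1, each bulged (gap)
#' nucleotide 2, every penalty doubled when the miRNA position lies in the
#' seed window (positions 2-13 from the miRNA 5' end). A site longer than
#' the miRNA implies a target bulge, shorter a miRNA bulge; at most one
#' bulge of up to \code{max_bulge} nt is considered, placed wherever the
#' penalty is least (ties: the 5'-most placement).
#'
#' @param mirna mature miRNA sequence, 5' to 3' (ACGU or ACGT, 19-24 nt).
#' @param site transcript subsequence, 5' to 3'.
#' @param params scoring parameters, see \code{duplexDefaults()}.
#' @param mirnaId,transcriptId,siteStart optional identifiers/coordinates
#'   recorded on the returned object (siteStart 1-based).
#' @return a \linkS4class{DuplexAlignment}.
#' @examples
#' mir <- "UGAUUGAGCCGCGCCAAUAUC"
#' site <- as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAString(chartr("U", "T", mir))))
#' expectation(scoreDuplex(mir, site))  # 0
#' @export
scoreDuplex <- function(mirna, site, params = duplexDefaults(),
                        mirnaId = "miRNA", transcriptId = "transcript",
                        siteStart = 1L) {
  mirna <- checkMirna(mirna)
  site <- normalizeSeq(site)
  M <- nchar(mirna); L <- nchar(site)
  d <- L - M
  if (abs(d) > params$max_bulge)
    stop("site length must be within the miRNA length +/- ",
         params$max_bulge, " nt")
  if (d < 0 && M + d < 2L) stop("site too short to align")
  mi <- seqToInt(mirna); si <- seqToInt(site)
  cfgs <- if (d == 0L) list(0L)
          else if (d > 0L) as.list(2:M)
          else as.list(2:(M + d))
  best <- NULL; bestScore <- Inf
  for (j in cfgs) {
    cols <- duplexColumns(si, mi, d, j, params)
    sc <- sum(cols$penalties)
    if (sc < bestScore - 1e-12) { bestScore <- sc; best <- cols }
  }
  new("DuplexAlignment", mirnaId = mirnaId, transcriptId = transcriptId,
      siteStart = as.integer(siteStart),
      siteEnd = as.integer(siteStart + L - 1L),
      states = best$states, positions = as.integer(best$positions),
      penalties = best$penalties, expectation = bestScore)
}

#' Classify a duplex as cleavable target or target mimic
#'
#' Plant miRNA-guided slicing cuts the target opposite miRNA positions
#' 10-11. A site whose duplex is disrupted inside the central window
#' (default miRNA positions 9-12) - by a mismatch or a bulge - binds but
#' resists cleavage and is classified a \emph{mimic}; an intact central
#' window gives a \emph{cleavable} call. Defects outside the window (e.g. a
#' mismatch at position 14) do not affect the class.
#'
#' @param duplex a \linkS4class{DuplexAlignment}.
#' @param central_window integer pair, miRNA positions (1-based, inclusive).
#' @return a \linkS4class{TargetSite}.
#' @export
classifyMimicry <- function(duplex, central_window = c(9L, 12L)) {
  stopifnot(is(duplex, "DuplexAlignment"))
  M <- sum(duplex@states != "target_bulge")
  if (central_window[1L] < 1L || central_window[2L] > M + 3L ||
      central_window[1L] > central_window[2L])
    stop("central_window must be an increasing interval within the miRNA")
  defect <- duplex@states %in% c("mismatch", "target_bulge", "mirna_bulge")
  inWin <- duplex@positions >= central_window[1L] &
    duplex@positions <= central_window[2L]
  defects <- sort(unique(duplex@positions[defect & inWin]))
  new("TargetSite", duplex = duplex,
      mimicryClass = if (length(defects)) "mimic" else "cleavable",
      centralDefects = as.integer(defects))
}

#' Scan transcripts for miRNA-binding sites
#'
#' Slides every miRNA along every transcript, scoring each window (with up
#' to one bulge of up to 3 nt) under the expectation scheme of
#' \code{\link{scoreDuplex}}, and keeps windows with expectation at or below
#' the cutoff. Overlapping hits of the same miRNA on the same transcript
#' are resolved to the lowest expectation, ties to the leftmost start, then
#' the shortest site. Each retained site is classified by
#' \code{\link{classifyMimicry}}.
#'
#' @param transcripts named character vector or \code{DNAStringSet}.
#' @param mirnas named character vector or \code{RNAStringSet} of mature
#'   miRNAs.
#' @param cutoff maximum expectation retained (default 3.0).
#' @param params scoring parameters (see \code{duplexDefaults()}).
#' @param central_window mimicry window passed to
#'   \code{\link{classifyMimicry}}.
#' @return list of \linkS4class{TargetSite} objects; see
#'   \code{\link{sitesTable}} for a tabular view.
#' @export
scanTranscripts <- function(transcripts, mirnas, cutoff = 3.0,
                            params = duplexDefaults(),
                            central_window = c(9L, 12L)) {
  transcripts <- normalizeSeq(transcripts)
  mirnas <- vapply(mirnas, checkMirna, character(1L))
  if (is.null(names(transcripts)) || is.null(names(mirnas)))
    stop("transcripts and mirnas must be named")
  if (any(nchar(transcripts) == 0L)) stop("empty transcript")
  out <- list()
  for (ti in seq_along(transcripts)) {
    txSeq <- transcripts[[ti]]; txId <- names(transcripts)[ti]
    txInt <- seqToInt(txSeq)
    for (mi in seq_along(mirnas)) {
      mirSeq <- mirnas[[mi]]; mirId <- names(mirnas)[mi]
      cand <- .scan_windows_cpp(txInt, seqToInt(mirSeq), cutoff,
                                params$mismatch, params$wobble, params$gap,
                                params$seed_window[1L],
                                params$seed_window[2L], params$seed_factor,
                                params$max_bulge)
      if (nrow(cand) == 0L) next
      ord <- order(cand$score, cand$start, cand$len)
      cand <- cand[ord, , drop = FALSE]
      kept <- logical(0); ivs <- matrix(numeric(0), ncol = 2L)
      for (k in seq_len(nrow(cand))) {
        s <- cand$start[k]; e <- cand$start[k] + cand$len[k] - 1L
        if (nrow(ivs) == 0L || all(e < ivs[, 1L] | s > ivs[, 2L])) {
          ivs <- rbind(ivs, c(s, e))
          site <- substr(txSeq, s, e)
          dup <- scoreDuplex(mirSeq, site, params, mirnaId = mirId,
                             transcriptId = txId, siteStart = s)
          out[[length(out) + 1L]] <- classifyMimicry(dup, central_window)
        }
      }
    }
  }
  out
}

#' Tabulate a list of target sites
#'
#' @param sites list of \linkS4class{TargetSite} objects (as returned by
#'   \code{\link{scanTranscripts}}).
#' @return data.frame with columns mirna_id, transcript_id, start, end
#'   (1-based inclusive), expectation, n_wobble, n_mismatch, bulge_len,
#'   mimicry_class, central_defects (comma-joined).
#' @export
sitesTable <- function(sites) {
  if (length(sites) == 0L)
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), n_wobble = integer(),
                      n_mismatch = integer(), bulge_len = integer(),
                      mimicry_class = character(),
                      central_defects = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(sites, function(ts) {
    d <- ts@duplex
    data.frame(mirna_id = d@mirnaId, transcript_id = d@transcriptId,
               start = d@siteStart, end = d@siteEnd,
               expectation = d@expectation,
               n_wobble = sum(d@states == "wobble"),
               n_mismatch = sum(d@states == "mismatch"),
               bulge_len = sum(d@states %in%
                                 c("target_bulge", "mirna_bulge")),
               mimicry_class = ts@mimicryClass,
               central_defects = paste(ts@centralDefects, collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[order(df$transcript_id, df$mirna_id, df$start), , drop = FALSE]
}
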