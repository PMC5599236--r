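#' Find homology patches between a TE transcript and a gene mRNA
#'
#' Local (Smith-Waterman) alignment with affine gaps, run in both
#' orientations: TE vs gene (sense) and TE vs the reverse-complemented gene
#' (antisense). All non-overlapping patches scoring at least
#' \code{min_score} are reported, best first; after each patch is taken its
#' residues are masked and the search repeats, so patches never reuse TE or
#' gene positions. A gap of length k costs \code{gap_open + k * gap_ext}.
#' Defaults (match +1, mismatch -2, gap open -4, gap extend -1, min score
#' 20) favour near-exact patches of roughly 20 nt and up - the TE-derived
#' fragments the pairing step needs - not sensitive remote homology.
#'
#' @param te,gene sequences (character or \code{DNAString}); \code{te} may
#'   also carry names used in the output.
#' @param min_score minimum patch score (> 0).
#' @param match,mismatch,gap_open,gap_ext alignment parameters.
#' @param te_id,gene_id identifiers for the output rows.
#' @param max_patches safety bound on patches per orientation.
#' @return data.frame (te_id, gene_id, orientation, te_start, te_end,
#'   gene_start, gene_end, length, identity, score); coordinates 1-based
#'   inclusive on the input (forward) strands, \code{length} the aligned
#'   gene span, \code{identity} matches over alignment columns.
#' @export
findPatches <- function(te, gene, min_score = 20, match = 1, mismatch = -2,
                        gap_open = -4, gap_ext = -1, te_id = "TE",
                        gene_id = "gene", max_patches = 50L) {
  if (min_score <= 0) stop("min_score must be positive")
  te <- normalizeSeq(te); gene <- normalizeSeq(gene)
  if (nchar(te) == 0L || nchar(gene) == 0L) stop("empty sequence")
  teI <- seqToInt(te)
  runOne <- function(geneSeq, orientation) {
    gI <- seqToInt(geneSeq)
    hits <- .sw_patches_cpp(teI, gI, match, mismatch, gap_open, gap_ext,
                            min_score, max_patches)
    if (nrow(hits) == 0L) return(NULL)
    gs <- hits$b_start; ge <- hits$b_end
    if (orientation == "antisense") {
      # map back to forward-strand gene coordinates
      L <- nchar(geneSeq)
      tmp <- L - hits$b_end + 1L
      ge <- L - hits$b_start + 1L
      gs <- tmp
    }
    data.frame(te_id = te_id, gene_id = gene_id, orientation = orientation,
               te_start = hits$a_start, te_end = hits$a_end,
               gene_start = gs, gene_end = ge, length = hits$length,
               identity = hits$n_match / hits$n_cols, score = hits$score,
               stringsAsFactors = FALSE)
  }
  res <- rbind(runOne(gene, "sense"), runOne(revComp(gene), "antisense"))
  if (is.null(res))
    return(data.frame(te_id = character(), gene_id = character(),
                      orientation = character(), te_start = integer(),
                      te_end = integer(), gene_start = integer(),
                      gene_end = integer(), length = integer(),
                      identity = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  res <- res[order(-res$score, res$orientation, res$te_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarise homology patches by TE group
#'
#' For TE groups (typically expressed vs silent, labels supplied by the
#' expression filter) reports the fraction of TEs carrying at least one
#' patch, per-orientation patch-length summaries, and a rank-sum comparison
#' of sense vs antisense patch lengths (pooled over groups).
#'
#' @param patches data.frame as returned by \code{\link{findPatches}}
#'   (possibly row-bound over many TE-gene pairs).
#' @param te_groups named character vector: names are TE ids, values group
#'   labels; every scanned TE must appear (TEs without patches included).
#' @return list with \code{fractions} (data.frame group, n_te, n_with_patch,
#'   fraction), \code{length_summary} (data.frame orientation, n,
#'   median_length, mean_length) and \code{length_test}
#'   (\code{\link{rankSumTest}} of sense vs antisense lengths, or NULL when
#'   either orientation is absent).
#' @export
patchSummary <- function(patches, te_groups) {
  if (length(te_groups) == 0L) stop("empty TE group labels")
  groups <- unique(te_groups)
  withPatch <- unique(patches$te_id)
  fractions <- do.call(rbind, lapply(groups, function(g) {
    ids <- names(te_groups)[te_groups == g]
    if (length(ids) == 0L) stop("empty group: ", g)
    data.frame(group = g, n_te = length(ids),
               n_with_patch = sum(ids %in% withPatch),
               fraction = mean(ids %in% withPatch),
               stringsAsFactors = FALSE)
  }))
  lens <- split(patches$length, factor(patches$orientation,
                                       levels = c("sense", "antisense")))
  length_summary <- data.frame(
    orientation = names(lens),
    n = vapply(lens, length, integer(1L)),
    median_length = vapply(lens, function(x)
      if (length(x)) stats::median(x) else NA_real_, numeric(1L)),
    mean_length = vapply(lens, function(x)
      if (length(x)) mean(x) else NA_real_, numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(length_summary) <- NULL
  length_test <- NULL
  if (all(vapply(lens, length, integer(1L)) >= 1L) &&
      length(unique(c(lens$sense, lens$antisense))) > 1L)
    length_test <- rankSumTest(lens$sense, lens$antisense)
  list(fractions = fractions, length_summary = length_summary,
       length_test = length_test)
}
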