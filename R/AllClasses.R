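#' DuplexAlignment: a scored miRNA-target duplex
#'
#' One alignment of a mature miRNA against a transcript site, read in the
#' reverse-complement register (miRNA position 1 pairs the 3'-most site
#' base). Each alignment column carries a state in
#' \code{match, wobble, mismatch, target_bulge, mirna_bulge} and a penalty;
#' the expectation score is the sum of the penalties. Transcript coordinates
#' are 1-based inclusive.
#'
#' @slot mirnaId,transcriptId identifiers.
#' @slot siteStart,siteEnd site interval on the transcript (1-based,
#'   inclusive).
#' @slot states per-column states, miRNA 5' to 3'.
#' @slot positions per-column miRNA position (1-based from the miRNA 5'
#'   end); a target-bulge column carries the position of the next paired
#'   miRNA base (its insertion point).
#' @slot penalties per-column penalty contributions.
#' @slot expectation total expectation (penalty) score, >= 0.
#' @export
setClass("DuplexAlignment", representation(
  mirnaId = "character", transcriptId = "character",
  siteStart = "integer", siteEnd = "integer",
  states = "character", positions = "integer",
  penalties = "numeric", expectation = "numeric"
))

setValidity("DuplexAlignment", function(object) {
  msg <- character()
  okStates <- c("match", "wobble", "mismatch", "target_bulge", "mirna_bulge")
  if (!all(object@states %in% okStates))
    msg <- c(msg, "invalid alignment state")
  if (length(object@states) != length(object@positions) ||
      length(object@states) != length(object@penalties))
    msg <- c(msg, "states, positions and penalties must be parallel")
  if (object@siteEnd < object@siteStart)
    msg <- c(msg, "siteEnd must be >= siteStart")
  if (!isTRUE(all.equal(object@expectation, sum(object@penalties))))
    msg <- c(msg, "expectation must equal the sum of per-column penalties")
  if (object@expectation < -1e-9) msg <- c(msg, "expectation must be >= 0")
  if (length(msg)) msg else TRUE
})

#' TargetSite: a classified miRNA-binding site
#'
#' A retained duplex together with its mimicry class. A site is a
#' \emph{mimic} iff at least one mismatch or bulge falls at a miRNA position
#' inside the central (cleavage-register) window; otherwise it is
#' \emph{cleavable}.
#'
#' @slot duplex the underlying \linkS4class{DuplexAlignment}.
#' @slot mimicryClass \code{"cleavable"} or \code{"mimic"}.
#' @slot centralDefects miRNA positions (1-based) of central-window
#'   mismatches/bulges; empty for cleavable sites.
#' @export
setClass("TargetSite", representation(
  duplex = "DuplexAlignment", mimicryClass = "character",
  centralDefects = "integer"
))

setValidity("TargetSite", function(object) {
  msg <- character()
  if (!object@mimicryClass %in% c("cleavable", "mimic"))
    msg <- c(msg, "mimicryClass must be 'cleavable' or 'mimic'")
  isMimic <- length(object@centralDefects) > 0L
  if (isMimic != (object@mimicryClass == "mimic"))
    msg <- c(msg, "mimicryClass 'mimic' iff centralDefects non-empty")
  if (length(msg)) msg else TRUE
})

#' DegradomeProfile: per-position degradome 5'-end counts
#'
#' Counts of uncapped read 5' ends along one transcript; position i of
#' \code{counts} is transcript position i (1-based).
#'
#' @slot transcriptId identifier.
#' @slot counts non-negative integer vector, one entry per transcript
#'   position.
#' @export
setClass("DegradomeProfile", representation(
  transcriptId = "character", counts = "integer"
))

setValidity("DegradomeProfile", function(object) {
  if (length(object@counts) < 1L) return("counts must be non-empty")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  TRUE
})

#' CleavageCall: degradome evidence at a predicted site
#'
#' CleaveLand-style category (0 best to 4 worst) for the degradome signal at
#' a predicted miRNA-binding site, plus the support decision.
#'
#' @slot transcriptId,mirnaId identifiers.
#' @slot expectedPos transcript position(s) opposite miRNA position 10; an
#'   interval when a bulge spans the cleavage register.
#' @slot peakPos argmax position within the site window.
#' @slot peakCount count at \code{peakPos}.
#' @slot category integer 0-4.
#' @slot supportsCleavage TRUE iff category <= 2 and the peak lies within
#'   the tolerance of the expected position.
#' @export
setClass("CleavageCall", representation(
  transcriptId = "character", mirnaId = "character",
  expectedPos = "integer", peakPos = "integer", peakCount = "integer",
  category = "integer", supportsCleavage = "logical"
))

setValidity("CleavageCall", function(object) {
  if (!object@category %in% 0:4) return("category must be in 0..4")
  TRUE
})

#' LTRAgeEstimate: LTR insertion age from divergence
#'
#' Age under the molecular-clock dating of LTR retrotransposons:
#' T = D/(2t) for a paired-LTR comparison (both LTRs diverge from the
#' identical state at insertion) and T = D/t for a solo LTR compared to the
#' family consensus (taken as the youngest copy).
#'
#' @slot mode \code{"paired"} or \code{"solo"}.
#' @slot D divergence (proportion of differing aligned sites).
#' @slot rate substitution rate t, per site per year.
#' @slot age T, years since insertion.
#' @slot alignedSites number of compared (non-gap) positions.
#' @export
setClass("LTRAgeEstimate", representation(
  mode = "character", D = "numeric", rate = "numeric",
  age = "numeric", alignedSites = "integer"
))

setValidity("LTRAgeEstimate", function(object) {
  msg <- character()
  if (!object@mode %in% c("paired", "solo"))
    msg <- c(msg, "mode must be 'paired' or 'solo'")
  if (object@D < 0 || object@D > 1) msg <- c(msg, "D must lie in [0,1]")
  if (object@rate <= 0) msg <- c(msg, "rate must be positive")
  expT <- if (object@mode == "paired") object@D / (2 * object@rate)
          else object@D / object@rate
  if (!isTRUE(all.equal(object@age, expT)))
    msg <- c(msg, "age inconsistent with mode, D and rate")
  if (length(msg)) msg else TRUE
})

#' SimConfig: configuration of the synthetic-data generator
#'
#' All knobs of the ground-truth simulator. Defaults describe the study
#' conditions the downstream analyses assume; see the methods vignette.
#'
#' @slot seed RNG seed (all outputs are byte-identical for a fixed seed).
#' @slot nGenes,nTEs,nMirnas,nTissues,replicatesPerTissue counts (>= 1).
#' @slot lengthRange transcript length range in nt.
#' @slot plantedMimicFraction fraction of TEs carrying a planted mimic site.
#' @slot plantedCleavableFraction fraction of genes carrying a planted
#'   cleavable site.
#' @slot silentTeFraction fraction of TEs simulated below the expression
#'   filter.
#' @slot targetCorrelation intended tissue-wise Pearson r of planted
#'   TE-gene pairs.
#' @slot expressionNoiseSd per-replicate log2 noise SD.
#' @slot degradomePeakEnrichment fold enrichment of the cleavage-position
#'   degradome count over background (>= 1).
#' @slot degradomeBackground mean background degradome count per position
#'   (Poisson).
#' @slot ltrRate substitution rate per site per year.
#' @slot ltrTrueAges true insertion ages (years) simulated for LTR pairs.
#' @export
setClass("SimConfig", representation(
  seed = "integer", nGenes = "integer", nTEs = "integer",
  nMirnas = "integer", nTissues = "integer",
  replicatesPerTissue = "integer", lengthRange = "integer",
  plantedMimicFraction = "numeric", plantedCleavableFraction = "numeric",
  silentTeFraction = "numeric", targetCorrelation = "numeric",
  expressionNoiseSd = "numeric", degradomePeakEnrichment = "numeric",
  degradomeBackground = "numeric", ltrRate = "numeric",
  ltrTrueAges = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(object@nGenes, object@nTEs, object@nMirnas, object@nTissues,
           object@replicatesPerTissue)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  fr <- c(object@plantedMimicFraction, object@plantedCleavableFraction,
          object@silentTeFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0,1]")
  if (abs(object@targetCorrelation) > 1)
    msg <- c(msg, "targetCorrelation must lie in [-1,1]")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1L] > object@lengthRange[2L] ||
      object@lengthRange[1L] < 30L)
    msg <- c(msg, "lengthRange must be an increasing pair >= 30 nt")
  if (object@degradomePeakEnrichment < 1)
    msg <- c(msg, "degradomePeakEnrichment must be >= 1")
  if (object@degradomeBackground <= 0)
    msg <- c(msg, "degradomeBackground must be positive")
  if (object@ltrRate <= 0) msg <- c(msg, "ltrRate must be positive")
  if (any(object@ltrTrueAges < 0)) msg <- c(msg, "ltrTrueAges must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimTruth: ground truth of a simulated dataset
#'
#' Planted structure emitted alongside the simulated files, used to close
#' the loop between the generator and the discovery pipeline.
#'
#' @slot mimicSites data.frame (te_id, mirna_id, start, end).
#' @slot cleavableSites data.frame (gene_id, mirna_id, start, end).
#' @slot plantedPairs data.frame (te_id, gene_id, mirna_id, target_r).
#' @slot ltrTruth data.frame (pair_id, mode, true_divergence, true_age).
#' @export
setClass("SimTruth", representation(
  mimicSites = "data.frame", cleavableSites = "data.frame",
  plantedPairs = "data.frame", ltrTruth = "data.frame"
))

setMethod("show", "DuplexAlignment", function(object) {
  cat(sprintf("DuplexAlignment %s ~ %s:%d-%d expectation=%.2f [%s]\n",
              object@mirnaId, object@transcriptId, object@siteStart,
              object@siteEnd, object@expectation,
              paste(substr(object@states, 1L, 2L), collapse = "")))
})

setMethod("show", "TargetSite", function(object) {
  cat(sprintf("TargetSite [%s] ", object@mimicryClass))
  show(object@duplex)
  if (length(object@centralDefects))
    cat("  central defects at miRNA position(s): ",
        paste(object@centralDefects, collapse = ", "), "\n", sep = "")
})

setMethod("show", "LTRAgeEstimate", function(object) {
  cat(sprintf(
    "LTRAgeEstimate (%s): D=%.5f over %d sites, t=%.3g/site/yr, T=%.3g yr (%.2f Mya)\n",
    object@mode, object@D, object@alignedSites, object@rate, object@age,
    object@age / 1e6))
})

setMethod("show", "CleavageCall", function(object) {
  cat(sprintf(
    "CleavageCall %s ~ %s: expected %s, peak %d (n=%d), category %d, %s\n",
    object@mirnaId, object@transcriptId,
    paste(range(object@expectedPos), collapse = "-"), object@peakPos,
    object@peakCount, object@category,
    if (object@supportsCleavage) "supports cleavage" else "no cleavage support"))
})
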