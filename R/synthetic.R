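#' Construct a synthetic-data generator configuration
#'
#' Defaults describe the study conditions the discovery pipeline assumes:
#' tissue-specific log-normal RPKM with planted TE-gene correlations,
#' TE transcripts carrying central-mismatch (mimic) miRNA sites and genes
#' carrying near-perfect (cleavable) sites, degradome profiles peaked at
#' the cleavage register of cleavable sites only, and LTR pairs mutated at
#' a known rate x age. See the methods vignette for the rationale behind
#' each default.
#'
#' @param seed RNG seed; identical seed and config give byte-identical
#'   output files.
#' @param n_genes,n_tes,n_mirnas,n_tissues,replicates_per_tissue counts.
#' @param transcript_length_range nt interval for simulated transcripts.
#' @param planted_mimic_fraction fraction of TEs with a planted mimic site.
#' @param planted_cleavable_fraction fraction of genes with a planted
#'   cleavable site.
#' @param silent_te_fraction fraction of TEs simulated below the RPKM
#'   filter.
#' @param target_correlation intended tissue-wise Pearson r of planted
#'   pairs.
#' @param expression_noise_sd per-replicate log2 noise SD.
#' @param degradome_peak_enrichment fold enrichment of the cleavage
#'   position over background (>= 1).
#' @param degradome_background mean background degradome count per
#'   position (Poisson).
#' @param ltr_rate substitution rate per site per year.
#' @param ltr_true_ages true insertion ages (years) of simulated LTR
#'   elements.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed = 1L, n_genes = 60L, n_tes = 40L,
                      n_mirnas = 10L, n_tissues = 10L,
                      replicates_per_tissue = 3L,
                      transcript_length_range = c(600L, 1500L),
                      planted_mimic_fraction = 0.25,
                      planted_cleavable_fraction = 0.4,
                      silent_te_fraction = 0.25,
                      target_correlation = 0.9,
                      expression_noise_sd = 0.25,
                      degradome_peak_enrichment = 20,
                      degradome_background = 0.15,
                      ltr_rate = 1.3e-8,
                      ltr_true_ages = c(3.7e6, 1.2e6)) {
  cfg <- new("SimConfig", seed = as.integer(seed),
             nGenes = as.integer(n_genes), nTEs = as.integer(n_tes),
             nMirnas = as.integer(n_mirnas),
             nTissues = as.integer(n_tissues),
             replicatesPerTissue = as.integer(replicates_per_tissue),
             lengthRange = as.integer(transcript_length_range),
             plantedMimicFraction = planted_mimic_fraction,
             plantedCleavableFraction = planted_cleavable_fraction,
             silentTeFraction = silent_te_fraction,
             targetCorrelation = target_correlation,
             expressionNoiseSd = expression_noise_sd,
             degradomePeakEnrichment = degradome_peak_enrichment,
             degradomeBackground = degradome_background,
             ltrRate = ltr_rate, ltrTrueAges = as.numeric(ltr_true_ages))
  validObject(cfg)
  cfg
}

bases <- c("A", "C", "G", "T")
compBase <- function(b) chartr("ACGT", "TGCA", b)
wobblePartner <- function(b) switch(b, G = "T", T = "G", NA_character_)

randomSeq <- function(len) paste(sample(bases, len, replace = TRUE),
                                 collapse = "")

#' Random transcript sequences
#'
#' Uniform-composition random sequences; a building block for simulated
#' datasets and tests.
#'
#' @param n number of sequences.
#' @param length_range nt interval (lengths drawn uniformly).
#' @param prefix id prefix.
#' @return named character vector.
#' @export
randomTranscripts <- function(n, length_range = c(600L, 1500L),
                              prefix = "tx") {
  lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
  out <- vapply(lens, randomSeq, character(1L))
  names(out) <- sprintf("%s%03d", prefix, seq_len(n))
  out
}

# overwrite transcript[start..] with block, returning the sequence
embedAt <- function(transcript, block, start) {
  if (start < 1L || start + nchar(block) - 1L > nchar(transcript))
    stop("planted block exceeds transcript bounds")
  paste0(substr(transcript, 1L, start - 1L), block,
         substr(transcript, start + nchar(block), nchar(transcript)))
}

# perfect site, optional single wobble at a non-central miRNA position
makeCleavableSite <- function(mirna, wobble_pos = 15L) {
  site <- revComp(mirna)
  m <- seqChars(mirna)
  if (!is.na(wobble_pos) && wobble_pos <= nchar(mirna)) {
    wb <- wobblePartner(m[wobble_pos])
    if (!is.na(wb)) {
      idx <- nchar(mirna) - wobble_pos + 1L
      substr(site, idx, idx) <- wb
    }
  }
  site
}

# mimic site: mismatches at the given miRNA positions (default the
# MIKKI-style central position 11)
makeMimicSite <- function(mirna, mismatch_pos = 11L) {
  site <- revComp(mirna)
  m <- seqChars(mirna)
  for (p in mismatch_pos) {
    bad <- setdiff(bases, c(compBase(m[p]), wobblePartner(m[p])))
    idx <- nchar(mirna) - p + 1L
    substr(site, idx, idx) <- sample(bad, 1L)
  }
  site
}

# substitute each site with probability q, uniformly among the 3 others
mutateSeq <- function(seq, q) {
  s <- seqChars(seq)
  hit <- runif(length(s)) < q
  if (any(hit))
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1L))
  paste(s, collapse = "")
}

#' Simulate LTR sequence pairs at a known age
#'
#' Each element starts from a random ancestor LTR; in paired mode both
#' copies are mutated independently with per-site substitution probability
#' rate x age (substitutions uniform over the three alternative bases, no
#' indels), in solo mode only the solo copy is mutated and the unmutated
#' ancestor stands for the family consensus (the youngest copy).
#'
#' @param n number of elements.
#' @param length LTR length in nt.
#' @param age true insertion age in years.
#' @param rate substitution rate per site per year.
#' @param mode \code{"paired"} or \code{"solo"}.
#' @param prefix id prefix.
#' @return list with \code{seqs} (named character: two records per
#'   element) and \code{truth} (data.frame pair_id, mode, true_divergence,
#'   true_age) where \code{true_divergence} is the realised p-distance.
#' @export
simulateLTRPairs <- function(n, length = 1000L, age, rate = 1.3e-8,
                             mode = c("paired", "solo"), prefix = "ltr") {
  mode <- match.arg(mode)
  if (rate <= 0) stop("rate must be positive")
  if (age < 0) stop("age must be non-negative")
  q <- rate * age
  if (q >= 1) stop("rate x age must be < 1 per site")
  seqs <- character(0); truth <- vector("list", n)
  for (i in seq_len(n)) {
    anc <- randomSeq(length)
    id <- sprintf("%s%03d", prefix, i)
    if (mode == "paired") {
      a <- mutateSeq(anc, q); b <- mutateSeq(anc, q)
      seqs[[paste0(id, "_5p")]] <- a
      seqs[[paste0(id, "_3p")]] <- b
    } else {
      a <- mutateSeq(anc, q); b <- anc
      seqs[[paste0(id, "_solo")]] <- a
      seqs[[paste0(id, "_consensus")]] <- b
    }
    truth[[i]] <- data.frame(
      pair_id = id, mode = mode,
      true_divergence = sum(seqChars(a) != seqChars(b)) / length,
      true_age = age, stringsAsFactors = FALSE)
  }
  list(seqs = seqs, truth = do.call(rbind, truth))
}

#' Simulate a complete pipeline input dataset with known ground truth
#'
#' Generates mature miRNAs, gene and TE transcripts with planted cleavable
#' and mimic binding sites, sense/antisense homology blocks between planted
#' TE-gene pairs, a tissue x replicate RPKM matrix whose planted pairs
#' share a tissue profile calibrated so the expected tissue-mean Pearson r
#' equals \code{target_correlation}, degradome profiles with Poisson
#' background and a peak (enrichment x background) at the cleavage register
#' of cleavable sites only, and LTR pairs mutated at rate x age. All
#' outputs are written as plain-text files (FASTA/TSV/JSON, LF endings)
#' and returned in memory together with the ground truth.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param dir output directory (created if needed); NULL skips writing.
#' @return list: \code{config}, \code{truth} (\linkS4class{SimTruth}),
#'   \code{mirnas}, \code{genes}, \code{tes}, \code{ltr} (named character
#'   sequences), \code{expression} (\code{SummarizedExperiment}),
#'   \code{degradome} (list of \linkS4class{DegradomeProfile}) and
#'   \code{files} (named paths, when \code{dir} is given).
#' @export
simulateDataset <- function(config = simConfig(), dir = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nM <- config@nMirnas; nG <- config@nGenes; nT <- config@nTEs

  mirnas <- vapply(seq_len(nM), function(i) randomSeq(21L), character(1L))
  names(mirnas) <- sprintf("miR%03d", seq_len(nM))

  genes <- randomTranscripts(nG, config@lengthRange, prefix = "gene")
  tes <- randomTranscripts(nT, config@lengthRange, prefix = "TE")

  nSilent <- floor(nT * config@silentTeFraction)
  silentIds <- if (nSilent > 0L) names(tes)[(nT - nSilent + 1L):nT]
               else character(0)
  expressedIds <- setdiff(names(tes), silentIds)

  nMimic <- round(nT * config@plantedMimicFraction)
  if (nMimic > length(expressedIds))
    stop("planted_mimic_fraction requires more expressed TEs than available")
  nCleav <- round(nG * config@plantedCleavableFraction)
  if (nMimic > 0L && nCleav < min(nMimic, nM) + 1L)
    stop("planted_cleavable_fraction too small to partner every mimic TE")

  siteLen <- 21L

  # cleavable sites on genes, miRNAs assigned cyclically
  cleavRows <- list()
  for (i in seq_len(nCleav)) {
    gid <- names(genes)[i]
    mid <- names(mirnas)[(i - 1L) %% nM + 1L]
    site <- makeCleavableSite(mirnas[[mid]],
                              wobble_pos = if (i %% 2L == 0L) 15L else NA)
    start <- sample(seq_len(nchar(genes[[gid]]) - siteLen + 1L), 1L)
    genes[[gid]] <- embedAt(genes[[gid]], site, start)
    cleavRows[[i]] <- data.frame(gene_id = gid, mirna_id = mid,
                                 start = start, end = start + siteLen - 1L,
                                 stringsAsFactors = FALSE)
  }

  # mimic sites on expressed TEs; TE i partners gene i (same miRNA by the
  # cyclic assignment); the first TE is the MIKKI-like flagship with
  # mismatches at positions 11 and 14 and a second partner gene
  mimicRows <- list(); pairRows <- list()
  for (i in seq_len(nMimic)) {
    tid <- expressedIds[i]
    mid <- names(mirnas)[(i - 1L) %% nM + 1L]
    mm <- if (i == 1L) c(11L, 14L) else 11L
    site <- makeMimicSite(mirnas[[mid]], mm)
    start <- sample(seq_len(nchar(tes[[tid]]) - siteLen + 1L), 1L)
    tes[[tid]] <- embedAt(tes[[tid]], site, start)
    mimicRows[[i]] <- data.frame(te_id = tid, mirna_id = mid,
                                 start = start, end = start + siteLen - 1L,
                                 stringsAsFactors = FALSE)
    partners <- names(genes)[i]
    if (i == 1L) {
      # flagship gets extra partner genes carrying the same miRNA site
      extra <- c(nM + 1L, 2L * nM + 1L)
      partners <- c(partners, names(genes)[extra[extra <= nCleav]])
    }
    for (gid in partners)
      pairRows[[length(pairRows) + 1L]] <- data.frame(
        te_id = tid, gene_id = gid, mirna_id = mid,
        target_r = config@targetCorrelation, stringsAsFactors = FALSE)
  }
  mimicSites <- if (length(mimicRows)) do.call(rbind, mimicRows) else
    data.frame(te_id = character(), mirna_id = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  cleavSites <- if (length(cleavRows)) do.call(rbind, cleavRows) else
    data.frame(gene_id = character(), mirna_id = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  plantedPairs <- if (length(pairRows)) do.call(rbind, pairRows) else
    data.frame(te_id = character(), gene_id = character(),
               mirna_id = character(), target_r = numeric(),
               stringsAsFactors = FALSE)

  # homology blocks: copy a gene block into the paired TE (every 4th pair
  # antisense), avoiding the planted mimic site
  blockLen <- 120L
  for (k in seq_len(nrow(plantedPairs))) {
    tid <- plantedPairs$te_id[k]; gid <- plantedPairs$gene_id[k]
    g <- genes[[gid]]; te <- tes[[tid]]
    gSite <- cleavSites[cleavSites$gene_id == gid, , drop = FALSE]
    bStart <- 1L
    for (try in seq_len(50L)) {
      bStart <- sample(seq_len(nchar(g) - blockLen + 1L), 1L)
      clear <- nrow(gSite) == 0L ||
        bStart + blockLen - 1L < gSite$start[1L] || bStart > gSite$end[1L]
      if (clear) break
    }
    block <- substr(g, bStart, bStart + blockLen - 1L)
    if (k %% 4L == 0L) block <- revComp(block)
    siteIv <- mimicSites[mimicSites$te_id == tid, , drop = FALSE][1L, ]
    ok <- FALSE; tries <- 0L
    while (!ok && tries < 50L) {
      tStart <- sample(seq_len(nchar(te) - blockLen + 1L), 1L)
      ok <- (tStart + blockLen - 1L < siteIv$start) ||
        (tStart > siteIv$end)
      tries <- tries + 1L
    }
    if (ok) tes[[tid]] <- embedAt(te, block, tStart)
  }

  # expression: log2 tissue profiles, shared between planted partners with
  # tissue-level noise calibrated to the target correlation of
  # tissue-mean log2 expression
  nTis <- config@nTissues; nRep <- config@replicatesPerTissue
  sigmaS <- 2.0
  rho <- config@targetCorrelation
  sigmaEeff2 <- if (abs(rho) > 0) sigmaS^2 * (1 - abs(rho)) / abs(rho)
                else Inf
  sigmaE <- sqrt(max(sigmaEeff2 - config@expressionNoiseSd^2 / nRep, 0))
  tissues <- sprintf("tissue%02d", seq_len(nTis))
  samples <- as.vector(t(outer(tissues, seq_len(nRep),
                               function(t, r) sprintf("%s_rep%d", t, r))))
  sampleTissue <- rep(tissues, each = nRep)

  sharedProfiles <- list()   # one per paired TE, reused by partner genes
  for (tid in unique(plantedPairs$te_id))
    sharedProfiles[[tid]] <- rnorm(1L, 6, 1) + rnorm(nTis, 0, sigmaS)

  logExpr <- function(id, kind) {
    if (kind == "silent") return(-6 + rnorm(nTis, 0, 1))
    if (id %in% plantedPairs$te_id && is.finite(sigmaEeff2))
      return(sharedProfiles[[id]] + rnorm(nTis, 0, sigmaE))
    gi <- match(id, plantedPairs$gene_id)
    if (!is.na(gi) && is.finite(sigmaEeff2)) {
      sp <- sharedProfiles[[plantedPairs$te_id[gi]]]
      base <- if (rho >= 0) sp else 2 * mean(sp) - sp
      return(base + rnorm(nTis, 0, sigmaE))
    }
    rnorm(1L, 6, 1) + rnorm(nTis, 0, sigmaS)
  }

  allIds <- c(names(genes), names(tes))
  kinds <- c(rep("gene", nG),
             ifelse(names(tes) %in% silentIds, "silent", "te"))
  rpkm <- matrix(0, nrow = length(allIds), ncol = length(samples),
                 dimnames = list(allIds, samples))
  for (i in seq_along(allIds)) {
    mu <- logExpr(allIds[i], kinds[i])
    x <- rep(mu, each = nRep) +
      rnorm(nTis * nRep, 0, config@expressionNoiseSd)
    rpkm[i, ] <- round(2^x, 4)
  }

  # degradome: background everywhere, a peak at the cleavage register of
  # cleavable (gene) sites; mimic (TE) sites get background only
  bg <- config@degradomeBackground
  degradome <- list()
  for (k in seq_len(nrow(cleavSites))) {
    gid <- cleavSites$gene_id[k]
    cnt <- rpois(nchar(genes[[gid]]), bg)
    cleavePos <- cleavSites$end[k] - 9L   # base paired to miRNA position 10
    # a detected cleavage product always leaves >= 2 reads; shifted Poisson
    # keeps the mean at exactly enrichment x background
    peakMean <- config@degradomePeakEnrichment * bg
    cnt[cleavePos] <- 2L + rpois(1L, max(peakMean - 2, 0))
    degradome[[gid]] <- new("DegradomeProfile", transcriptId = gid,
                            counts = as.integer(cnt))
  }
  for (k in seq_len(nrow(mimicSites))) {
    tid <- mimicSites$te_id[k]
    degradome[[tid]] <- new("DegradomeProfile", transcriptId = tid,
                            counts = as.integer(rpois(nchar(tes[[tid]]), bg)))
  }

  # LTR pairs at the configured true ages (paired mode, plus one solo set
  # per age)
  ltrSeqs <- character(0); ltrRows <- list()
  for (ai in seq_along(config@ltrTrueAges)) {
    p <- simulateLTRPairs(1L, 1000L, config@ltrTrueAges[ai],
                          config@ltrRate, "paired",
                          prefix = sprintf("ltrpair_a%d_", ai))
    s <- simulateLTRPairs(1L, 1000L, config@ltrTrueAges[ai],
                          config@ltrRate, "solo",
                          prefix = sprintf("ltrsolo_a%d_", ai))
    ltrSeqs <- c(ltrSeqs, p$seqs, s$seqs)
    ltrRows[[length(ltrRows) + 1L]] <- rbind(p$truth, s$truth)
  }
  ltrTruth <- if (length(ltrRows)) do.call(rbind, ltrRows) else
    data.frame(pair_id = character(), mode = character(),
               true_divergence = numeric(), true_age = numeric(),
               stringsAsFactors = FALSE)

  truth <- new("SimTruth", mimicSites = mimicSites,
               cleavableSites = cleavSites, plantedPairs = plantedPairs,
               ltrTruth = ltrTruth)

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(genes = file.path(dir, "genes.fasta"),
               tes = file.path(dir, "tes.fasta"),
               mirnas = file.path(dir, "mirnas.fasta"),
               expression = file.path(dir, "expression.tsv"),
               sample_map = file.path(dir, "sample_map.tsv"),
               degradome = file.path(dir, "degradome.tsv"),
               ltr = file.path(dir, "ltr.fasta"),
               truth = file.path(dir, "truth.json"))
    writeFasta(genes, files[["genes"]])
    writeFasta(tes, files[["tes"]])
    writeFasta(mirnas, files[["mirnas"]])
    exprDf <- data.frame(transcript_id = rownames(rpkm), rpkm,
                         check.names = FALSE, stringsAsFactors = FALSE)
    writeTsv(exprDf, files[["expression"]])
    writeTsv(data.frame(sample_id = samples, tissue = sampleTissue,
                        stringsAsFactors = FALSE), files[["sample_map"]])
    degRows <- list()
    for (id in names(degradome)) {
      cnt <- degradome[[id]]@counts
      nz <- which(cnt > 0L)
      if (length(nz))
        degRows[[id]] <- data.frame(transcript_id = id, position = nz,
                                    count = cnt[nz],
                                    stringsAsFactors = FALSE)
    }
    degDf <- if (length(degRows)) do.call(rbind, degRows) else
      data.frame(transcript_id = character(), position = integer(),
                 count = integer(), stringsAsFactors = FALSE)
    rownames(degDf) <- NULL
    writeTsv(degDf, files[["degradome"]])
    writeFasta(ltrSeqs, files[["ltr"]])
    writeTruth(truth, files[["truth"]])
  }

  list(config = config, truth = truth, mirnas = mirnas, genes = genes,
       tes = tes, ltr = ltrSeqs,
       expression = asExpressionSE(rpkm, tissue = sampleTissue),
       degradome = degradome, expressed_te_ids = expressedIds,
       silent_te_ids = silentIds, files = files)
}

truthSchemas <- function() list(
  mimic_sites = c(te_id = "character", mirna_id = "character",
                  start = "integer", end = "integer"),
  cleavable_sites = c(gene_id = "character", mirna_id = "character",
                      start = "integer", end = "integer"),
  planted_pairs = c(te_id = "character", gene_id = "character",
                    mirna_id = "character", target_r = "numeric"),
  ltr_truth = c(pair_id = "character", mode = "character",
                true_divergence = "numeric", true_age = "numeric"))

#' Write / read ground truth as JSON
#'
#' The truth file round-trips losslessly: \code{readTruth(writeTruth(x))}
#' equals \code{x}.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path JSON path.
#' @return \code{writeTruth}: the path, invisibly; \code{readTruth}: a
#'   \linkS4class{SimTruth}.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  obj <- list(mimic_sites = truth@mimicSites,
              cleavable_sites = truth@cleavableSites,
              planted_pairs = truth@plantedPairs,
              ltr_truth = truth@ltrTruth)
  jsonlite::write_json(obj, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  schemas <- truthSchemas()
  fix <- function(name) {
    sch <- schemas[[name]]
    df <- obj[[name]]
    if (is.null(df) || length(df) == 0L || nrow(as.data.frame(df)) == 0L) {
      cols <- lapply(sch, function(ty) vector(ty, 0L))
      return(as.data.frame(cols, stringsAsFactors = FALSE))
    }
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (cn in names(sch)) storage.mode(df[[cn]]) <-
        switch(sch[[cn]], integer = "integer", numeric = "double",
               character = "character")
    df[, names(sch), drop = FALSE]
  }
  new("SimTruth", mimicSites = fix("mimic_sites"),
      cleavableSites = fix("cleavable_sites"),
      plantedPairs = fix("planted_pairs"), ltrTruth = fix("ltr_truth"))
}
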