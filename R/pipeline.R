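#' Pipeline configuration
#'
#' Assembles and validates the configuration of the full discovery
#' pipeline. Paths may be NULL where a stage is optional (degradome,
#' sample map). Thresholds default to the module defaults documented on
#' the stage functions.
#'
#' @param genes_fasta,tes_fasta,mirnas_fasta,expression_tsv input paths.
#' @param sample_map_tsv optional sample-to-tissue TSV.
#' @param degradome_tsv optional degradome profile TSV.
#' @param expectation_cutoff site expectation cutoff (default 3).
#' @param central_window mimicry window (default 9-12).
#' @param r_threshold pair correlation threshold (default 0.5).
#' @param rpkm_threshold expressed-TE filter threshold (default 1).
#' @param degradome_tolerance peak-position tolerance in nt (default 1).
#' @param min_patch_score homology patch score threshold (default 20).
#' @param seed RNG seed recorded in the provenance block.
#' @param out_dir output directory.
#' @return a validated config (list with class \code{"temimic_config"}).
#' @export
pipelineConfig <- function(genes_fasta, tes_fasta, mirnas_fasta,
                           expression_tsv, sample_map_tsv = NULL,
                           degradome_tsv = NULL, expectation_cutoff = 3.0,
                           central_window = c(9L, 12L), r_threshold = 0.5,
                           rpkm_threshold = 1, degradome_tolerance = 1L,
                           min_patch_score = 20, seed = 1L,
                           out_dir = "temimic_out") {
  cfg <- list(genes_fasta = genes_fasta, tes_fasta = tes_fasta,
              mirnas_fasta = mirnas_fasta, expression_tsv = expression_tsv,
              sample_map_tsv = sample_map_tsv,
              degradome_tsv = degradome_tsv,
              expectation_cutoff = expectation_cutoff,
              central_window = as.integer(central_window),
              r_threshold = r_threshold, rpkm_threshold = rpkm_threshold,
              degradome_tolerance = as.integer(degradome_tolerance),
              min_patch_score = min_patch_score, seed = as.integer(seed),
              out_dir = out_dir)
  if (cfg$expectation_cutoff < 0 || cfg$rpkm_threshold < 0 ||
      cfg$min_patch_score <= 0 || cfg$degradome_tolerance < 0)
    stop("threshold outside its documented range")
  class(cfg) <- "temimic_config"
  cfg
}

# write the MANIFEST: every output with its md5 checksum, plus provenance
writeManifest <- function(dir, files, cfg, complete) {
  rel <- basename(files)
  sums <- unname(tools::md5sum(files))
  prov <- list(
    package = "TEmimic",
    version = as.character(utils::packageVersion("TEmimic")),
    seed = cfg$seed,
    config_md5 = {
      # hash the analytic parameters only: the output location must not
      # change the provenance of identical analyses
      hashed <- unclass(cfg)
      hashed$out_dir <- NULL
      tmp <- tempfile(); on.exit(unlink(tmp))
      writeLines(as.character(jsonlite::toJSON(hashed, auto_unbox = TRUE,
                                               null = "null")), tmp)
      unname(tools::md5sum(tmp))
    },
    complete = complete)
  jsonlite::write_json(list(provenance = prov,
                            outputs = data.frame(file = rel, md5 = sums,
                                                 stringsAsFactors = FALSE)),
                       file.path(dir, "MANIFEST.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Run the full target-mimic discovery pipeline
#'
#' Stage order: expression filter (max RPKM > threshold keeps a TE as
#' transcribed) -> miRNA site scan of expressed TEs and all genes ->
#' homology patches for TE-gene combinations sharing a miRNA ->
#' co-expression pairing (tissue-mean Pearson r) -> mimicry evidence ->
#' degradome check (optional). A candidate target mimic is a TE with at
#' least one mimic-class site, passing the expression filter, with at
#' least one pair above the correlation threshold; candidates whose
#' degradome profile supports cleavage at the mimic site are flagged
#' "cleaved" and excluded from the ranked mimic list. Candidates are
#' ranked by number of correlated partners, then lowest best expectation,
#' then id. Every stage writes its TSV before the report; a MANIFEST.json
#' with md5 checksums and a provenance block is written last.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list: \code{report} (ranked candidate data.frame),
#'   \code{pairs}, \code{counts}, \code{te_sites}, \code{gene_sites},
#'   \code{patches}, \code{degradome_calls} (NULL without degradome
#'   input), \code{files}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "temimic_config"))
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (length(written)) writeManifest(dir, written, config, FALSE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, fname) {
    path <- file.path(dir, fname)
    writeTsv(df, path)
    written <<- c(written, path)
    path
  }

  inp <- stage("input", {
    for (p in c(config$genes_fasta, config$tes_fasta, config$mirnas_fasta,
                config$expression_tsv, config$sample_map_tsv,
                config$degradome_tsv))
      if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
    list(genes = readSeqFasta(config$genes_fasta),
         tes = readSeqFasta(config$tes_fasta),
         mirnas = readSeqFasta(config$mirnas_fasta),
         se = readExpressionTsv(config$expression_tsv,
                                config$sample_map_tsv))
  })

  expressedTEs <- stage("expression_filter", {
    ids <- intersect(expressedFilter(inp$se, config$rpkm_threshold),
                     names(inp$tes))
    emit(data.frame(te_id = ids, stringsAsFactors = FALSE),
         "expressed_tes.tsv")
    ids
  })

  sites <- stage("site_scan", {
    teSites <- scanTranscripts(inp$tes[expressedTEs], inp$mirnas,
                               cutoff = config$expectation_cutoff,
                               central_window = config$central_window)
    geneSites <- scanTranscripts(inp$genes, inp$mirnas,
                                 cutoff = config$expectation_cutoff,
                                 central_window = config$central_window)
    emit(sitesTable(teSites), "te_sites.tsv")
    emit(sitesTable(geneSites), "gene_sites.tsv")
    list(te = sitesTable(teSites), gene = sitesTable(geneSites),
         teObjs = teSites)
  })

  patches <- stage("homology", {
    combos <- unique(merge(
      unique(sites$te[, c("transcript_id", "mirna_id")]),
      unique(sites$gene[, c("transcript_id", "mirna_id")]),
      by = "mirna_id", suffixes = c("_te", "_gene")
    )[, c("transcript_id_te", "transcript_id_gene")])
    res <- list()
    if (nrow(combos))
      for (k in seq_len(nrow(combos))) {
        tid <- combos$transcript_id_te[k]
        gid <- combos$transcript_id_gene[k]
        res[[k]] <- findPatches(inp$tes[[tid]], inp$genes[[gid]],
                                min_score = config$min_patch_score,
                                te_id = tid, gene_id = gid)
      }
    out <- if (length(res)) do.call(rbind, res) else
      findPatches("ACGT", "ACGT", te_id = "x", gene_id = "x")[0, ]
    out <- out[order(out$te_id, out$gene_id, -out$score), , drop = FALSE]
    rownames(out) <- NULL
    emit(out, "patches.tsv")
    out
  })

  pairing <- stage("pairing", {
    pr <- buildPairs(sites$te, sites$gene, patches, inp$se,
                     r_threshold = config$r_threshold)
    emit(pr$pairs, "pairs.tsv")
    emit(pr$counts, "pair_counts.tsv")
    pr
  })

  degCalls <- NULL
  if (!is.null(config$degradome_tsv)) {
    degCalls <- stage("degradome", {
      lens <- nchar(c(inp$tes, inp$genes))
      profiles <- readDegradomeTsv(config$degradome_tsv, lens)
      calls <- list()
      for (ts in sites$teObjs) {
        tid <- ts@duplex@transcriptId
        prof <- profiles[[tid]]
        if (is.null(prof) || sum(prof@counts) == 0L) next
        calls[[length(calls) + 1L]] <- callCleavage(
          prof, ts, tolerance = config$degradome_tolerance)
      }
      tab <- cleavageTable(calls)
      emit(tab, "degradome_calls.tsv")
      tab
    })
  }

  report <- stage("report", {
    mimicTab <- sites$te[sites$te$mimicry_class == "mimic", , drop = FALSE]
    rows <- list()
    for (tid in unique(mimicTab$transcript_id)) {
      if (!tid %in% expressedTEs) next
      myPairs <- pairing$pairs[pairing$pairs$te_id == tid &
                                 pairing$pairs$pass_threshold, ,
                               drop = FALSE]
      if (nrow(myPairs) == 0L) next
      mine <- mimicTab[mimicTab$transcript_id == tid, , drop = FALSE]
      supported <- NA
      if (!is.null(degCalls) && nrow(degCalls)) {
        dc <- degCalls[degCalls$transcript_id == tid &
                         degCalls$mirna_id %in% mine$mirna_id, ,
                       drop = FALSE]
        if (nrow(dc)) supported <- any(dc$supports_cleavage)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        te_id = tid,
        mirna_ids = paste(sort(unique(mine$mirna_id)), collapse = ","),
        n_correlated_partners = nrow(myPairs),
        partner_genes = paste(sort(myPairs$gene_id), collapse = ","),
        best_expectation = min(mine$expectation),
        max_r = max(myPairs$r),
        degradome_supports_cleavage = supported,
        status = if (isTRUE(supported)) "cleaved" else "candidate_mimic",
        stringsAsFactors = FALSE)
    }
    rep <- if (length(rows)) do.call(rbind, rows) else
      data.frame(te_id = character(), mirna_ids = character(),
                 n_correlated_partners = integer(),
                 partner_genes = character(), best_expectation = numeric(),
                 max_r = numeric(), degradome_supports_cleavage = logical(),
                 status = character(), stringsAsFactors = FALSE)
    rep <- rep[order(rep$status != "candidate_mimic",
                     -rep$n_correlated_partners, rep$best_expectation,
                     rep$te_id), , drop = FALSE]
    rep$rank <- ifelse(rep$status == "candidate_mimic",
                       cumsum(rep$status == "candidate_mimic"), NA_integer_)
    rownames(rep) <- NULL
    emit(rep, "report.tsv")
    rep
  })

  writeManifest(dir, written, config, TRUE)
  list(report = report, pairs = pairing$pairs, counts = pairing$counts,
       te_sites = sites$te, gene_sites = sites$gene, patches = patches,
       degradome_calls = degCalls,
       files = c(written, file.path(dir, "MANIFEST.json")))
}
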