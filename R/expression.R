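#' Build an RPKM expression matrix
#'
#' RPKM = count / ((length/1000) x (library_size/1e6)). The result is a
#' \code{SummarizedExperiment} with one assay \code{"rpkm"}, transcript
#' lengths in \code{rowData} and the sample-to-tissue map in
#' \code{colData$tissue}.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param lengths transcript lengths in nt (named or in row order; > 0).
#' @param library_sizes mapped reads per sample (named or in column order;
#'   > 0).
#' @param sample_tissue named character vector mapping sample ids to
#'   tissues; defaults to one tissue per sample.
#' @return a \code{SummarizedExperiment}.
#' @export
rpkmMatrix <- function(counts, lengths, library_sizes,
                       sample_tissue = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (!is.null(names(library_sizes)) && !is.null(colnames(counts)))
    library_sizes <- library_sizes[colnames(counts)]
  if (any(lengths <= 0) || anyNA(lengths)) stop("lengths must be > 0")
  if (any(library_sizes <= 0) || anyNA(library_sizes))
    stop("library sizes must be > 0")
  rpkm <- sweep(counts, 1L, lengths / 1000, "/")
  rpkm <- sweep(rpkm, 2L, library_sizes / 1e6, "/")
  if (is.null(sample_tissue))
    sample_tissue <- setNames(colnames(counts), colnames(counts))
  if (!is.null(colnames(counts)) &&
      !all(colnames(counts) %in% names(sample_tissue)))
    stop("every sample must be mapped to a tissue")
  asExpressionSE(rpkm, lengths,
                 sample_tissue[colnames(rpkm)])
}

# wrap an RPKM matrix into the canonical SummarizedExperiment container
asExpressionSE <- function(rpkm, lengths = NULL, tissue = NULL) {
  if (any(rpkm < 0)) stop("RPKM values must be non-negative")
  if (anyDuplicated(rownames(rpkm))) stop("duplicate transcript ids")
  if (is.null(tissue)) tissue <- colnames(rpkm)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = rpkm),
    rowData = S4Vectors::DataFrame(
      length = if (is.null(lengths)) rep(NA_integer_, nrow(rpkm))
               else unname(lengths), row.names = rownames(rpkm)),
    colData = S4Vectors::DataFrame(tissue = unname(tissue),
                                   row.names = colnames(rpkm)))
}

#' Read an expression matrix from TSV
#'
#' Expects a header row with \code{transcript_id} followed by sample ids,
#' and optionally a sample map TSV (columns sample_id, tissue).
#'
#' @param path expression TSV.
#' @param sample_map_path optional sample-to-tissue TSV.
#' @return a \code{SummarizedExperiment} (assay \code{"rpkm"}).
#' @export
readExpressionTsv <- function(path, sample_map_path = NULL) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  tissue <- colnames(m)
  if (!is.null(sample_map_path)) {
    sm <- readTsv(sample_map_path)
    if (!all(colnames(m) %in% sm$sample_id))
      stop("sample map is missing samples present in the matrix")
    tissue <- sm$tissue[match(colnames(m), sm$sample_id)]
  }
  asExpressionSE(m, tissue = tissue)
}

#' Expressed-transcript filter
#'
#' Retains transcripts whose maximum RPKM across all samples strictly
#' exceeds the threshold (the "maximal RPKM > 1" rule used to call a TE
#' transcribed).
#'
#' @param se \code{SummarizedExperiment} with an \code{"rpkm"} assay.
#' @param threshold RPKM threshold (default 1; strict inequality).
#' @return character vector of retained transcript ids.
#' @export
expressedFilter <- function(se, threshold = 1) {
  if (threshold < 0) stop("threshold must be >= 0")
  m <- SummarizedExperiment::assay(se, "rpkm")
  rownames(m)[apply(m, 1L, max) > threshold]
}

#' Pearson correlation of two expression profiles
#'
#' Standard product-moment correlation; errors on constant input rather
#' than returning NA so that degenerate pairs are skipped explicitly.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector")
  cor(x, y, method = "pearson")
}

#' Tissue-mean expression
#'
#' Averages replicate samples within each tissue (columns collapse to one
#' per tissue, in first-appearance order).
#'
#' @param se \code{SummarizedExperiment} with an \code{"rpkm"} assay and
#'   \code{colData$tissue}.
#' @return matrix transcripts x tissues.
#' @export
tissueMeans <- function(se) {
  m <- SummarizedExperiment::assay(se, "rpkm")
  tissue <- SummarizedExperiment::colData(se)$tissue
  lev <- unique(tissue)
  out <- vapply(lev, function(t)
    rowMeans(m[, tissue == t, drop = FALSE]), numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m),
                                       dimnames = list(rownames(m), lev))
  colnames(out) <- lev
  out
}

#' Assemble TE-gene candidate pairs
#'
#' A TE and a gene form a candidate pair when (i) each carries at least one
#' predicted binding site for the same miRNA and (ii) they share at least
#' one homology patch. The pair's orientation is that of the
#' highest-scoring shared patch; its correlation r is the Pearson
#' correlation of tissue-mean expression, by default on the log2(RPKM + 1)
#' scale. Pairs whose expression is constant are skipped with a warning.
#'
#' @param te_sites,gene_sites lists of \linkS4class{TargetSite} (or tables
#'   from \code{\link{sitesTable}}) for TE and gene transcripts.
#' @param patches data.frame from \code{\link{findPatches}}.
#' @param se expression \code{SummarizedExperiment} containing every TE and
#'   gene id.
#' @param r_threshold correlation threshold for the pass flag (default
#'   0.5).
#' @param log_transform correlate log2(RPKM + 1) (default) or raw RPKM.
#' @return list with \code{pairs} (data.frame te_id, gene_id, orientation,
#'   shared_mirnas, r, pass_threshold, sorted by te_id then gene_id) and
#'   \code{counts} (data.frame orientation, n_pairs, n_above_threshold).
#' @export
buildPairs <- function(te_sites, gene_sites, patches, se,
                       r_threshold = 0.5, log_transform = TRUE) {
  tab <- function(x) if (is.data.frame(x)) x else sitesTable(x)
  teTab <- tab(te_sites); geneTab <- tab(gene_sites)
  tm <- tissueMeans(se)
  if (log_transform) tm <- log2(tm + 1)
  rows <- list()
  if (nrow(teTab) && nrow(geneTab) && nrow(patches)) {
    key <- paste(patches$te_id, patches$gene_id)
    for (combo in unique(key)) {
      p <- patches[key == combo, , drop = FALSE]
      teId <- p$te_id[1L]; geneId <- p$gene_id[1L]
      shared <- intersect(teTab$mirna_id[teTab$transcript_id == teId],
                          geneTab$mirna_id[geneTab$transcript_id == geneId])
      if (length(shared) == 0L) next
      if (!teId %in% rownames(tm) || !geneId %in% rownames(tm))
        stop("pair ids missing from the expression matrix: ", teId, "/",
             geneId)
      r <- tryCatch(pearson(tm[teId, ], tm[geneId, ]), error = function(e) {
        warning("skipping pair ", teId, "/", geneId, ": ",
                conditionMessage(e))
        NA_real_
      })
      if (is.na(r)) next
      best <- p[which.max(p$score), ]
      rows[[length(rows) + 1L]] <- data.frame(
        te_id = teId, gene_id = geneId, orientation = best$orientation,
        shared_mirnas = paste(sort(shared), collapse = ","), r = r,
        pass_threshold = r > r_threshold, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(te_id = character(), gene_id = character(),
               orientation = character(), shared_mirnas = character(),
               r = numeric(), pass_threshold = logical(),
               stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$te_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  counts <- do.call(rbind, lapply(c("sense", "antisense"), function(o) {
    sub <- pairs[pairs$orientation == o, , drop = FALSE]
    data.frame(orientation = o, n_pairs = nrow(sub),
               n_above_threshold = sum(sub$pass_threshold),
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, counts = counts)
}
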