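smallConfig <- function(seed = 1L, ...) {
  simConfig(seed = seed, n_genes = 24L, n_tes = 16L, n_mirnas = 5L,
            n_tissues = 8L, replicates_per_tissue = 2L,
            transcript_length_range = c(400L, 800L), ...)
}

test_that("identical seed and config give byte-identical output files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulateDataset(smallConfig(seed = 9L), d1)
  s2 <- simulateDataset(smallConfig(seed = 9L), d2)
  for (f in names(s1$files))
    expect_equal(unname(tools::md5sum(s1$files[[f]])),
                 unname(tools::md5sum(s2$files[[f]])), label = f)
  # and a different seed changes the data
  s3 <- simulateDataset(smallConfig(seed = 10L), withr::local_tempdir())
  expect_false(unname(tools::md5sum(s3$files[["genes"]])) ==
                 unname(tools::md5sum(s1$files[["genes"]])))
})

test_that("planted fractions control the emitted truth", {
  s0 <- simulateDataset(smallConfig(planted_mimic_fraction = 0))
  expect_equal(nrow(slot(s0$truth, "mimicSites")), 0L)
  expect_equal(nrow(slot(s0$truth, "plantedPairs")), 0L)

  s <- simulateDataset(smallConfig(planted_mimic_fraction = 0.5))
  truth <- s$truth
  expect_equal(nrow(slot(truth, "mimicSites")), 8L)
  # every planted id exists in the emitted sequence sets, every interval
  # within bounds
  ms <- slot(truth, "mimicSites")
  expect_true(all(ms$te_id %in% names(s$tes)))
  expect_true(all(ms$end <= nchar(s$tes[ms$te_id])))
  cs <- slot(truth, "cleavableSites")
  expect_true(all(cs$gene_id %in% names(s$genes)))
  expect_true(all(cs$end <= nchar(s$genes[cs$gene_id])))
})

test_that("truth JSON round-trips losslessly", {
  dir <- withr::local_tempdir()
  s <- simulateDataset(smallConfig(), dir)
  reread <- readTruth(file.path(dir, "truth.json"))
  for (sl in c("mimicSites", "cleavableSites", "plantedPairs", "ltrTruth"))
    expect_equal(slot(reread, sl), slot(s$truth, sl), label = sl)

  # empty truth round-trips too
  empty <- simulateDataset(smallConfig(planted_mimic_fraction = 0,
                                       planted_cleavable_fraction = 0))
  p <- file.path(dir, "empty.json")
  writeTruth(empty$truth, p)
  re <- readTruth(p)
  expect_equal(nrow(slot(re, "mimicSites")), 0L)
  expect_equal(slot(re, "cleavableSites"),
               slot(empty$truth, "cleavableSites"))
})

test_that("planted sites close the loop with the scanner", {
  s <- simulateDataset(smallConfig(seed = 3L))
  ms <- slot(s$truth, "mimicSites")
  cs <- slot(s$truth, "cleavableSites")
  teTab <- sitesTable(scanTranscripts(s$tes[unique(ms$te_id)], s$mirnas))
  for (k in seq_len(nrow(ms))) {
    row <- teTab[teTab$transcript_id == ms$te_id[k] &
                   teTab$mirna_id == ms$mirna_id[k] &
                   teTab$start == ms$start[k], , drop = FALSE]
    expect_equal(nrow(row), 1L)
    expect_equal(row$mimicry_class, "mimic")
    expect_lte(row$expectation, 3.0)
  }
  geneTab <- sitesTable(scanTranscripts(s$genes[unique(cs$gene_id)],
                                        s$mirnas))
  for (k in seq_len(nrow(cs))) {
    row <- geneTab[geneTab$transcript_id == cs$gene_id[k] &
                     geneTab$mirna_id == cs$mirna_id[k] &
                     geneTab$start == cs$start[k], , drop = FALSE]
    expect_equal(nrow(row), 1L)
    expect_equal(row$mimicry_class, "cleavable")
  }
})

test_that("planted pair correlation calibration converges to the target", {
  s <- simulateDataset(simConfig(seed = 8L, n_genes = 60L, n_tes = 50L,
                                 n_mirnas = 8L, silent_te_fraction = 0,
                                 planted_mimic_fraction = 1,
                                 planted_cleavable_fraction = 1,
                                 target_correlation = 0.9))
  tm <- log2(tissueMeans(s$expression) + 1)
  pp <- slot(s$truth, "plantedPairs")
  rs <- mapply(function(t, g) cor(tm[t, ], tm[g, ]), pp$te_id, pp$gene_id)
  expect_gt(length(rs), 40)
  expect_lt(abs(mean(rs) - 0.9), 0.06)
})

test_that("silent TEs stay below the expression filter, expressed pass it", {
  s <- simulateDataset(smallConfig(seed = 12L))
  expressed <- expressedFilter(s$expression, 1)
  expect_true(all(s$expressed_te_ids %in% expressed))
  expect_false(any(s$silent_te_ids %in% expressed))
})

test_that("degradome truth separates cleavable peaks from mimic background", {
  s <- simulateDataset(smallConfig(seed = 21L))
  cs <- slot(s$truth, "cleavableSites")
  regCounts <- vapply(seq_len(nrow(cs)), function(k)
    slot(s$degradome[[cs$gene_id[k]]], "counts")[cs$end[k] - 9L],
    integer(1))
  # a detected cleavage pile-up always has read support
  expect_true(all(regCounts >= 2L))
  # mean register count is enrichment x background
  cfg <- s$config
  expect_lt(abs(mean(regCounts) -
                  slot(cfg, "degradomePeakEnrichment") *
                  slot(cfg, "degradomeBackground")), 2)
  # mimic-site profiles are background only: sparse, low counts
  ms <- slot(s$truth, "mimicSites")
  mimicCnt <- unlist(lapply(unique(ms$te_id), function(id)
    slot(s$degradome[[id]], "counts")))
  expect_lt(mean(mimicCnt), 0.3)
  expect_lt(max(mimicCnt), 6)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(n_genes = 0), "counts")
  expect_error(simConfig(planted_mimic_fraction = 1.2), "fractions")
  expect_error(simConfig(transcript_length_range = c(25, 20)),
               "lengthRange")
  expect_error(simConfig(ltr_rate = 0), "ltrRate")
  expect_error(simConfig(degradome_peak_enrichment = 0.5), "Enrichment|>= 1")
  expect_error(simulateLTRPairs(2, age = -5, rate = 1.3e-8), "non-negative")
})
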