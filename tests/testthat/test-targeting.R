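test_that("duplex expectation follows the penalty scheme on forced cases", {
  set.seed(101)
  mir <- randSeq(21)
  site <- rcSeq(mir)
  m <- strsplit(mir, "")[[1]]

  d0 <- scoreDuplex(mir, site)
  expect_equal(expectation(d0), 0)
  expect_true(all(slot(d0, "states") == "match"))

  # one G:U wobble at miRNA position 15 (outside seed) -> 0.5; force a
  # wobble-capable base first
  mir2 <- mir; substr(mir2, 15, 15) <- "G"
  site2 <- rcSeq(mir2); idx <- 21 - 15 + 1
  substr(site2, idx, idx) <- "T"
  expect_equal(expectation(scoreDuplex(mir2, site2)), 0.5)

  # one mismatch at miRNA position 5 (inside seed) -> 2.0
  site3 <- siteWithMismatches(mir, 5)
  d3 <- scoreDuplex(mir, site3)
  expect_equal(expectation(d3), 2.0)
  expect_equal(slot(d3, "states")[5], "mismatch")

  # RNA (U) and DNA (T) representations score identically
  mirU <- chartr("T", "U", mir)
  expect_equal(expectation(scoreDuplex(mirU, site3)), expectation(d3))
})

test_that("expectation is monotone in added mismatches", {
  set.seed(202)
  for (rep in 1:20) {
    mir <- randSeq(21)
    site <- rcSeq(mir)
    prev <- expectation(scoreDuplex(mir, site))
    positions <- sample(3:19, 4)
    for (k in seq_along(positions)) {
      site <- siteWithMismatches(mir, positions[seq_len(k)])
      e <- expectation(scoreDuplex(mir, site))
      expect_gte(e, prev)
      prev <- e
    }
  }
})

test_that("mimicry classification keys on the central window", {
  set.seed(303)
  mir <- randSeq(21)

  perfect <- classifyMimicry(scoreDuplex(mir, rcSeq(mir)))
  expect_equal(mimicryClass(perfect), "cleavable")
  expect_length(centralDefects(perfect), 0)

  # MIKKI-style: mismatches at positions 11 and 14; only 11 is central
  mikki <- classifyMimicry(scoreDuplex(mir, siteWithMismatches(mir, c(11, 14))))
  expect_equal(mimicryClass(mikki), "mimic")
  expect_equal(centralDefects(mikki), 11L)

  # IPS1-style: 3-nt target bulge between positions 10 and 11
  site <- rcSeq(mir)
  bulged <- paste0(substr(site, 1, 11), "AAA", substr(site, 12, 21))
  # force the insertion to be recognisable: bulge bases cannot pair
  ips <- classifyMimicry(scoreDuplex(mir, bulged))
  expect_equal(mimicryClass(ips), "mimic")

  # a defect-free duplex with wobbles stays cleavable
  mir2 <- mir; substr(mir2, 10, 10) <- "G"
  s2 <- rcSeq(mir2); substr(s2, 12, 12) <- "T"   # wobble at position 10
  wob <- classifyMimicry(scoreDuplex(mir2, s2))
  expect_equal(mimicryClass(wob), "cleavable")

  expect_error(classifyMimicry(scoreDuplex(mir, rcSeq(mir)),
                               central_window = c(0, 5)))
})

test_that("scan finds embedded perfect sites exactly once", {
  set.seed(404)
  mir <- randSeq(21)
  tx <- embedSite(randSeq(500), rcSeq(mir), 101)
  sites <- scanTranscripts(c(tx1 = tx), c(m1 = mir))
  tab <- sitesTable(sites)
  perfectHits <- tab[tab$expectation == 0, ]
  expect_equal(nrow(perfectHits), 1L)
  expect_equal(perfectHits$start, 101L)
  expect_equal(perfectHits$end, 121L)
  # non-overlap: no other retained site may touch the perfect interval
  others <- tab[tab$expectation > 0, ]
  if (nrow(others))
    expect_true(all(others$end < 101 | others$start > 121))
})

test_that("poly-A transcript yields no sites for a C/G-containing miRNA", {
  tx <- paste(rep("A", 500), collapse = "")
  mir <- paste(c(rep("G", 10), rep("C", 11)), collapse = "")
  expect_length(scanTranscripts(c(t = tx), c(m = mir)), 0)
})

test_that("scan equals the exhaustive enumeration oracle", {
  set.seed(505)
  for (rep in 1:12) {
    mir <- randSeq(21)
    tx <- randSeq(200)
    # plant one mimic-type site so non-trivial hits exist in most reps
    if (rep %% 2 == 0)
      tx <- embedSite(tx, siteWithMismatches(mir, c(11, 14)), 50)
    got <- sitesTable(scanTranscripts(c(t = tx), c(m = mir)))
    want <- oracleScan(tx, mir)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      got <- got[order(got$start), ]
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$expectation, want$score)
      expect_equal(got$mimicry_class == "mimic", want$mimic)
    }
  }
})

test_that("site table orientation and U/T plumbing are invariant", {
  set.seed(606)
  mir <- randSeq(21)
  tx <- embedSite(randSeq(300), siteWithMismatches(mir, 11), 120)
  a <- sitesTable(scanTranscripts(c(t = tx), c(m = mir)))
  b <- sitesTable(scanTranscripts(c(t = chartr("T", "U", tx)),
                                  c(m = chartr("T", "U", mir))))
  expect_identical(a, b)
})

test_that("scoreDuplex rejects invalid inputs", {
  mir <- paste(rep("ACGT", 6), collapse = "")  # 24 nt, upper bound ok
  expect_error(scoreDuplex("ACGT", "ACGT"), "19-24")
  expect_error(scoreDuplex(mir, paste(rep("A", 30), collapse = "")),
               "within the miRNA length")
  expect_error(scoreDuplex(substr(mir, 1, 21), "ACGTNACGTNACGTNACGTNA"),
               "alphabet")
})
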