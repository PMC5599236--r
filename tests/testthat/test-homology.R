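test_that("verbatim gene blocks are found as sense/antisense patches", {
  set.seed(11)
  gene <- randSeq(600)
  block <- substr(gene, 201, 300)
  te <- embedSite(randSeq(500), block, 151)

  p <- findPatches(te, gene, te_id = "te", gene_id = "g")
  sense <- p[p$orientation == "sense", ]
  expect_gte(nrow(sense), 1L)
  top <- sense[1, ]
  # the top patch covers the verbatim block (chance matches in the random
  # context may extend it by a base or two)
  expect_gte(top$length, 100L)
  expect_lte(top$length, 104L)
  expect_gte(top$identity, 0.98)
  expect_lte(top$te_start, 151L); expect_gte(top$te_end, 250L)
  expect_lte(top$gene_start, 201L); expect_gte(top$gene_end, 300L)
  expect_gte(top$score, 100L)

  te2 <- embedSite(randSeq(500), rcSeq(block), 151)
  p2 <- findPatches(te2, gene)
  expect_equal(p2$orientation[1], "antisense")
  expect_gte(p2$length[1], 100L)
  expect_lte(p2$gene_start[1], 201L); expect_gte(p2$gene_end[1], 300L)
})

test_that("reverse-complementing the gene swaps orientation labels", {
  set.seed(22)
  gene <- randSeq(400)
  te <- embedSite(randSeq(400), substr(gene, 101, 160), 201)
  a <- findPatches(te, gene)
  b <- findPatches(te, rcSeq(gene))
  expect_equal(sort(a$score[a$orientation == "sense"]),
               sort(b$score[b$orientation == "antisense"]))
  expect_equal(sort(a$score[a$orientation == "antisense"]),
               sort(b$score[b$orientation == "sense"]))
})

test_that("patch scores are symmetric in the two sequences", {
  set.seed(33)
  gene <- randSeq(350)
  te <- embedSite(randSeq(300), substr(gene, 50, 120), 101)
  a <- findPatches(te, gene)
  b <- findPatches(gene, te)
  expect_equal(sort(a$score), sort(b$score))
})

test_that("patches match an independent dynamic-programming oracle", {
  set.seed(44)
  for (rep in 1:6) {
    gene <- randSeq(300)
    te <- randSeq(250)
    if (rep %% 2 == 0) {
      blk <- substr(gene, 40, 40 + 59)
      # add a couple of point differences so gaps/mismatches exercise
      substr(blk, 20, 20) <- "A"; substr(blk, 41, 41) <- "C"
      te <- embedSite(te, blk, 100)
    }
    got <- findPatches(te, gene, min_score = 15)
    got <- got[got$orientation == "sense", ]
    want <- oracleSW(te, gene, min_score = 15)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(sort(got$score), sort(want$score))
      expect_equal(sort(got$te_start), sort(want$a_start))
      expect_equal(sort(got$gene_start), sort(want$b_start))
    }
  }
})

test_that("top patch score agrees with Biostrings local alignment", {
  set.seed(55)
  gene <- randSeq(400)
  te <- embedSite(randSeq(300), substr(gene, 100, 190), 120)
  got <- findPatches(te, gene)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(te), Biostrings::DNAString(gene), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2),
    gapOpening = 4, gapExtension = 1)
  expect_equal(got$score[1], Biostrings::score(al))
})

test_that("patch summary reports group fractions and length bias", {
  set.seed(66)
  n <- 400
  groups <- setNames(rep(c("expressed", "silent"), each = n / 2),
                     sprintf("TE%03d", 1:n))
  # plant patches in 64% of expressed and 41% of silent TEs; sense patches
  # longer than antisense
  rows <- list()
  for (i in seq_len(n)) {
    g <- groups[i]
    frac <- if (g == "expressed") 0.64 else 0.41
    if (runif(1) < frac) {
      ori <- if (runif(1) < 0.7) "sense" else "antisense"
      len <- if (ori == "sense") sample(80:150, 1) else sample(25:60, 1)
      rows[[length(rows) + 1]] <- data.frame(
        te_id = names(groups)[i], gene_id = "g", orientation = ori,
        te_start = 1, te_end = len, gene_start = 1, gene_end = len,
        length = len, identity = 1, score = len,
        stringsAsFactors = FALSE)
    }
  }
  patches <- do.call(rbind, rows)
  s <- patchSummary(patches, groups)
  fe <- s$fractions$fraction[s$fractions$group == "expressed"]
  fs <- s$fractions$fraction[s$fractions$group == "silent"]
  expect_lt(abs(fe - 0.64), 0.08)
  expect_lt(abs(fs - 0.41), 0.08)
  expect_gt(s$length_summary$median_length[
    s$length_summary$orientation == "sense"],
    s$length_summary$median_length[
      s$length_summary$orientation == "antisense"])
  expect_lt(s$length_test$p_two_sided, 1e-6)

  # degenerate cases
  empty <- patches[0, ]
  s0 <- patchSummary(empty, groups)
  expect_true(all(s0$fractions$fraction == 0))
  expect_true(all(s0$length_summary$n == 0))
  expect_null(s0$length_test)
  allTE <- patchSummary(patches, groups[unique(patches$te_id)])
  expect_true(all(allTE$fractions$fraction == 1))
})
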