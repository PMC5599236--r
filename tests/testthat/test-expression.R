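test_that("rpkm matches its definition and scales as expected", {
  counts <- matrix(c(10, 0, 50), nrow = 3,
                   dimnames = list(c("a", "b", "c"), "s1"))
  se <- rpkmMatrix(counts, lengths = c(a = 1000, b = 500, c = 2000),
                   library_sizes = c(s1 = 1e6))
  m <- SummarizedExperiment::assay(se, "rpkm")
  expect_equal(unname(m["a", 1]), 10)
  expect_equal(unname(m["b", 1]), 0)

  se2 <- rpkmMatrix(matrix(50, 1, 1, dimnames = list("x", "s")),
                    lengths = c(x = 2000), library_sizes = c(s = 5e6))
  expect_equal(unname(SummarizedExperiment::assay(se2)[1, 1]), 5)

  # linear in counts, inverse in length and library size
  set.seed(1)
  cnt <- matrix(rpois(20, 50), 5, 4,
                dimnames = list(paste0("t", 1:5), paste0("s", 1:4)))
  lens <- setNames(sample(500:2000, 5), rownames(cnt))
  libs <- setNames(sample(1e6:5e6, 4), colnames(cnt))
  m1 <- SummarizedExperiment::assay(rpkmMatrix(cnt, lens, libs))
  m2 <- SummarizedExperiment::assay(rpkmMatrix(3 * cnt, lens, libs))
  expect_equal(m2, 3 * m1)
  m3 <- SummarizedExperiment::assay(rpkmMatrix(cnt, 2 * lens, libs))
  expect_equal(m3, m1 / 2)
  m4 <- SummarizedExperiment::assay(rpkmMatrix(cnt, lens, 2 * libs))
  expect_equal(m4, m1 / 2)

  expect_error(rpkmMatrix(cnt, lens * 0, libs), "lengths")
  expect_error(rpkmMatrix(cnt, lens, libs * 0), "library")
})

test_that("expressed filter applies a strict maximum-RPKM rule", {
  m <- rbind(zero = c(0, 0, 0), at = c(1, 1, 1), just = c(0.2, 1.001, 0.1),
             high = c(50, 2, 0))
  colnames(m) <- paste0("s", 1:3)
  se <- TEmimic:::asExpressionSE(m)
  expect_setequal(expressedFilter(se, 1), c("just", "high"))
  expect_false("at" %in% expressedFilter(se, 1))   # strict inequality
  expect_setequal(expressedFilter(se, 0), c("at", "just", "high"))
})

test_that("pearson matches the product-moment definition", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  # frozen from the definition: cov = 3/4 * 4, var = 5 each -> r = 3/5
  expect_equal(pearson(x, y), 0.6)
  expect_equal(pearson(x, x), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  # affine invariance with positive slope
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson(a, b), pearson(2 * a + 3, b))
  expect_equal(pearson(a, b), -pearson(-a, b))
  expect_error(pearson(a, rep(1, 20)), "constant")
  expect_error(pearson(a, b[1:10]), "equal length")
})

test_that("planted expression rows pass the filter exactly", {
  set.seed(3)
  n <- 100
  above <- sample(n, 40)
  m <- matrix(runif(n * 6, 0, 0.9), n, 6,
              dimnames = list(sprintf("t%03d", 1:n), paste0("s", 1:6)))
  m[above, 3] <- runif(40, 1.5, 30)
  se <- TEmimic:::asExpressionSE(m)
  expect_setequal(expressedFilter(se, 1), rownames(m)[above])
})

test_that("buildPairs joins sites, patches and correlation correctly", {
  set.seed(4)
  # two TEs, two genes; TE1/gene1 share miR1 and a patch and are
  # correlated; TE2/gene2 share miR2 and a patch but are uncorrelated;
  # TE1/gene2 share nothing
  tissues <- sprintf("ti%02d", 1:8)
  shared <- rnorm(8, 6, 2)
  m <- rbind(TE1 = 2^(shared + rnorm(8, 0, 0.3)),
             gene1 = 2^(shared + rnorm(8, 0, 0.3)),
             TE2 = 2^rnorm(8, 6, 2), gene2 = 2^rnorm(8, 6, 2))
  colnames(m) <- tissues
  se <- TEmimic:::asExpressionSE(m)
  mkSite <- function(tx, mir) data.frame(
    mirna_id = mir, transcript_id = tx, start = 1, end = 21,
    expectation = 2, n_wobble = 0, n_mismatch = 1, bulge_len = 0,
    mimicry_class = "mimic", central_defects = "11",
    stringsAsFactors = FALSE)
  teSites <- rbind(mkSite("TE1", "miR1"), mkSite("TE2", "miR2"))
  geneSites <- rbind(mkSite("gene1", "miR1"), mkSite("gene2", "miR2"))
  patches <- data.frame(
    te_id = c("TE1", "TE2"), gene_id = c("gene1", "gene2"),
    orientation = c("sense", "antisense"), te_start = 1, te_end = 60,
    gene_start = 1, gene_end = 60, length = 60, identity = 1,
    score = c(60, 40), stringsAsFactors = FALSE)

  res <- buildPairs(teSites, geneSites, patches, se, r_threshold = 0.5)
  expect_equal(nrow(res$pairs), 2L)
  p1 <- res$pairs[res$pairs$te_id == "TE1", ]
  expect_true(p1$pass_threshold)
  expect_equal(p1$orientation, "sense")
  expect_equal(p1$shared_mirnas, "miR1")

  # no shared miRNAs -> no pairs even with patches
  res0 <- buildPairs(mkSite("TE1", "miRx"), geneSites, patches, se)
  expect_equal(nrow(res0$pairs), 0L)

  # counts table split by orientation
  expect_setequal(res$counts$orientation, c("sense", "antisense"))
  expect_equal(sum(res$counts$n_pairs), 2L)

  # input order does not matter
  res2 <- buildPairs(teSites[2:1, ], geneSites[2:1, ], patches[2:1, ], se)
  expect_identical(res$pairs, res2$pairs)
})

test_that("tissue means collapse replicates before correlation", {
  m <- matrix(c(1, 3, 10, 30, 2, 2, 20, 20), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"),
                              c("t1_r1", "t1_r2", "t2_r1", "t2_r2")))
  se <- TEmimic:::asExpressionSE(m, tissue = c("t1", "t1", "t2", "t2"))
  tm <- tissueMeans(se)
  expect_equal(dim(tm), c(2L, 2L))
  expect_equal(unname(tm["a", ]), c(2, 20))
  expect_equal(unname(tm["b", ]), c(2, 20))
})
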