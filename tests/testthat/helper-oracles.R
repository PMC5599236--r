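# Independent brute-force oracles and small sequence helpers.
# These deliberately share no code with the package internals: scoring and
# alignment are re-derived from first principles so the package can be
# checked against them.

BASES <- c("A", "C", "G", "T")

rcSeq <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# --- duplex expectation oracle ------------------------------------------
# Exhaustive enumeration of every window configuration: bulge-free, one
# target bulge of 1..3 nt at every insertion point, one miRNA bulge of
# 1..3 nt at every internal position. Penalties: match 0, G:U wobble 0.5,
# mismatch 1, gap 2 per bulged base, doubled at miRNA positions 2-13.

oraclePenaltyTable <- local({
  # pen[m, s]: base penalty of pairing miRNA base m with site base s
  pen <- matrix(1, 4, 4, dimnames = list(BASES, BASES))
  pen["A", "T"] <- 0; pen["C", "G"] <- 0; pen["G", "C"] <- 0
  pen["T", "A"] <- 0
  pen["G", "T"] <- 0.5; pen["T", "G"] <- 0.5
  pen
})

oracleSeedMult <- function(pos) ifelse(pos >= 2 & pos <= 13, 2, 1)

# score one configuration; returns list(score, central_defect) where
# central_defect is TRUE when a mismatch or bulge touches miRNA positions
# 9-12 (the target-bulge insertion point counts at the next paired miRNA
# position)
oracleConfigScore <- function(mirChars, siteChars, d, j) {
  M <- length(mirChars); L <- length(siteChars)
  score <- 0; defect <- FALSE
  central <- function(p) p >= 9 && p <= 12
  if (d > 0) {
    score <- score + d * 2 * oracleSeedMult(j)
    if (central(j)) defect <- TRUE
  }
  for (i in seq_len(M)) {
    if (d < 0 && i >= j && i < j - d) {   # bulged miRNA base
      score <- score + 2 * oracleSeedMult(i)
      if (central(i)) defect <- TRUE
      next
    }
    sidx <- if (d == 0) L - i + 1
            else if (d > 0) { if (i < j) L - i + 1 else L - i + 1 - d }
            else { if (i < j) L - i + 1 else L - i + 1 - d }
    p <- oraclePenaltyTable[mirChars[i], siteChars[sidx]]
    score <- score + p * oracleSeedMult(i)
    if (p == 1 && central(i)) defect <- TRUE
  }
  list(score = score, defect = defect)
}

# best expectation for a fixed site window (enumeration over placements)
oracleBestScore <- function(mir, site) {
  mc <- strsplit(mir, "")[[1]]; sc <- strsplit(site, "")[[1]]
  M <- length(mc); d <- length(sc) - M
  best <- Inf; bestDefect <- NA
  cfgs <- if (d == 0) list(c(0, 0))
          else if (d > 0) lapply(2:M, function(j) c(d, j))
          else lapply(2:(M + d), function(j) c(d, j))
  for (cf in cfgs) {
    r <- oracleConfigScore(mc, sc, cf[1], cf[2])
    if (r$score < best - 1e-12) { best <- r$score; bestDefect <- r$defect }
  }
  list(score = best, defect = bestDefect)
}

# full scan oracle: every start and window length, then non-overlap
# resolution by (score, start, length)
oracleScan <- function(tx, mir, cutoff = 3, max_bulge = 3) {
  M <- nchar(mir); N <- nchar(tx)
  rows <- list()
  for (d in -max_bulge:max_bulge) {
    L <- M + d
    if (L < 1 || (d < 0 && M + d < 2)) next
    for (s in seq_len(max(0, N - L + 1))) {
      r <- oracleBestScore(mir, substr(tx, s, s + L - 1))
      if (r$score <= cutoff + 1e-9)
        rows[[length(rows) + 1]] <- data.frame(
          start = s, end = s + L - 1, score = r$score,
          mimic = r$defect)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      score = numeric(), mimic = logical()))
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$score, cand$start, cand$end - cand$start), ]
  keep <- rep(FALSE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      kk <- cand[keep, ]
      ok <- all(cand$end[k] < kk$start | cand$start[k] > kk$end)
    }
    keep[k] <- ok
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

# --- Smith-Waterman oracle ----------------------------------------------
# Plain-R affine-gap local alignment with iterative masking; gap of length
# k costs open + k * ext. Returns patches (score, intervals) best-first.

oracleSW <- function(a, b, match = 1, mismatch = -2, open = -4, ext = -1,
                     min_score = 20, max_patches = 25) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  maskA <- rep(FALSE, n); maskB <- rep(FALSE, m)
  out <- list()
  repeat {
    H <- matrix(0, n + 1, m + 1)
    E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
    F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
    for (i in 1:n) for (j in 1:m) {
      s <- if (maskA[i] || maskB[j]) -Inf else
        if (av[i] == bv[j]) match else mismatch
      E[i + 1, j + 1] <- max(H[i + 1, j] + open + ext, E[i + 1, j] + ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] + open + ext, F[i, j + 1] + ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1],
                             F[i + 1, j + 1])
    }
    best <- max(H)
    if (best < min_score || length(out) >= max_patches) break
    pos <- which(H == best, arr.ind = TRUE)
    pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE][1, ]
    i <- pos[1] - 1; j <- pos[2] - 1
    ae <- i; be <- j; state <- "H"
    while (TRUE) {
      if (state == "H") {
        if (H[i + 1, j + 1] <= 0) break
        s <- if (maskA[i] || maskB[j]) -Inf else
          if (av[i] == bv[j]) match else mismatch
        if (abs(H[i + 1, j + 1] - (H[i, j] + s)) < 1e-9) {
          i <- i - 1; j <- j - 1
        } else if (abs(H[i + 1, j + 1] - E[i + 1, j + 1]) < 1e-9) {
          state <- "E"
        } else state <- "F"
      } else if (state == "E") {
        if (abs(E[i + 1, j + 1] - (H[i + 1, j] + open + ext)) < 1e-9) {
          j <- j - 1; state <- "H"
        } else j <- j - 1
      } else {
        if (abs(F[i + 1, j + 1] - (H[i, j + 1] + open + ext)) < 1e-9) {
          i <- i - 1; state <- "H"
        } else i <- i - 1
      }
    }
    as <- i + 1; bs <- j + 1
    out[[length(out) + 1]] <- data.frame(a_start = as, a_end = ae,
                                         b_start = bs, b_end = be,
                                         score = best)
    maskA[as:ae] <- TRUE; maskB[bs:be] <- TRUE
  }
  if (!length(out))
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      score = numeric()))
  do.call(rbind, out)
}

# build a transcript with a given site embedded at position `at`
embedSite <- function(tx, site, at) {
  paste0(substr(tx, 1, at - 1), site,
         substr(tx, at + nchar(site), nchar(tx)))
}

# mutate a perfect complement site at given miRNA positions
siteWithMismatches <- function(mir, positions) {
  site <- rcSeq(mir)
  m <- strsplit(mir, "")[[1]]
  for (p in positions) {
    comp <- chartr("ACGT", "TGCA", m[p])
    wob <- switch(m[p], G = "T", T = "G", "_")
    bad <- setdiff(BASES, c(comp, wob))[1]
    idx <- nchar(mir) - p + 1
    substr(site, idx, idx) <- bad
  }
  site
}
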