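test_that("in-loop observations count midpoints and handle clipped flanks", {
  # span [0, 10000): the left flank is fully clipped, so the right flank
  # [10000, 20000) is used alone
  ls <- mkLoops("chr1", 0, 2000, 8000, 10000, raw = 5, norm = 5)
  fp <- mkPeaks("chr1", c(2000, 50000), c(2100, 50100), signal = 1)
  obs <- loopFactorObservation(ls, fp)
  expect_equal(obs$insideCount, 1)
  expect_equal(obs$flankCount, 0)
  expect_true(obs$leftClipped)

  # peak midpoint in the right flank is counted there
  fp2 <- mkPeaks("chr1", c(2000, 15000), c(2100, 15100), signal = 1)
  obs2 <- loopFactorObservation(ls, fp2)
  expect_equal(obs2$flankCount, 1)

  none <- loopFactorObservation(ls, fp[0])
  expect_equal(none$insideCount, 0)
  expect_equal(none$flankCount, 0)
})

test_that("observation counts match a brute-force midpoint scan", {
  set.seed(90)
  n <- 100
  s0 <- sort(sample(0:2e6, n))
  fp <- mkPeaks("chr1", s0, s0 + sample(100:800, n, TRUE), runif(n))
  mids <- floor((s0 + (s0 + width(fp) )) / 2)  # 0-based midpoints
  ls <- mkLoops("chr1", c(100000, 900000), c(101000, 905000),
                c(400000, 1500000), c(401000, 1501000), raw = 4, norm = 4)
  obs <- loopFactorObservation(ls, fp)
  for (i in 1:2) {
    a <- start(anchors(ls, 1))[i] - 1
    b <- end(anchors(ls, 2))[i]
    w <- b - a
    expect_equal(obs$insideCount[i], orCountMid(mids, a, b))
    expect_equal(obs$flankCount[i],
                 (orCountMid(mids, a - w, a) + orCountMid(mids, b, b + w)) / 2)
  }
})

test_that("observations are invariant under coordinate reflection", {
  set.seed(91)
  L <- 2e6
  s0 <- sort(sample(1e5:1.9e6, 50))
  fp <- mkPeaks("chr1", s0, s0 + 200, runif(50))
  ls <- mkLoops("chr1", 500000, 501000, 800000, 801000, raw = 3, norm = 3)
  obs <- loopFactorObservation(ls, fp)
  # reflect everything through L
  rs0 <- L - (s0 + 200)
  rfp <- mkPeaks("chr1", sort(rs0), sort(rs0) + 200, runif(50))
  rls <- mkLoops("chr1", L - 801000, L - 800000, L - 501000, L - 500000,
                 raw = 3, norm = 3)
  robs <- loopFactorObservation(rls, rfp)
  expect_equal(robs$insideCount, obs$insideCount)
  expect_equal(robs$flankCount, obs$flankCount)
})

test_that("signed-rank test is exact for small n and warns on all zeros", {
  # five uniformly positive differences: two-sided exact p = 2/32
  r <- wilcoxonSignedRank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
  expect_equal(r$p.value, 0.0625)
  expect_equal(unname(r$statistic), 15)
  expect_match(r$method, "exact")

  # differences symmetric under negation: W at its null mean, p ~ 1
  d <- c(1.5, -1.5, 2.5, -2.5, 3.5, -3.5)
  sym <- wilcoxonSignedRank(d, rep(0, 6))
  expect_gt(sym$p.value, 0.9)

  expect_warning(z <- wilcoxonSignedRank(rep(2, 4), rep(2, 4)), "zero")
  expect_equal(z$p.value, 1)
  expect_equal(unname(z$parameter), 0L)
})

test_that("signed-rank agrees with stats::wilcox.test on both branches", {
  set.seed(14)
  x <- rnorm(10, 0.8); y <- rnorm(10)
  ours <- wilcoxonSignedRank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p.value, ref$p.value)

  x2 <- rnorm(60, 0.3); y2 <- rnorm(60)
  ours2 <- wilcoxonSignedRank(x2, y2)
  ref2 <- stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                             correct = TRUE)
  expect_equal(ours2$p.value, ref2$p.value, tolerance = 1e-10)
})

test_that("exact enumeration and normal approximation agree for n 10..14", {
  # one-sided tails, as used by the enrichment test; two-sided mid-range
  # p-values carry twice the discretization error of the lattice
  set.seed(3)
  for (n in 10:14) {
    d <- round(rnorm(n, 0.4, 1), 6)
    pExact <- orSignedRankP(d, alternative = "greater")
    pApprox <- wilcoxonSignedRank(d, rep(0, n), exact = FALSE,
                                  alternative = "greater")$p.value
    expect_lt(abs(pExact - pApprox), 0.01)
    # and the automatic branch agrees with the enumeration oracle at n <= 12
    if (n <= 12)
      expect_equal(wilcoxonSignedRank(d, rep(0, n),
                                      alternative = "greater")$p.value,
                   pExact)
  }
})

test_that("upstream grouping is strand-aware", {
  tssP <- mkTSS("chr1", 100000, "+", "P")
  tssM <- mkTSS("chr1", 100000, "-", "M")
  pk <- mkPeaks("chr1", 85000, 86000, 1)
  expect_equal(groupGenesByUpstreamPeak(tssP, pk)$withPeak, "P")
  # for a minus-strand gene the upstream window lies right of the TSS
  expect_equal(groupGenesByUpstreamPeak(tssM, pk)$withoutPeak, "M")
  pkR <- mkPeaks("chr1", 110000, 111000, 1)
  expect_equal(groupGenesByUpstreamPeak(tssM, pkR)$withPeak, "M")

  both <- c(tssP, tssM <- mkTSS("chr1", 500000, "-", "M"))
  g <- groupGenesByUpstreamPeak(both, pk[0])
  expect_setequal(g$withoutPeak, c("P", "M"))
  expect_length(g$withPeak, 0L)
})

test_that("rank-sum U matches brute-force pair counting", {
  r <- rankSumCompare(c(3, 4, 5), c(1, 2))
  expect_equal(unname(r$statistic), 6)
  set.seed(44)
  for (rep in 1:10) {
    a <- sample(0:30, 12, TRUE); b <- sample(0:30, 9, TRUE)
    expect_equal(unname(rankSumCompare(a, b)$statistic), orU(a, b))
  }
  ident <- rankSumCompare(1:20, 1:20)
  expect_gt(ident$p.value, 0.9)
  expect_error(rankSumCompare(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum detects a one-sd shift at n = 200 per group", {
  set.seed(202)
  hits <- replicate(200, {
    b <- rnorm(200); a <- rnorm(200, 1)
    rankSumCompare(a, b, alternative = "greater")$p.value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})
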