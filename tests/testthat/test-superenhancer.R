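test_that("peak stitching merges within the stitch distance and sums signal", {
  pk <- mkPeaks("chr1", c(0, 10000), c(1000, 11000), signal = c(5, 7))
  st <- stitchPeaks(pk)  # gap 9000 <= 12500
  expect_length(st, 1L)
  expect_equal(start(st) - 1L, 0L)
  expect_equal(end(st), 11000L)
  expect_equal(mcols(st)$totalSignal, 12)
  expect_equal(sort(as.list(mcols(st)$constituentIds)[[1]]), c("p001", "p002"))

  far <- mkPeaks("chr1", c(0, 14001), c(1000, 15000), signal = c(5, 7))
  expect_length(stitchPeaks(far), 2L)  # gap 13001 > 12500
})

test_that("stitching matches the transitive-closure oracle on random peaks", {
  set.seed(18)
  for (rep in 1:10) {
    n <- 30
    s0 <- sort(sample(0:5e5, n))
    e0 <- s0 + sample(500:3000, n, TRUE)
    sig <- runif(n, 0.5, 20)
    pk <- mkPeaks("chr1", s0, e0, sig)
    st <- stitchPeaks(pk, stitchDistance = 12500)
    comp <- orClusterAssign(s0, e0, gap = 12500)
    expect_equal(length(st), length(unique(comp)))
    orSums <- sort(vapply(unique(comp), function(cmp)
      sum(sig[comp == cmp]), numeric(1)))
    expect_equal(sort(mcols(st)$totalSignal), orSums)
  }
})

test_that("TSS exclusion drops peaks fully inside the exclusion zone", {
  tss <- mkTSS("chr1", 50000, "+", "A")
  pk <- mkPeaks("chr1", c(49500, 48000, 100000), c(50500, 54000, 101000),
                signal = c(1, 1, 1))
  st <- stitchPeaks(pk, tssExclusion = 2500, tss = tss)
  # peak [49500,50500) is inside [47500,52500); [48000,54000) is not fully
  expect_equal(sum(mcols(st)$nConstituents), 2L)
})

test_that("rank-curve cutoff matches the exhaustive scan oracle", {
  set.seed(66)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    sig <- switch(1 + rep %% 3,
                  rlnorm(n, 1, 1),
                  c(runif(n - 3, 0, 5), runif(3, 50, 100)),
                  runif(n, 0, 10))
    sig <- round(sig, 3)
    if (length(unique(sig)) < 2) next
    pk <- mkPeaks("chr1", seq(0, by = 50000, length.out = n) ,
                  seq(0, by = 50000, length.out = n) + 1000, sig)
    st <- stitchPeaks(pk)
    calls <- rankSuperEnhancers(st)
    srt <- sort(mcols(st)$totalSignal)
    expect_equal(cutoffSignal(calls), srt[orInflectionIdx(srt)])
    expect_equal(isSuper(calls),
                 mcols(seRegions(calls))$totalSignal > cutoffSignal(calls))
  }
})

test_that("calls are invariant under affine signal rescaling", {
  set.seed(8)
  sig <- c(rlnorm(40, 0.5, 0.8), runif(5, 30, 80))
  pos <- seq(0, by = 1e5, length.out = length(sig))
  base <- rankSuperEnhancers(stitchPeaks(mkPeaks("chr1", pos, pos + 1000, sig)))
  for (ab in list(c(10, 0), c(3.7, 12), c(0.01, 100))) {
    tr <- rankSuperEnhancers(stitchPeaks(
      mkPeaks("chr1", pos, pos + 1000, ab[1] * sig + ab[2])))
    expect_equal(isSuper(tr), isSuper(base))
    expect_equal(mcols(seRegions(tr))$rank, mcols(seRegions(base))$rank)
  }
})

test_that("degenerate and boundary rank curves behave deterministically", {
  pos <- seq(0, by = 1e5, length.out = 10)
  flat <- mkPeaks("chr1", pos, pos + 1000, rep(4, 10))
  expect_warning(calls <- rankSuperEnhancers(stitchPeaks(flat)),
                 "identical")
  expect_equal(sum(isSuper(calls)), 0L)
  expect_equal(cutoffSignal(calls), 4)

  # signals exactly linear in rank: deterministic result, repeated runs agree
  lin <- mkPeaks("chr1", pos, pos + 1000, 1:10)
  c1 <- rankSuperEnhancers(stitchPeaks(lin))
  c2 <- rankSuperEnhancers(stitchPeaks(lin))
  expect_equal(isSuper(c1), isSuper(c2))
  expect_equal(cutoffSignal(c1), cutoffSignal(c2))

  # the top-ranked region is always a super-enhancer when any exists
  set.seed(5)
  for (rep in 1:10) {
    sig <- rlnorm(30, 1, 1.2)
    calls <- rankSuperEnhancers(stitchPeaks(
      mkPeaks("chr1", seq(0, by = 1e5, length.out = 30),
              seq(0, by = 1e5, length.out = 30) + 1000, sig)))
    if (sum(isSuper(calls)) > 0)
      expect_true(isSuper(calls)[which(mcols(seRegions(calls))$rank == 1)])
  }
})

test_that("SE-gene linking requires one anchor in the SE and one in a promoter", {
  tss <- mkTSS("chr1", c(301000, 500000), c("+", "+"), c("G", "H"))
  prom <- makePromoters(tss)  # G: [299000, 303000)
  pk <- mkPeaks("chr1", c(100000, 110000, 120000), c(103000, 113000, 123000),
                signal = c(50, 60, 70))
  # one region: no meaningful cutoff (warns), linked via superOnly = FALSE
  calls <- suppressWarnings(rankSuperEnhancers(stitchPeaks(pk)))
  # force the single region to be super by using superOnly = FALSE
  ls <- mkLoops("chr1",
                s1 = c(105000, 105000), e1 = c(110000, 110000),
                s2 = c(300000, 118000), e2 = c(305000, 121000),
                raw = 5, norm = 5, id = c("hit", "internal"))
  links <- linkSEToGenes(calls, ls, prom, superOnly = FALSE)
  expect_equal(nrow(links), 1L)
  expect_equal(links$geneId, "G")
  expect_equal(links$loopIds, "hit")
  # the loop with both anchors inside the SE contributes no link
  expect_false(any(grepl("internal", links$loopIds)))
})

test_that("SE-gene links match a brute-force triple scan on a random toy", {
  set.seed(23)
  for (rep in 1:5) {
    nSE <- 4; nGene <- 12; nLoop <- 50
    seS <- sort(sample(seq(0, 9e5, by = 2e5)))[1:nSE]
    seDf <- data.frame(s = seS, e = seS + 30000)
    g0 <- sort(sample(seq(5e4, 1e6, by = 5e4), nGene))
    promDf <- data.frame(s = pmax(0, g0 - 2000), e = g0 + 2000,
                         gene = sprintf("G%02d", seq_len(nGene)))
    s1 <- sample(0:1e6, nLoop); s2 <- sample(0:1e6, nLoop)
    loopDf <- data.frame(s1 = pmin(s1, s2), e1 = pmin(s1, s2) + 4000,
                         s2 = pmax(s1, s2), e2 = pmax(s1, s2) + 4000)
    expected <- orLinkScan(seDf, loopDf, promDf)

    regions <- gr0("chr1", seDf$s, seDf$e)
    mcols(regions)$totalSignal <- seq_len(nSE) + 100
    mcols(regions)$rank <- rank(-mcols(regions)$totalSignal,
                                ties.method = "first")
    mcols(regions)$isSuper <- rep(TRUE, nSE)
    calls <- methods::new("SuperEnhancerCalls", regions = regions,
                          cutoffSignal = 0, metadata = list())
    prom <- gr0("chr1", promDf$s, promDf$e)
    mcols(prom)$geneId <- promDf$gene
    ls <- mkLoops("chr1", loopDf$s1, loopDf$e1, loopDf$s2, loopDf$e2,
                  raw = 3, norm = 3)
    got <- linkSEToGenes(calls, ls, prom)
    expect_equal(nrow(got), nrow(expected))
    expect_setequal(paste(got$seIndex, got$geneId),
                    paste(expected$seIndex, expected$geneId))
    # linking soundness: every reported link has a witness loop
    for (k in seq_len(nrow(got))) {
      i <- got$seIndex[k]
      wit <- strsplit(got$loopIds[k], ",")[[1]]
      lsub <- ls[loopIds(ls) %in% wit]
      pg <- prom[mcols(prom)$geneId == got$geneId[k]]
      ok1 <- overlapsAny(anchors(lsub, 1), regions[i]) &
             overlapsAny(anchors(lsub, 2), pg)
      ok2 <- overlapsAny(anchors(lsub, 2), regions[i]) &
             overlapsAny(anchors(lsub, 1), pg)
      expect_true(all(ok1 | ok2))
    }
  }
})

test_that("nearest-gene skip fraction counts linked SEs only", {
  tss <- mkTSS("chr1", c(210000, 500000, 900000), c("+", "+", "+"),
               c("NEAR", "FAR", "OTHER"))
  regions <- gr0("chr1", c(100000, 700000), c(130000, 730000))
  mcols(regions)$totalSignal <- c(10, 9)
  mcols(regions)$rank <- 1:2
  mcols(regions)$isSuper <- c(TRUE, TRUE)
  calls <- methods::new("SuperEnhancerCalls", regions = regions,
                        cutoffSignal = 1, metadata = list())
  # SE1 links FAR (nearest is NEAR -> skips); SE2 links OTHER (its nearest)
  links <- data.frame(seIndex = c(1L, 2L), seRegion = "",
                      geneId = c("FAR", "OTHER"),
                      loopIds = "L", nLoops = 1L)
  out <- nearestGeneSkipFraction(links, calls, tss)
  expect_equal(out$fraction, 0.5)
  expect_equal(out$n, 2L)
  expect_equal(out$table$nearestGene, c("NEAR", "OTHER"))
  expect_equal(out$table$skipsNearest, c(TRUE, FALSE))

  allNear <- data.frame(seIndex = c(1L, 2L), seRegion = "",
                        geneId = c("NEAR", "OTHER"), loopIds = "L",
                        nLoops = 1L)
  expect_equal(nearestGeneSkipFraction(allNear, calls, tss)$fraction, 0)

  expect_error(nearestGeneSkipFraction(links, calls, mkTSS("chr1", 1, "+", "x")[0]),
               "empty")
})
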