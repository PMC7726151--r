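test_that("depth normalization rescales to the reference depth", {
  ls <- mkLoops("chr1", 0, 5000, 20000, 25000, raw = 6)
  out <- normalizeLoops(ls, totalValidPairs = 2e7, referenceDepth = 1e7)
  expect_equal(normCounts(out), 3.0)
  expect_equal(rawCounts(out), 6L)

  # reference depth equal to the sample depth leaves counts unchanged
  same <- normalizeLoops(ls, 2e7, 2e7)
  expect_equal(normCounts(same), as.numeric(rawCounts(same)))

  expect_error(normalizeLoops(ls, 2e7, 1e7, sampleId = "other"),
               "sample mismatch")
})

test_that("normalization conserves total mass exactly", {
  set.seed(101)
  n <- 200
  s1 <- sort(sample(0:1e6, n)) * 10
  ls <- mkLoops("chr1", s1, s1 + 1000, s1 + 50000, s1 + 51000,
                raw = sample(1:50, n, replace = TRUE))
  depth <- 1.7e7; ref <- 1.1e7
  out <- normalizeLoops(ls, depth, ref)
  expect_equal(sum(normCounts(out)),
               (ref / depth) * sum(rawCounts(out)))
})

test_that("anchor merging follows single-linkage with transitive chaining", {
  # pairwise gaps 1400 and 1300: one cluster spanning all three by
  # transitivity even though the outer pair is 3300 apart
  ls <- mkLoops("chr1",
                s1 = c(0, 2400, 4300), e1 = c(1000, 3000, 5000),
                s2 = c(1e6, 2e6, 3e6), e2 = c(1e6 + 1e3, 2e6 + 1e3, 3e6 + 1e3),
                raw = c(1, 1, 1))
  m <- mergeAnchors(ls, gap = 1500)
  a1 <- anchors(m, 1)
  expect_true(all(start(a1) == 1L & end(a1) == 5000L))  # [0,5000) on disk
})

test_that("anchors in the same cluster give self-loops that are dropped", {
  ls <- mkLoops("chr1", 0, 1000, 2000, 3000, raw = 4)  # gap 1000 <= 1500
  m <- mergeAnchors(ls, gap = 1500)
  expect_length(m, 0L)
  expect_equal(m@metadata$selfLoopsDropped, 1L)
})

test_that("coordinate-identical merged loops collapse with counts summed", {
  ls <- mkLoops("chr1",
                s1 = c(0, 500), e1 = c(1000, 1500),
                s2 = c(100000, 100500), e2 = c(101000, 101500),
                raw = c(2, 3), norm = c(1, 1.5))
  m <- mergeAnchors(ls, gap = 1500)
  expect_length(m, 1L)
  expect_equal(rawCounts(m), 5L)
  expect_equal(normCounts(m), 2.5)
  expect_equal(m@metadata$loopsCollapsed, 1L)
})

test_that("anchor merging is idempotent and separates clusters by > gap", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 40
    s <- sort(sample(0:2e5, n)) * 3
    ls <- mkLoops("chr1", s, s + sample(500:2000, n, replace = TRUE),
                  s + 3e6, s + 3e6 + 1000, raw = sample(1:9, n, TRUE))
    m1 <- mergeAnchors(ls, gap = 1500)
    m2 <- mergeAnchors(m1, gap = 1500)
    expect_equal(as.data.frame(m2), as.data.frame(m1))
    # every pair of distinct output anchors is separated by > 1500 bp
    all <- sort(unique(c(anchors(m1, 1), anchors(m1, 2))))
    if (length(all) > 1) {
      gaps <- start(all)[-1] - end(all)[-length(all)] - 1L
      expect_true(all(gaps > 1500))
    }
  }
})

test_that("cluster assignment matches the O(n^2) transitive-closure oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    s0 <- sort(sample(0:300000, n))
    e0 <- s0 + sample(200:3000, n, replace = TRUE)
    gap <- sample(c(0, 500, 1500, 5000), 1)
    comp <- orClusterAssign(s0, e0, gap)
    red <- GenomicRanges::reduce(gr0("c", s0, e0), min.gapwidth = gap + 1)
    hit <- findOverlaps(gr0("c", s0, e0), red, select = "first")
    # identical partitions: same pairs together
    expect_equal(outer(comp, comp, "=="), outer(hit, hit, "=="))
  }
})

test_that("loop filtering applies inclusive length and strength thresholds", {
  # length is midpoint distance; anchors of width 1000 make it s2 - s1
  ls <- mkLoops("chr1",
                s1 = c(0, 0, 0), e1 = c(1000, 1000, 1000),
                s2 = c(5000, 5000, 50000), e2 = c(6000, 6000, 51000),
                raw = c(3, 3, 3), norm = c(3.0, 2.9, 2.9),
                id = c("keep", "weak", "weak2"))
  out <- filterLoops(ls)
  expect_equal(loopIds(out), "keep")
  rep <- filterReport(out)
  expect_equal(rep$removedWeak, 2L)
  expect_equal(rep$removedShort, 0L)
  expect_equal(rep$retained, 1L)

  empty <- filterLoops(ls[0])
  expect_length(empty, 0L)
  expect_equal(filterReport(empty)$removedWeak, 0L)

  raw <- mkLoops("chr1", 0, 1000, 50000, 51000, raw = 5)
  expect_error(filterLoops(raw), "normalized counts are unset")
})

test_that("raising filter thresholds gives nested retained sets", {
  set.seed(9)
  n <- 120
  s1 <- sample(0:1e6, n) * 5
  len <- sample(1000:200000, n, replace = TRUE)
  ls <- mkLoops("chr1", s1, s1 + 1000, s1 + len, s1 + len + 1000,
                raw = sample(1:20, n, TRUE),
                norm = runif(n, 0, 8))
  prev <- NULL
  for (minN in c(1, 3, 5)) {
    ids <- loopIds(filterLoops(ls, minLength = 5000, minNormCount = minN))
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
  prev <- NULL
  for (minL in c(2000, 5000, 50000)) {
    ids <- loopIds(filterLoops(ls, minLength = minL, minNormCount = 3))
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("replicate concatenation sums counts on identical coordinates", {
  r1 <- mkLoops("chr1", c(0, 10000), c(1000, 11000), c(50000, 70000),
                c(51000, 71000), raw = c(2, 5))
  r2 <- mkLoops("chr1", 0, 1000, 50000, 51000, raw = 4)
  comb <- concatLoopSets(list(r1, r2))
  expect_length(comb, 2L)
  expect_equal(sum(rawCounts(comb)), 11L)
  expect_equal(rawCounts(comb)[1], 6L)
})
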