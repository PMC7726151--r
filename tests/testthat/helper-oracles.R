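# Independent brute-force oracles (O(n^2) transitive closure, exhaustive
# enumeration) and small builders used across the suite. Oracles deliberately
# avoid the package's code paths; coordinates are BED-style 0-based half-open
# like the on-disk formats.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# GRanges from 0-based half-open coordinates
gr0 <- function(chrom, s0, e0, ...) GRanges(chrom, IRanges(s0 + 1, e0), ...)

mkPeaks <- function(chrom, s0, e0, signal, id = NULL, sample = "S") {
  gr <- gr0(chrom, s0, e0)
  mcols(gr)$signal <- signal
  mcols(gr)$peakId <- if (is.null(id)) sprintf("p%03d", seq_along(gr)) else id
  S4Vectors::metadata(gr)$sampleId <- sample
  gr
}

mkTSS <- function(chrom, t0, strand, gene) {
  gr <- gr0(chrom, t0, t0 + 1, strand = strand)
  mcols(gr)$geneId <- gene
  gr
}

mkLoops <- function(chrom, s1, e1, s2, e2, raw, norm = NA_real_,
                    sample = "S", id = NULL) {
  LoopSet(gr0(chrom, s1, e1), gr0(chrom, s2, e2), as.integer(raw), norm,
          sample, loopId = id)
}

# single-linkage clustering of intervals: adjacency when the gap between
# [s_i, e_i) and [s_j, e_j) is <= gap (overlapping intervals have negative
# gap); transitive closure by flood fill over the n x n adjacency matrix
orClusterAssign <- function(s0, e0, gap) {
  n <- length(s0)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    g <- max(s0[i], s0[j]) - min(e0[i], e0[j])
    adj[i, j] <- g <= gap
  }
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    frontier <- i
    comp[i] <- nc
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) for (j in seq_len(n))
        if (adj[f, j] && is.na(comp[j])) { comp[j] <- nc; nxt <- c(nxt, j) }
      frontier <- nxt
    }
  }
  comp
}

# exhaustive scan over all candidate cut indices of the min-max scaled rank
# curve; picks the slope-1 crossing = max distance below the diagonal,
# rightmost on ties
orInflectionIdx <- function(sortedSignals) {
  n <- length(sortedSignals)
  best <- -Inf; bestIdx <- NA_integer_
  for (i in seq_len(n)) {
    x <- (i - 1) / (n - 1)
    y <- (sortedSignals[i] - sortedSignals[1]) /
         (sortedSignals[n] - sortedSignals[1])
    if (x - y >= best - 1e-12) { best <- max(best, x - y); bestIdx <- i }
  }
  bestIdx
}

# exact signed-rank p by enumeration over all 2^n sign assignments
orSignedRankP <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  tot <- 2^n
  sums <- numeric(tot)
  for (k in 0:(tot - 1)) {
    s <- 0
    for (b in seq_len(n)) if (bitwAnd(k, bitwShiftL(1L, b - 1L)) != 0)
      s <- s + r[b]
    sums[k + 1] <- s
  }
  eps <- 1e-9
  pG <- mean(sums >= W - eps)
  pL <- mean(sums <= W + eps)
  switch(alternative,
         two.sided = min(1, 2 * min(pG, pL)),
         greater = pG, less = pL)
}

# brute-force (SE, gene) links: triple scan over SEs, loops and promoters;
# 0-based half-open overlap
orLinkScan <- function(seDf, loopDf, promDf) {
  ov <- function(a0, a1, b0, b1) a0 < b1 && b0 < a1
  out <- NULL
  for (i in seq_len(nrow(seDf))) for (l in seq_len(nrow(loopDf)))
    for (p in seq_len(nrow(promDf))) {
      fwd <- ov(loopDf$s1[l], loopDf$e1[l], seDf$s[i], seDf$e[i]) &&
             ov(loopDf$s2[l], loopDf$e2[l], promDf$s[p], promDf$e[p])
      rev <- ov(loopDf$s2[l], loopDf$e2[l], seDf$s[i], seDf$e[i]) &&
             ov(loopDf$s1[l], loopDf$e1[l], promDf$s[p], promDf$e[p])
      if (fwd || rev)
        out <- rbind(out, data.frame(seIndex = i, geneId = promDf$gene[p]))
    }
  if (is.null(out)) data.frame(seIndex = integer(0), geneId = character(0))
  else unique(out)
}

# midpoint membership count in 0-based half-open [a, b)
orCountMid <- function(mids, a, b) sum(mids >= a & mids < b)

# Mann-Whitney U of a over b by explicit pair counting
orU <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# lightweight null/power enrichment simulation: K random loop spans, factor
# peaks placed uniformly (ratio 1) or weighted into the spans (ratio > 1)
simulateEnrichmentRun <- function(nLoops = 100, ratio = 1, nFactor = 800,
                                  L = 1e7) {
  w <- runif(nLoops, 2e4, 2e5)
  s <- runif(nLoops, 0, L - 3 * w)
  loops <- mkLoops("chrS", s + w, s + w + 1000, s + 2 * w - 1000, s + 2 * w,
                   raw = 5)
  if (ratio == 1) {
    fp <- sort(round(runif(nFactor, 200, L - 200)))
  } else {
    spans <- GenomicRanges::reduce(loopSpan(loops))
    fp <- enhancerConnectome:::.placeFactorPeaks(nFactor, ratio, spans, L)
  }
  fgr <- mkPeaks("chrS", fp - 100, fp + 100, signal = 1,
                 id = as.character(seq_along(fp)))
  loopFactorObservation(loops, fgr)
}
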