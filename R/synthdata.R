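#' Configuration for the synthetic connectome generator
#'
#' Defaults describe a compact but realistic single-chromosome study: a 10 Mb
#' chromosome with 300 genes; 800 typical H3K27ac peaks with heavy-tailed
#' (log-normal) signal; 20 super-enhancer loci of 5 clustered high-signal
#' constituent peaks each; 1500 intra-chromosomal loops with distance-decay
#' counts plus one planted high-count SE-to-promoter loop per SE (the target
#' being the nearest gene, or a farther gene for a planted fraction of
#' "skipping" SEs); factor peaks placed with a given inside:outside intensity
#' ratio over the planted loop spans; and log-scale expression elevated for
#' genes with a peak within 20 kb upstream. Two replicate loop files with
#' distinct depths are emitted to exercise replicate concatenation and depth
#' normalization.
#'
#' @param chromName chromosome name.
#' @param chromLength chromosome length, bp.
#' @param nGenes number of genes (TSSs).
#' @param nTypicalPeaks number of typical enhancer/promoter peaks.
#' @param nSELoci number of planted super-enhancer loci.
#' @param seConstituents constituent peaks per SE locus (placed within the
#'   stitch distance of each other).
#' @param signalMeanlog,signalSdlog log-normal signal parameters of typical
#'   peaks.
#' @param seSignalMultiplier multiplicative signal boost of SE constituent
#'   peaks (>= 5).
#' @param seSignalSdlog dispersion of SE constituent signals.
#' @param nLoops total loops per sample.
#' @param decayExponent distance-decay exponent of loop counts
#'   (count ~ 1 + Poisson(A * (d / 10 kb)^-decay)).
#' @param epLinkFraction fraction of SE loci given a planted promoter link.
#' @param plantedSkipFraction fraction of linked SEs planted to skip their
#'   nearest gene.
#' @param factorInsideRatio factor-peak intensity ratio inside planted loop
#'   spans vs elsewhere (>= 1; 1 = no enrichment).
#' @param nFactorPeaks number of factor (CTCF/SMC1-style) peaks.
#' @param replicateDepths total valid read pairs of the two replicates.
#' @param expressionBase,expressionEffect log-scale expression baseline and
#'   mean shift for genes with an upstream peak (sd 1).
#' @param stitchDistance stitch distance the SE constituents are placed
#'   within.
#' @param seed integer RNG seed; the whole simulation is deterministic given
#'   the config.
#' @return a validated config (class \code{ConnectomeSimConfig}).
#' @export
syntheticConfig <- function(chromName = "chrS",
                            chromLength = 1e7,
                            nGenes = 300,
                            nTypicalPeaks = 800,
                            nSELoci = 20,
                            seConstituents = 5,
                            signalMeanlog = 0.75,
                            signalSdlog = 0.6,
                            seSignalMultiplier = 80,
                            seSignalSdlog = 0.4,
                            nLoops = 1500,
                            decayExponent = 1.0,
                            epLinkFraction = 1.0,
                            plantedSkipFraction = 0.4,
                            factorInsideRatio = 3,
                            nFactorPeaks = 800,
                            replicateDepths = c(2e7, 1.5e7),
                            expressionBase = 6,
                            expressionEffect = 1,
                            stitchDistance = 12500,
                            seed = 1) {
  cfg <- list(chromName = chromName, chromLength = as.integer(chromLength),
              nGenes = as.integer(nGenes),
              nTypicalPeaks = as.integer(nTypicalPeaks),
              nSELoci = as.integer(nSELoci),
              seConstituents = as.integer(seConstituents),
              signalMeanlog = signalMeanlog, signalSdlog = signalSdlog,
              seSignalMultiplier = seSignalMultiplier,
              seSignalSdlog = seSignalSdlog,
              nLoops = as.integer(nLoops), decayExponent = decayExponent,
              epLinkFraction = epLinkFraction,
              plantedSkipFraction = plantedSkipFraction,
              factorInsideRatio = factorInsideRatio,
              nFactorPeaks = as.integer(nFactorPeaks),
              replicateDepths = as.numeric(replicateDepths),
              expressionBase = expressionBase,
              expressionEffect = expressionEffect,
              stitchDistance = as.integer(stitchDistance),
              seed = as.integer(seed))
  .checkScalarString(cfg$chromName, "chromName")
  for (f in c("chromLength", "nGenes", "nTypicalPeaks", "nSELoci",
              "seConstituents", "nLoops", "nFactorPeaks", "stitchDistance"))
    .checkPositiveScalar(cfg[[f]], f)
  for (f in c("epLinkFraction", "plantedSkipFraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must be in [0, 1]", call. = FALSE)
  if (cfg$factorInsideRatio < 1)
    stop("factorInsideRatio must be >= 1", call. = FALSE)
  if (length(cfg$replicateDepths) != 2L || any(cfg$replicateDepths < 1))
    stop("replicateDepths must be two positive depths", call. = FALSE)
  # feasibility: constituents (width 1500, gaps >= 2000) must fit in the
  # stitch distance; SE slots plus gene slots must fit the chromosome
  if (cfg$seConstituents > 1 && cfg$stitchDistance < 2000)
    stop("infeasible config: constituents cannot fit within stitchDistance",
         call. = FALSE)
  if (cfg$chromLength / cfg$nGenes < 12000)
    stop("infeasible config: gene density too high for non-overlapping promoters",
         call. = FALSE)
  if (cfg$chromLength / cfg$nSELoci < 100000)
    stop("infeasible config: too many SE loci for the chromosome", call. = FALSE)
  structure(cfg, class = "ConnectomeSimConfig")
}

# jittered-grid placement: n positions on [margin, L - margin] with
# guaranteed minimum separation
.jitteredGrid <- function(n, L, margin, jitterPad) {
  slot <- (L - 2 * margin) / n
  margin + (seq_len(n) - 1) * slot +
    stats::runif(n, jitterPad, slot - jitterPad)
}

#' Simulate a synthetic enhancer-connectome study with recorded truth
#'
#' Generates peaks, replicate loop sets, TSSs, factor peaks and expression
#' for one synthetic sample, together with the planted ground truth (SE
#' regions, true SE-to-gene links, per-SE nearest-gene skip flags, enriched
#' loop ids, expression groups). Deterministic for a fixed config seed. When
#' \code{outDir} is given, all parts are also written as plain-text files
#' (\code{peaks.bed}, \code{loops_rep1.bedpe}, \code{loops_rep2.bedpe},
#' \code{tss.tsv}, \code{factor.bed}, \code{expr.tsv}, \code{truth.json}).
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param outDir optional output directory.
#' @return a list of class \code{ConnectomeSimulation} with components
#'   \code{peaks} (GRanges), \code{loopReplicates} (list of two
#'   \code{LoopSet}s), \code{loops} (the combined LoopSet), \code{tss},
#'   \code{factorPeaks}, \code{expression}, \code{truth}, \code{config},
#'   and \code{files} when written.
#' @export
simulateConnectome <- function(config = syntheticConfig(), outDir = NULL) {
  stopifnot(inherits(config, "ConnectomeSimConfig"))
  .withSeed(config$seed, .simulateConnectomeImpl(config, outDir))
}

.simulateConnectomeImpl <- function(cfg, outDir) {
  L <- cfg$chromLength
  chrom <- cfg$chromName

  ## genes: jittered grid keeps promoter windows (+/-2 kb) non-overlapping
  tss0 <- as.integer(round(.jitteredGrid(cfg$nGenes, L, 20000, 5000)))
  strand <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
  geneId <- sprintf("G%04d", seq_len(cfg$nGenes))
  tss <- .gr0(chrom, tss0, tss0 + 1L, strand = strand)
  mcols(tss)$geneId <- geneId

  ## SE loci: coarse grid; centers re-drawn until 8-60 kb from the nearest
  ## TSS so planted loops always exceed the minimum loop length
  seCenter <- numeric(cfg$nSELoci)
  slot <- L / cfg$nSELoci
  for (i in seq_len(cfg$nSELoci)) {
    lo <- (i - 1) * slot + 30000; hi <- i * slot - 30000
    for (try in 1:200) {
      cand <- stats::runif(1, lo, hi)
      dNear <- min(abs(tss0 - cand))
      if (dNear >= 8000 && dNear <= 60000) break
      cand <- NA
    }
    if (is.na(cand))
      stop("infeasible config: could not place SE locus ", i, call. = FALSE)
    seCenter[i] <- cand
  }

  ## SE constituent peaks: width 1500, gaps 2000..6000 (always stitchable)
  seW <- 1500L
  sePeakStart <- integer(0); seLocus <- integer(0)
  for (i in seq_len(cfg$nSELoci)) {
    gaps <- stats::runif(cfg$seConstituents - 1, 2000, 6000)
    offs <- cumsum(c(0, gaps + seW))
    span <- offs[length(offs)] + seW
    st <- as.integer(round(seCenter[i] - span / 2 + offs))
    sePeakStart <- c(sePeakStart, st)
    seLocus <- c(seLocus, rep(i, cfg$seConstituents))
  }
  seSignal <- cfg$seSignalMultiplier *
    stats::rlnorm(length(sePeakStart), cfg$signalMeanlog, cfg$seSignalSdlog)
  seRegions0 <- vapply(seq_len(cfg$nSELoci), function(i) {
    st <- sePeakStart[seLocus == i]
    c(min(st), max(st) + seW)
  }, numeric(2))
  seRegions <- .gr0(chrom, seRegions0[1, ], seRegions0[2, ])

  ## typical peaks: small multi-summit enhancer clusters (2-4 peaks spanning
  ## a few kb), cluster loci on a jittered grid separated by more than the
  ## stitch distance, and kept clear of the SE spans by the same margin, so
  ## planted SEs are the only large clusters and every locus stitches to
  ## itself
  exclusion <- GenomicRanges::resize(
    seRegions, width = width(seRegions) + 2L * (cfg$stitchDistance + 2000L),
    fix = "center")
  sizes <- integer(0)
  while (sum(sizes) < cfg$nTypicalPeaks)
    sizes <- c(sizes, sample(2:4, 64, replace = TRUE, prob = c(.4, .4, .2)))
  sizes <- sizes[cumsum(sizes) <= cfg$nTypicalPeaks]
  if (sum(sizes) < cfg$nTypicalPeaks)
    sizes <- c(sizes, cfg$nTypicalPeaks - sum(sizes))
  nGroups <- length(sizes)
  maxExtent <- 4L * 1500L + 3L * 1200L  # widest possible cluster, bp
  slot <- (L - 40000) / nGroups
  pad <- (slot - maxExtent - (cfg$stitchDistance + 2000)) / 2
  if (pad <= 0)
    stop("infeasible config: typical-peak density too high for the stitch distance",
         call. = FALSE)
  pad <- min(pad, 8000)
  centers <- .jitteredGrid(nGroups, L, 20000, max(0, slot / 2 - pad))
  # drop cluster loci colliding with an SE exclusion zone
  keep <- !overlapsAny(.gr0(chrom, as.integer(centers),
                            as.integer(centers) + 1L), exclusion)
  sizes <- sizes[keep]; centers <- centers[keep]
  tStart <- integer(0); tW <- integer(0)
  for (gi in seq_along(sizes)) {
    k <- sizes[gi]
    w <- as.integer(round(stats::runif(k, 400, 1500)))
    gaps <- if (k > 1) stats::runif(k - 1, 300, 1200) else numeric(0)
    offs <- cumsum(c(0, gaps + w[-k]))
    ext <- offs[k] + w[k]
    st <- as.integer(round(centers[gi] - ext / 2 + offs))
    tStart <- c(tStart, st); tW <- c(tW, w)
  }
  nTyp <- length(tStart)
  tSignal <- stats::rlnorm(nTyp, cfg$signalMeanlog, cfg$signalSdlog)

  peaks <- .gr0(chrom, c(tStart, sePeakStart),
                c(tStart + tW, sePeakStart + seW))
  mcols(peaks)$signal <- round(c(tSignal, seSignal), 4)
  mcols(peaks)$peakId <- c(sprintf("tp%04d", seq_len(nTyp)),
                           sprintf("se%02d_c%d", seLocus,
                                   as.integer(stats::ave(seLocus, seLocus,
                                                         FUN = seq_along))))
  ord <- order(start(peaks))
  peaks <- peaks[ord]
  S4Vectors::metadata(peaks)$sampleId <- "synthetic"

  ## planted SE -> promoter loops
  nLinked <- round(cfg$epLinkFraction * cfg$nSELoci)
  linkedSE <- if (nLinked > 0) sort(sample(seq_len(cfg$nSELoci), nLinked))
              else integer(0)
  nSkip <- round(cfg$plantedSkipFraction * nLinked)
  skipSE <- if (nSkip > 0) sort(sample(linkedSE, nSkip)) else integer(0)
  planted <- list(); skipFlag <- logical(0); targetGene <- character(0)
  for (i in linkedSE) {
    d <- suppressWarnings(GenomicRanges::distance(seRegions[i], tss,
                                                  ignore.strand = TRUE))
    ordd <- order(d, geneId)
    nearest <- ordd[1]
    target <- if (i %in% skipSE) {
      # a farther gene, 3rd-6th by distance, at least 25 kb away so the
      # choice is unambiguous
      cands <- ordd[3:6]
      cands <- cands[d[cands] >= 25000]
      if (!length(cands)) cands <- ordd[6]
      sample(rep(cands, 2), 1)  # rep() guard: sample(scalar) pitfall
    } else nearest
    # anchor inside the SE: middle constituent; anchor at target promoter
    st <- sort(sePeakStart[seLocus == i])
    aSE <- st[ceiling(length(st) / 2)]
    tpos <- tss0[target]
    planted[[length(planted) + 1L]] <- data.frame(
      s1 = aSE, e1 = aSE + seW, s2 = tpos - 1000L, e2 = tpos + 1000L,
      count = 8L + stats::rpois(1, 6), se = i, gene = geneId[target])
    skipFlag <- c(skipFlag, i %in% skipSE)
    targetGene <- c(targetGene, geneId[target])
  }
  plantedDf <- if (length(planted)) do.call(rbind, planted) else NULL

  ## background loops with distance-decay counts, anchored at typical peaks
  ## and promoters
  anchorPos <- c(tStart + as.integer(tW / 2), tss0)
  nRandom <- max(0L, cfg$nLoops - nrow0(plantedDf))
  rnd <- NULL
  if (nRandom > 0) {
    got <- 0L; parts <- list()
    while (got < nRandom) {
      m <- 3L * (nRandom - got)
      i <- sample(length(anchorPos), m, replace = TRUE)
      j <- sample(length(anchorPos), m, replace = TRUE)
      d <- abs(anchorPos[i] - anchorPos[j])
      ok <- d >= 6000 & d <= 2e6
      i <- i[ok]; j <- j[ok]; d <- d[ok]
      if (!length(i)) next
      lam <- 6 * (d / 10000)^(-cfg$decayExponent)
      cnt <- 1L + stats::rpois(length(d), lam)
      lo <- pmin(anchorPos[i], anchorPos[j])
      hi <- pmax(anchorPos[i], anchorPos[j])
      parts[[length(parts) + 1L]] <- data.frame(
        s1 = lo - 750L, e1 = lo + 750L, s2 = hi - 750L, e2 = hi + 750L,
        count = cnt)
      got <- got + length(i)
    }
    rnd <- utils::head(do.call(rbind, parts), nRandom)
    rnd$s1 <- pmax(0L, as.integer(rnd$s1)); rnd$s2 <- pmax(0L, as.integer(rnd$s2))
  }
  loopDf <- rbind(
    if (!is.null(plantedDf))
      data.frame(s1 = plantedDf$s1, e1 = plantedDf$e1, s2 = plantedDf$s2,
                 e2 = plantedDf$e2, count = plantedDf$count) else NULL,
    rnd)
  # canonical order within rows
  flip <- loopDf$s1 > loopDf$s2
  tmp <- loopDf[flip, c("s1", "e1")]
  loopDf[flip, c("s1", "e1")] <- loopDf[flip, c("s2", "e2")]
  loopDf[flip, c("s2", "e2")] <- tmp
  loopId <- sprintf("SL%05d", seq_len(nrow(loopDf)))
  plantedLoopIds <- if (!is.null(plantedDf)) loopId[seq_len(nrow(plantedDf))]
                    else character(0)

  loops <- LoopSet(.gr0(chrom, loopDf$s1, loopDf$e1),
                   .gr0(chrom, loopDf$s2, loopDf$e2),
                   as.integer(loopDf$count), NA_real_, "synthetic",
                   loopId = loopId)

  ## replicate split: per-loop binomial thinning by relative depth; a loop
  ## absent from one replicate file keeps its pairs in the other
  p1 <- cfg$replicateDepths[1] / sum(cfg$replicateDepths)
  c1 <- stats::rbinom(length(loops), rawCounts(loops), p1)
  c2 <- rawCounts(loops) - c1
  mk <- function(cnt) {
    keep <- cnt > 0
    LoopSet(loops@anchor1[keep], loops@anchor2[keep],
            as.integer(cnt[keep]), NA_real_, "synthetic",
            loopId = loops@loopId[keep])
  }
  loopReplicates <- list(rep1 = mk(c1), rep2 = mk(c2))

  ## factor peaks: intensity ratio inside planted loop spans vs elsewhere
  plantedSpans <- if (!is.null(plantedDf))
    GenomicRanges::reduce(.gr0(chrom, pmin(plantedDf$s1, plantedDf$s2),
                               pmax(plantedDf$e1, plantedDf$e2)))
  else GRanges()
  factorPos <- .placeFactorPeaks(cfg$nFactorPeaks, cfg$factorInsideRatio,
                                 plantedSpans, L)
  factorPeaks <- .gr0(chrom, factorPos - 100L, factorPos + 100L)
  mcols(factorPeaks)$signal <- rep(1, length(factorPeaks))
  mcols(factorPeaks)$peakId <- sprintf("fp%04d", seq_along(factorPeaks))

  ## expression: elevated for genes with a peak within 20 kb upstream
  groups <- groupGenesByUpstreamPeak(tss, peaks, window = 20000)
  flag <- geneId %in% groups$withPeak
  expression <- data.frame(
    geneId = geneId,
    expression = round(stats::rnorm(cfg$nGenes,
                                    cfg$expressionBase +
                                      cfg$expressionEffect * flag, 1), 4),
    stringsAsFactors = FALSE)

  truth <- list(
    chromName = chrom, chromLength = L,
    seRegions = data.frame(seIndex = seq_len(cfg$nSELoci),
                           chrom = chrom,
                           start = .start0(seRegions),
                           end = .end0(seRegions)),
    trueLinks = if (!is.null(plantedDf))
      data.frame(seIndex = plantedDf$se, geneId = plantedDf$gene,
                 loopId = plantedLoopIds, stringsAsFactors = FALSE)
    else data.frame(seIndex = integer(0), geneId = character(0),
                    loopId = character(0)),
    skipFlags = if (length(linkedSE))
      data.frame(seIndex = linkedSE, skips = skipFlag,
                 targetGene = targetGene, stringsAsFactors = FALSE)
    else data.frame(seIndex = integer(0), skips = logical(0),
                    targetGene = character(0)),
    plantedSkipFraction = if (nLinked) nSkip / nLinked else NA_real_,
    enrichedLoopIds = if (cfg$factorInsideRatio > 1) plantedLoopIds
                      else character(0),
    factorInsideRatio = cfg$factorInsideRatio,
    expressionGroups = data.frame(geneId = geneId, withUpstreamPeak = flag,
                                  stringsAsFactors = FALSE),
    replicateDepths = cfg$replicateDepths,
    seed = cfg$seed)

  sim <- structure(list(peaks = peaks, loopReplicates = loopReplicates,
                        loops = concatLoopSets(loopReplicates),
                        tss = tss, factorPeaks = factorPeaks,
                        expression = expression, truth = truth,
                        config = cfg),
                   class = "ConnectomeSimulation")
  if (!is.null(outDir)) sim$files <- .writeSimulation(sim, outDir)
  sim
}

nrow0 <- function(df) if (is.null(df)) 0L else nrow(df)

# length-weighted placement: inside segments get weight ratio, the rest of
# the chromosome weight 1
.placeFactorPeaks <- function(n, ratio, insideSpans, L) {
  if (!length(insideSpans) || ratio == 1) {
    return(sort(as.integer(round(stats::runif(n, 200, L - 200)))))
  }
  s0 <- .start0(insideSpans); e0 <- .end0(insideSpans)
  lin <- sum(e0 - s0)
  pin <- ratio * lin / (ratio * lin + (L - lin))
  nin <- stats::rbinom(1, n, pin)
  posIn <- integer(0)
  if (nin > 0) {
    seg <- sample(length(insideSpans), nin, replace = TRUE,
                  prob = (e0 - s0))
    posIn <- as.integer(round(stats::runif(nin, s0[seg], e0[seg])))
  }
  posOut <- integer(0)
  need <- n - nin
  while (need > 0) {
    cand <- as.integer(round(stats::runif(2 * need + 10, 200, L - 200)))
    gr <- .gr0(rep("x", length(cand)), cand, cand + 1L)
    spans <- .gr0(rep("x", length(insideSpans)), s0, e0)
    ok <- cand[!overlapsAny(gr, spans)]
    take <- utils::head(ok, need)
    posOut <- c(posOut, take)
    need <- need - length(take)
  }
  sort(c(posIn, posOut))
}

.writeSimulation <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    peaks = file.path(outDir, "peaks.bed"),
    loopsRep1 = file.path(outDir, "loops_rep1.bedpe"),
    loopsRep2 = file.path(outDir, "loops_rep2.bedpe"),
    tss = file.path(outDir, "tss.tsv"),
    factor = file.path(outDir, "factor.bed"),
    expression = file.path(outDir, "expr.tsv"),
    truth = file.path(outDir, "truth.json"))
  writePeaks(sim$peaks, files$peaks)
  writeLoops(sim$loopReplicates$rep1, files$loopsRep1)
  writeLoops(sim$loopReplicates$rep2, files$loopsRep2)
  writeTSS(sim$tss, files$tss)
  writePeaks(sim$factorPeaks, files$factor)
  writeExpression(sim$expression, files$expression)
  jsonlite::write_json(sim$truth, files$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  files
}

#' Print a simulation summary
#' @param x a \code{ConnectomeSimulation}.
#' @param ... ignored.
#' @return \code{x}, invisibly.
#' @export
print.ConnectomeSimulation <- function(x, ...) {
  cat(sprintf("ConnectomeSimulation: %s (%d bp), seed %d\n",
              x$config$chromName, x$config$chromLength, x$config$seed))
  cat(sprintf("  %d peaks (%d SE loci), %d loops in %d replicates, %d genes\n",
              length(x$peaks), x$config$nSELoci, length(x$loops),
              length(x$loopReplicates), x$config$nGenes))
  cat(sprintf("  planted links: %d (skip fraction %.2f), factor ratio %.1f\n",
              nrow(x$truth$trueLinks), x$truth$plantedSkipFraction,
              x$config$factorInsideRatio))
  invisible(x)
}

#' Recovery of planted structure by the pipeline
#'
#' Compares a pipeline run against the recorded ground truth of the
#' simulation that produced its inputs: super-enhancer precision/recall
#' (overlap-based region matching), SE-to-gene link recall, the absolute
#' error of the estimated nearest-gene skip fraction, and whether in-loop
#' factor enrichment was detected.
#'
#' @param sim a \code{ConnectomeSimulation} (or its \code{$truth}).
#' @param result a \code{\link{runPipeline}} result on the simulation's
#'   outputs.
#' @param alpha significance level for the enrichment-detected flag
#'   (default 0.01).
#' @return list with \code{sePrecision}, \code{seRecall}, \code{linkRecall},
#'   \code{skipFractionEstimate}, \code{skipFractionError},
#'   \code{enrichmentP}, \code{enrichmentDetected}.
#' @export
recoveryReport <- function(sim, result, alpha = 0.01) {
  truth <- if (inherits(sim, "ConnectomeSimulation")) sim$truth else sim
  missing <- setdiff(c("seCalls", "seLinks", "skip"), names(result))
  if (length(missing))
    stop("pipeline result is missing stages: ",
         paste(missing, collapse = ", "), call. = FALSE)
  trueSE <- .gr0(truth$seRegions$chrom, truth$seRegions$start,
                 truth$seRegions$end)
  called <- seRegions(result$seCalls)
  called <- called[mcols(called)$isSuper]
  seRecall <- if (length(trueSE)) mean(overlapsAny(trueSE, called)) else NA
  sePrecision <- if (length(called)) mean(overlapsAny(called, trueSE)) else NA

  links <- result$seLinks
  linkRecall <- if (nrow(truth$trueLinks)) {
    recovered <- vapply(seq_len(nrow(truth$trueLinks)), function(k) {
      i <- truth$trueLinks$seIndex[k]
      g <- truth$trueLinks$geneId[k]
      if (!nrow(links)) return(FALSE)
      any(links$geneId == g &
            links$seIndex %in% which(overlapsAny(seRegions(result$seCalls),
                                                 trueSE[i])))
    }, logical(1))
    mean(recovered)
  } else NA_real_

  skipEst <- result$skip$fraction
  skipErr <- if (!is.na(truth$plantedSkipFraction) && !is.na(skipEst))
    abs(skipEst - truth$plantedSkipFraction) else NA_real_

  enrichP <- if (!is.null(result$enrichment)) result$enrichment$p.value
             else NA_real_
  list(sePrecision = sePrecision, seRecall = seRecall,
       linkRecall = linkRecall,
       skipFractionEstimate = skipEst, skipFractionError = skipErr,
       enrichmentP = enrichP,
       enrichmentDetected = !is.na(enrichP) && enrichP < alpha)
}
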