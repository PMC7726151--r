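#' Stitch enhancer peaks into candidate super-enhancer regions
#'
#' Peaks whose inter-peak gap is at most \code{stitchDistance} bp are merged
#' transitively into one region spanning the constituents; the region's
#' signal is the sum of its constituents' signals. Optionally, peaks fully
#' inside TSS +/- \code{tssExclusion} are dropped first (off by default, as
#' in a default ROSE run).
#'
#' @param peaks enhancer-class peak \code{GRanges} (\code{signal},
#'   \code{peakId}).
#' @param stitchDistance maximum gap to stitch, bp (default 12500).
#' @param tssExclusion half-width of the TSS exclusion zone, bp (default 0 =
#'   no exclusion).
#' @param tss TSS \code{GRanges}; required when \code{tssExclusion > 0}.
#' @return \code{GRanges} of stitched regions with \code{totalSignal},
#'   \code{nConstituents} and \code{constituentIds} (CharacterList).
#' @export
stitchPeaks <- function(peaks, stitchDistance = 12500, tssExclusion = 0,
                        tss = NULL) {
  .checkPeaks(peaks)
  .checkPositiveScalar(stitchDistance, "stitchDistance")
  .checkPositiveScalar(tssExclusion, "tssExclusion", strict = FALSE)
  if (tssExclusion > 0) {
    if (is.null(tss))
      stop("tss must be supplied when tssExclusion > 0", call. = FALSE)
    excl <- makePromoters(tss, window = tssExclusion)
    inside <- overlapsAny(peaks, excl, type = "within", ignore.strand = TRUE)
    peaks <- peaks[!inside]
  }
  if (!length(peaks)) {
    gr <- GRanges()
    mcols(gr)$totalSignal <- numeric(0)
    mcols(gr)$nConstituents <- integer(0)
    mcols(gr)$constituentIds <- IRanges::CharacterList()
    return(gr)
  }
  regions <- GenomicRanges::reduce(granges(peaks),
                                   min.gapwidth = stitchDistance + 1L,
                                   ignore.strand = TRUE)
  h <- findOverlaps(peaks, regions, select = "first")
  mcols(regions)$totalSignal <-
    unname(rowsum(mcols(peaks)$signal,
                  factor(h, levels = seq_len(length(regions))))[, 1])
  mcols(regions)$nConstituents <- as.integer(table(factor(h,
    levels = seq_len(length(regions)))))
  mcols(regions)$constituentIds <- unname(IRanges::CharacterList(
    split(mcols(peaks)$peakId, factor(h, levels = seq_len(length(regions))))))
  regions
}

# Rank-curve inflection on min-max scaled axes: x = rank index in [0,1]
# (ascending signal), y = scaled signal in [0,1]. The cutoff sits where the
# curve's slope crosses 1: left of it the curve rises slower than the
# diagonal, right of it faster. On the discrete curve that is the point of
# maximum distance below the diagonal, max(x - y); ties resolve to the
# rightmost such point (fewer super-enhancers). Robust to adjacent near-ties,
# unlike the raw point-to-point slope. Returns the index into the ascending
# order.
.inflectionIndex <- function(sortedSignals) {
  n <- length(sortedSignals)
  y <- (sortedSignals - sortedSignals[1]) /
       (sortedSignals[n] - sortedSignals[1])
  x <- (seq_len(n) - 1) / (n - 1)
  d <- x - y
  max(which(d >= max(d) - sqrt(.Machine$double.eps) * max(1, abs(max(d)))))
}

#' Call super-enhancers by rank-curve inflection
#'
#' Stitched regions are ranked by total signal; both axes of the rank curve
#' are min-max scaled to [0, 1] and the cutoff is placed at the inflection
#' where the curve's slope crosses 1: the point of maximum distance below
#' the scaled diagonal (ties resolve to the rightmost point, i.e. fewer
#' calls). Regions with total signal strictly above the cutoff are
#' super-enhancers. The calls are invariant under any affine rescaling
#' \code{a * signal + b} (a > 0) of all signals.
#'
#' @param stitched stitched regions from \code{\link{stitchPeaks}}.
#' @return a \code{\link{SuperEnhancerCalls}}; regions keep their genomic
#'   order, \code{rank} 1 marks the highest signal.
#' @export
rankSuperEnhancers <- function(stitched) {
  n <- length(stitched)
  sig <- mcols(stitched)$totalSignal
  if (is.null(sig)) stop("stitched regions must carry totalSignal",
                         call. = FALSE)
  if (n == 0L)
    return(methods::new("SuperEnhancerCalls", regions = {
      gr <- stitched
      mcols(gr)$rank <- integer(0); mcols(gr)$isSuper <- logical(0); gr
    }, cutoffSignal = NA_real_, metadata = list()))
  rk <- as.integer(rank(-sig, ties.method = "first"))
  if (n < 3L || length(unique(sig)) == 1L) {
    if (length(unique(sig)) == 1L)
      warning("all stitched signals identical; no super-enhancers called",
              call. = FALSE)
    cutoff <- max(sig)
  } else {
    ordAsc <- order(sig, start(stitched), end(stitched))
    cutoff <- sig[ordAsc][.inflectionIndex(sig[ordAsc])]
  }
  mcols(stitched)$rank <- rk
  mcols(stitched)$isSuper <- sig > cutoff
  methods::new("SuperEnhancerCalls", regions = stitched,
               cutoffSignal = cutoff,
               metadata = list(nSuper = sum(sig > cutoff)))
}

#' Call super-enhancers from enhancer peaks
#'
#' Convenience wrapper: \code{\link{stitchPeaks}} followed by
#' \code{\link{rankSuperEnhancers}}.
#'
#' @inheritParams stitchPeaks
#' @return a \code{\link{SuperEnhancerCalls}}.
#' @export
callSuperEnhancers <- function(peaks, stitchDistance = 12500,
                               tssExclusion = 0, tss = NULL) {
  rankSuperEnhancers(stitchPeaks(peaks, stitchDistance, tssExclusion, tss))
}

#' Link super-enhancers to target genes through loops
#'
#' A link (SE, gene) is reported when some loop has one anchor overlapping
#' the SE region (>= 1 bp) and the other anchor overlapping the gene's
#' promoter window. Duplicate links are collapsed; supporting loop ids are
#' retained.
#'
#' @param seCalls a \code{\link{SuperEnhancerCalls}}; only regions flagged
#'   \code{isSuper} are linked (set \code{superOnly = FALSE} to link all
#'   stitched regions).
#' @param edges a \code{\link{ConnectomeEdges}} or \code{\link{LoopSet}} from
#'   the same sample.
#' @param promoters promoter windows from \code{\link{makePromoters}}.
#' @param superOnly restrict to super-enhancer regions (default TRUE).
#' @return data.frame with columns \code{seIndex} (index into
#'   \code{seRegions(seCalls)}), \code{seRegion} (label), \code{geneId},
#'   \code{loopIds} (comma-separated supporting loops), \code{nLoops}.
#' @export
linkSEToGenes <- function(seCalls, edges, promoters, superOnly = TRUE) {
  stopifnot(methods::is(seCalls, "SuperEnhancerCalls"))
  loops <- if (methods::is(edges, "ConnectomeEdges")) edgeLoops(edges)
           else edges
  stopifnot(methods::is(loops, "LoopSet"))
  regions <- seRegions(seCalls)
  keep <- if (superOnly) which(mcols(regions)$isSuper)
          else seq_along(regions)
  empty <- data.frame(seIndex = integer(0), seRegion = character(0),
                      geneId = character(0), loopIds = character(0),
                      nLoops = integer(0), stringsAsFactors = FALSE)
  if (!length(keep) || !length(loops) || !length(promoters)) return(empty)
  se <- regions[keep]
  hits <- list()
  for (side in 1:2) {
    aSE <- if (side == 1) loops@anchor1 else loops@anchor2
    aPr <- if (side == 1) loops@anchor2 else loops@anchor1
    hSE <- findOverlaps(aSE, se, ignore.strand = TRUE)
    hPr <- findOverlaps(aPr, promoters, ignore.strand = TRUE)
    # join on loop index
    common <- intersect(queryHits(hSE), queryHits(hPr))
    if (!length(common)) next
    seBy <- split(subjectHits(hSE), queryHits(hSE))
    prBy <- split(subjectHits(hPr), queryHits(hPr))
    for (li in common) {
      k <- as.character(li)
      grid <- expand.grid(seLocal = seBy[[k]], pr = prBy[[k]])
      hits[[length(hits) + 1L]] <- data.frame(
        seIndex = keep[grid$seLocal],
        geneId = mcols(promoters)$geneId[grid$pr],
        loopId = loops@loopId[li], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  all <- unique(do.call(rbind, hits))
  key <- paste(all$seIndex, all$geneId, sep = "\r")
  first <- !duplicated(key)
  loopsBy <- split(all$loopId, factor(key, levels = key[first]))
  out <- data.frame(
    seIndex = all$seIndex[first],
    seRegion = .intervalLabel(regions[all$seIndex[first]]),
    geneId = all$geneId[first],
    loopIds = vapply(loopsBy, function(v) paste(sort(unique(v)),
                                                collapse = ","), character(1)),
    nLoops = vapply(loopsBy, function(v) length(unique(v)), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$seIndex, out$geneId), , drop = FALSE]
}

#' Nearest-gene skipping fraction of linked super-enhancers
#'
#' For every SE with at least one linked gene, the nearest gene is the gene
#' whose TSS is closest to the SE region boundary (distance 0 when the TSS
#' lies inside the SE; ties broken by lexicographically smaller gene id). The
#' SE "skips" when its nearest gene is not among its linked genes.
#'
#' @param seLinks data.frame from \code{\link{linkSEToGenes}}.
#' @param seCalls the \code{\link{SuperEnhancerCalls}} the links refer to.
#' @param tss TSS \code{GRanges} with \code{geneId}.
#' @return list with \code{fraction} (skipping SEs / linked SEs), \code{n}
#'   (number of linked SEs) and \code{table} (per-SE nearest gene, linked
#'   genes, skip flag).
#' @export
nearestGeneSkipFraction <- function(seLinks, seCalls, tss) {
  stopifnot(methods::is(seCalls, "SuperEnhancerCalls"))
  .checkTSS(tss)
  if (!length(tss)) stop("tss is empty", call. = FALSE)
  regions <- seRegions(seCalls)
  idx <- sort(unique(seLinks$seIndex))
  if (!length(idx))
    return(list(fraction = NA_real_, n = 0L,
                table = data.frame(seIndex = integer(0),
                                   nearestGene = character(0),
                                   linkedGenes = character(0),
                                   skipsNearest = logical(0))))
  nearest <- vapply(idx, function(i)
    .nearestGeneId(regions[i], tss), character(1))
  linked <- lapply(idx, function(i)
    sort(unique(seLinks$geneId[seLinks$seIndex == i])))
  skips <- !mapply(function(nr, lk) nr %in% lk, nearest, linked)
  list(fraction = mean(skips), n = length(idx),
       table = data.frame(
         seIndex = idx,
         nearestGene = nearest,
         linkedGenes = vapply(linked, paste, character(1), collapse = ","),
         skipsNearest = unname(skips),
         stringsAsFactors = FALSE))
}

# nearest gene to a region: min boundary distance to TSS (0 inside), ties by
# smaller gene id; genes on other chromosomes are infinitely far
.nearestGeneId <- function(region, tss) {
  d <- suppressWarnings(GenomicRanges::distance(region, tss,
                                                ignore.strand = TRUE))
  d[is.na(d)] <- Inf
  ids <- mcols(tss)$geneId
  cand <- which(d == min(d))
  cand <- cand[order(ids[cand])]
  ids[cand[1]]
}
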