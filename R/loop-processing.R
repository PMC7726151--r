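#' Depth-normalize loop counts
#'
#' Loop scores are normalized by the total number of valid interaction read
#' pairs of the sample, rescaled to a common reference depth so that
#' normalized values stay on the read-pair scale:
#' \code{normCount = rawCount * referenceDepth / totalValidPairs}. With the
#' reference depth equal to the smallest sample depth in a run, the classic
#' "minimum of three normalized read pairs" retention rule remains meaningful.
#'
#' @param loops a \code{\link{LoopSet}}.
#' @param totalValidPairs the sample's total valid interaction read pairs
#'   (positive integer).
#' @param referenceDepth common reference depth (positive integer); e.g. the
#'   minimum depth across the samples being compared.
#' @param sampleId optional; when given it must match \code{sampleId(loops)}.
#' @return the \code{LoopSet} with \code{normCounts} set; raw counts and
#'   order unchanged.
#' @examples
#' a1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' a2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 21000))
#' ls <- LoopSet(a1, a2, rawCount = 6L, sampleId = "S1")
#' normCounts(normalizeLoops(ls, 2e7, 1e7))  # 3.0
#' @export
normalizeLoops <- function(loops, totalValidPairs, referenceDepth,
                           sampleId = NULL) {
  stopifnot(methods::is(loops, "LoopSet"))
  .checkPositiveScalar(totalValidPairs, "totalValidPairs")
  .checkPositiveScalar(referenceDepth, "referenceDepth")
  if (!is.null(sampleId) && !identical(sampleId, loops@sampleId))
    stop(sprintf("sample mismatch: depth is for '%s' but loops are from '%s'",
                 sampleId, loops@sampleId), call. = FALSE)
  loops@normCount <- loops@rawCount * referenceDepth / totalValidPairs
  methods::validObject(loops)
  loops
}

#' Merge loop anchors within a gap distance
#'
#' All anchors of the sample (left and right pooled) are clustered by single
#' linkage: two anchors belong to one cluster when the gap between their
#' intervals (0 if they overlap) is at most \code{gap} bp, transitively. Each
#' anchor is replaced by its cluster's spanning interval. Loops whose two
#' anchors fall into the same cluster are dropped as self-loops; loops that
#' become coordinate-identical are collapsed with raw and normalized counts
#' summed.
#'
#' @param loops a \code{\link{LoopSet}}.
#' @param gap maximum inter-anchor gap in bp to merge (default 1500).
#' @return a \code{LoopSet}; \code{metadata} records
#'   \code{selfLoopsDropped} and \code{loopsCollapsed}.
#' @export
mergeAnchors <- function(loops, gap = 1500) {
  stopifnot(methods::is(loops, "LoopSet"))
  .checkPositiveScalar(gap, "gap", strict = FALSE)
  if (!length(loops)) return(loops)
  pooled <- c(granges(loops@anchor1), granges(loops@anchor2))
  clusters <- GenomicRanges::reduce(pooled, min.gapwidth = gap + 1L,
                                    ignore.strand = TRUE)
  n <- length(loops)
  h <- findOverlaps(pooled, clusters, select = "first")
  h1 <- h[seq_len(n)]
  h2 <- h[n + seq_len(n)]
  self <- h1 == h2
  nSelf <- sum(self)
  h1 <- h1[!self]; h2 <- h2[!self]
  raw <- loops@rawCount[!self]
  nrm <- loops@normCount[!self]
  # canonical ordering on cluster indices (clusters are coordinate-sorted
  # within a chromosome)
  swap <- start(clusters)[h1] > start(clusters)[h2]
  tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
  key <- paste(h1, h2)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  rawSum <- as.integer(rowsum(raw, idx)[, 1])
  nrmSum <- if (all(is.na(nrm))) rep(NA_real_, sum(first))
            else unname(rowsum(nrm, idx)[, 1])
  nCollapsed <- length(key) - sum(first)
  md <- loops@metadata
  md$selfLoopsDropped <- nSelf
  md$loopsCollapsed <- nCollapsed
  LoopSet(clusters[h1[first]], clusters[h2[first]], rawSum, nrmSum,
          loops@sampleId, metadata = md)
}

#' Filter loops by length and normalized strength
#'
#' Retains loops whose length (distance between the two anchor midpoints) is
#' at least \code{minLength} bp and whose normalized count is at least
#' \code{minNormCount}; thresholds are inclusive. Relative order is
#' preserved. The removal tally per criterion is stored in
#' \code{metadata(x)$filterReport} (a loop failing both criteria is counted
#' under both).
#'
#' @param loops a \code{\link{LoopSet}} with normalized counts set.
#' @param minLength minimum loop length in bp (default 5000).
#' @param minNormCount minimum normalized read-pair count (default 3).
#' @return the retained \code{LoopSet}.
#' @export
filterLoops <- function(loops, minLength = 5000, minNormCount = 3) {
  stopifnot(methods::is(loops, "LoopSet"))
  .checkPositiveScalar(minLength, "minLength")
  .checkPositiveScalar(minNormCount, "minNormCount")
  if (length(loops) && any(is.na(loops@normCount)))
    stop("normalized counts are unset; run normalizeLoops() first",
         call. = FALSE)
  len <- loopLength(loops)
  short <- len < minLength
  weak <- loops@normCount < minNormCount
  keep <- !short & !weak
  out <- loops[keep]
  out@metadata <- loops@metadata
  out@metadata$filterReport <- list(
    input = length(loops),
    retained = sum(keep),
    removedShort = sum(short),
    removedWeak = sum(weak),
    minLength = minLength,
    minNormCount = minNormCount)
  out
}

#' Filter report of a processed LoopSet
#' @param loops a \code{\link{LoopSet}} returned by \code{\link{filterLoops}}.
#' @return the stored filter report list, or \code{NULL}.
#' @export
filterReport <- function(loops) {
  stopifnot(methods::is(loops, "LoopSet"))
  loops@metadata$filterReport
}
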