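#' Construct a LoopSet
#'
#' Builds a validated \code{\link{LoopSet}} from two parallel anchor
#' \code{GRanges}. Anchors are swapped into canonical order (leftmost first)
#' where needed; inter-chromosomal pairs are rejected.
#'
#' @param anchor1,anchor2 \code{GRanges} of equal length.
#' @param rawCount integer vector of supporting read pairs (>= 1).
#' @param normCount numeric vector of normalized counts, or \code{NA}
#'   (recycled) when not yet computed.
#' @param sampleId single string naming the sample.
#' @param loopId character vector of loop ids; autogenerated when \code{NULL}.
#' @param metadata list of provenance.
#' @return a \code{LoopSet}.
#' @examples
#' a1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' a2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 21000))
#' LoopSet(a1, a2, rawCount = 6L, sampleId = "S1")
#' @export
LoopSet <- function(anchor1, anchor2, rawCount, normCount = NA_real_,
                    sampleId, loopId = NULL, metadata = list()) {
  .checkScalarString(sampleId, "sampleId")
  n <- length(anchor1)
  if (length(anchor2) != n)
    stop("anchor1 and anchor2 must have equal length", call. = FALSE)
  rawCount <- as.integer(rawCount)
  normCount <- as.numeric(normCount)
  if (length(rawCount) == 1L) rawCount <- rep(rawCount, n)
  if (length(normCount) == 1L) normCount <- rep(normCount, n)
  if (n > 0L) {
    if (any(as.character(seqnames(anchor1)) != as.character(seqnames(anchor2))))
      stop("loops must be intra-chromosomal", call. = FALSE)
    swap <- start(anchor1) > start(anchor2)
    if (any(swap)) {
      tmp <- anchor1[swap]
      anchor1[swap] <- anchor2[swap]
      anchor2[swap] <- tmp
    }
  }
  if (is.null(loopId))
    loopId <- if (n) sprintf("loop%05d", seq_len(n)) else character(0)
  mcols(anchor1) <- NULL
  mcols(anchor2) <- NULL
  methods::new("LoopSet", anchor1 = anchor1, anchor2 = anchor2,
               loopId = as.character(loopId), rawCount = rawCount,
               normCount = normCount, sampleId = sampleId,
               metadata = metadata)
}

#' @rdname connectome-accessors
#' @export
setMethod("anchors", "LoopSet", function(x, type = "both", ...) {
  switch(as.character(type),
         "1" = x@anchor1,
         "2" = x@anchor2,
         "both" = list(anchor1 = x@anchor1, anchor2 = x@anchor2),
         stop("type must be 1, 2 or 'both'"))
})

#' @rdname connectome-accessors
#' @export
setMethod("rawCounts", "LoopSet", function(x) x@rawCount)

#' @rdname connectome-accessors
#' @export
setMethod("normCounts", "LoopSet", function(x) x@normCount)

#' @rdname connectome-accessors
#' @export
setMethod("loopIds", "LoopSet", function(x) x@loopId)

#' @rdname connectome-accessors
#' @export
setMethod("sampleId", "LoopSet", function(x) x@sampleId)

#' @describeIn connectome-accessors the full looped region per loop, from the
#'   left edge of anchor1 to the right edge of anchor2.
#' @export
setMethod("loopSpan", "LoopSet", function(x) {
  GRanges(seqnames(x@anchor1),
          IRanges(start(x@anchor1), end(x@anchor2)))
})

#' @describeIn connectome-accessors loop length in bp, the distance between
#'   the two anchor midpoints.
#' @export
setMethod("loopLength", "LoopSet", function(x) {
  .mid0(x@anchor2) - .mid0(x@anchor1)
})

#' @export
setMethod("length", "LoopSet", function(x) length(x@anchor1))

#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = TRUE) {
  methods::initialize(x,
    anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
    loopId = x@loopId[i], rawCount = x@rawCount[i],
    normCount = x@normCount[i])
})

#' @export
setMethod("show", "LoopSet", function(object) {
  cat(sprintf("LoopSet with %d loop%s (sample '%s')\n",
              length(object), if (length(object) == 1L) "" else "s",
              object@sampleId))
  if (length(object)) {
    nset <- sum(!is.na(object@normCount))
    cat(sprintf("  raw counts: %d..%d; normalized set for %d/%d loops\n",
                min(object@rawCount), max(object@rawCount), nset,
                length(object)))
    ll <- loopLength(object)
    cat(sprintf("  loop length (midpoint distance): %d..%d bp\n",
                min(ll), max(ll)))
  }
  invisible(NULL)
})

#' Coerce a LoopSet to a data.frame
#'
#' Columns use on-disk BEDPE conventions (0-based half-open anchor
#' coordinates).
#'
#' @param x a \code{LoopSet}.
#' @param row.names,optional,... ignored; present for generic compatibility.
#' @return a data.frame with one row per loop.
#' @export
as.data.frame.LoopSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    chrom1 = as.character(seqnames(x@anchor1)),
    start1 = .start0(x@anchor1), end1 = .end0(x@anchor1),
    chrom2 = as.character(seqnames(x@anchor2)),
    start2 = .start0(x@anchor2), end2 = .end0(x@anchor2),
    loopId = x@loopId, rawCount = x@rawCount, normCount = x@normCount,
    stringsAsFactors = FALSE)
}

#' Concatenate replicate loop sets of one sample
#'
#' Replicate loop files of the same sample are concatenated and loops with
#' identical anchor coordinates are collapsed into one loop with raw (and any
#' normalized) counts summed.
#'
#' @param ... \code{LoopSet} objects, or a single list of them.
#' @param sampleId sample id for the result; defaults to the common id of the
#'   inputs (an error if they disagree).
#' @return a \code{LoopSet}.
#' @export
concatLoopSets <- function(..., sampleId = NULL) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) &&
      !methods::is(args[[1]], "LoopSet"))
    args <- args[[1]]
  if (!length(args)) stop("no LoopSet supplied", call. = FALSE)
  for (ls in args)
    if (!methods::is(ls, "LoopSet")) stop("inputs must be LoopSet objects")
  sids <- unique(vapply(args, function(ls) ls@sampleId, character(1)))
  if (is.null(sampleId)) {
    if (length(sids) != 1L)
      stop("inputs have differing sampleIds; pass sampleId explicitly")
    sampleId <- sids
  }
  a1 <- do.call(c, unname(lapply(args, function(ls) ls@anchor1)))
  a2 <- do.call(c, unname(lapply(args, function(ls) ls@anchor2)))
  raw <- unlist(lapply(args, function(ls) ls@rawCount))
  nrm <- unlist(lapply(args, function(ls) ls@normCount))
  ids <- unlist(lapply(args, function(ls) ls@loopId))
  if (!length(a1))
    return(LoopSet(a1, a2, integer(0), numeric(0), sampleId))
  key <- paste(as.character(seqnames(a1)), start(a1), end(a1),
               start(a2), end(a2))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  rawSum <- as.integer(rowsum(raw, idx)[, 1])
  nrmSum <- if (all(is.na(nrm))) rep(NA_real_, sum(first))
            else unname(rowsum(nrm, idx)[, 1])
  LoopSet(a1[first], a2[first], rawSum, nrmSum, sampleId,
          loopId = make.unique(ids[first], sep = "_"))
}
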