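#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

#' LoopSet: a set of intra-chromosomal chromatin loops
#'
#' A \code{LoopSet} stores paired loop anchors as two parallel
#' \link[GenomicRanges]{GRanges} objects together with the raw supporting
#' read-pair count and (once computed) the depth-normalized count. Anchors are
#' kept in canonical order: for every loop, \code{anchor1} starts at or before
#' \code{anchor2} on the same chromosome. Only intra-chromosomal loops are
#' representable.
#'
#' @slot anchor1,anchor2 \code{GRanges} of equal length; per-loop left/right
#'   anchors on a common chromosome.
#' @slot loopId character vector of loop identifiers.
#' @slot rawCount integer vector, supporting read pairs (>= 1).
#' @slot normCount numeric vector, depth-normalized counts (\code{NA} until
#'   \code{\link{normalizeLoops}} is run).
#' @slot sampleId length-one character, the sample the loops belong to.
#' @slot metadata list of provenance (skipped rows, filter reports, ...).
#'
#' @seealso \code{\link{readLoops}}, \code{\link{normalizeLoops}},
#'   \code{\link{mergeAnchors}}, \code{\link{filterLoops}}
#' @exportClass LoopSet
setClass("LoopSet",
  representation(
    anchor1  = "GRanges",
    anchor2  = "GRanges",
    loopId   = "character",
    rawCount = "integer",
    normCount = "numeric",
    sampleId = "character",
    metadata = "list"
  )
)

setValidity("LoopSet", function(object) {
  n <- length(object@anchor1)
  msgs <- character(0)
  if (length(object@anchor2) != n ||
      length(object@rawCount) != n ||
      length(object@normCount) != n ||
      length(object@loopId) != n)
    msgs <- c(msgs, "anchor1, anchor2, loopId, rawCount and normCount must have equal length")
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  if (length(msgs) == 0L && n > 0L) {
    if (any(as.character(seqnames(object@anchor1)) !=
            as.character(seqnames(object@anchor2))))
      msgs <- c(msgs, "loops must be intra-chromosomal")
    if (any(start(object@anchor1) > start(object@anchor2)))
      msgs <- c(msgs, "anchors must be canonically ordered (anchor1 leftmost)")
    if (any(is.na(object@rawCount)) || any(object@rawCount < 1L))
      msgs <- c(msgs, "rawCount must be >= 1")
    if (any(!is.na(object@normCount) & object@normCount < 0))
      msgs <- c(msgs, "normCount must be non-negative where set")
  }
  if (length(msgs)) msgs else TRUE
})

#' ElementSet: promoter/enhancer partition of a peak set
#'
#' Partitions one sample's H3K27ac peaks into promoter-class peaks (those
#' overlapping any promoter window by at least 1 bp) and enhancer-class peaks
#' (all remaining peaks). The two classes are exhaustive and mutually
#' exclusive by construction.
#'
#' @slot promoterPeaks,enhancerPeaks \code{GRanges} carrying \code{signal} and
#'   \code{peakId} metadata columns.
#' @seealso \code{\link{classifyElements}}
#' @exportClass ElementSet
setClass("ElementSet",
  representation(promoterPeaks = "GRanges", enhancerPeaks = "GRanges"))

setValidity("ElementSet", function(object) {
  need <- c("signal", "peakId")
  for (slotnm in c("promoterPeaks", "enhancerPeaks")) {
    gr <- slot(object, slotnm)
    if (length(gr) && !all(need %in% names(mcols(gr))))
      return(sprintf("%s must carry 'signal' and 'peakId' metadata columns", slotnm))
  }
  TRUE
})

#' SuperEnhancerCalls: ranked stitched enhancers with an inflection cutoff
#'
#' Holds the stitched enhancer regions of one sample, ranked by total H3K27ac
#' signal, together with the rank-curve inflection cutoff separating
#' super-enhancers from typical enhancers.
#'
#' @slot regions \code{GRanges} with metadata columns \code{totalSignal},
#'   \code{rank} (1 = highest signal), \code{isSuper},
#'   \code{nConstituents} and \code{constituentIds} (CharacterList).
#' @slot cutoffSignal single numeric; calls with \code{totalSignal} strictly
#'   above it are super-enhancers.
#' @slot metadata list.
#' @seealso \code{\link{stitchPeaks}}, \code{\link{rankSuperEnhancers}}
#' @exportClass SuperEnhancerCalls
setClass("SuperEnhancerCalls",
  representation(regions = "GRanges", cutoffSignal = "numeric",
                 metadata = "list"))

setValidity("SuperEnhancerCalls", function(object) {
  gr <- object@regions
  need <- c("totalSignal", "rank", "isSuper")
  if (length(gr)) {
    if (!all(need %in% names(mcols(gr))))
      return("regions must carry totalSignal, rank and isSuper")
    if (!setequal(mcols(gr)$rank, seq_len(length(gr))))
      return("ranks must be a permutation of 1..N")
    if (length(object@cutoffSignal) != 1L)
      return("cutoffSignal must be a single number")
    if (!identical(unname(mcols(gr)$isSuper),
                   unname(mcols(gr)$totalSignal > object@cutoffSignal)))
      return("isSuper must equal totalSignal > cutoffSignal")
  }
  TRUE
})

#' ConnectomeEdges: loops annotated by regulatory-element class
#'
#' Each loop of a \code{\link{LoopSet}} is annotated with the element class of
#' its two anchors: \code{P} (overlaps a promoter window), \code{E} (overlaps
#' an enhancer-class peak), or \code{O} (neither), with precedence P > E > O.
#' The unordered pair gives the edge class \code{EE}, \code{EP}, \code{PP},
#' \code{EO}, \code{PO} or \code{OO}.
#'
#' @slot loops the annotated \code{LoopSet}.
#' @slot edgeClass character vector, one class per loop.
#' @slot elements1,elements2 \code{CharacterList}; ids of the elements
#'   (gene ids for P anchors, peak ids for E anchors) overlapped by each anchor.
#' @slot metadata list; carries per-class counts and the EE/EP/PP fractions.
#' @seealso \code{\link{annotateLoops}}
#' @exportClass ConnectomeEdges
setClass("ConnectomeEdges",
  representation(loops = "LoopSet", edgeClass = "character",
                 elements1 = "CharacterList", elements2 = "CharacterList",
                 metadata = "list"))

setValidity("ConnectomeEdges", function(object) {
  n <- length(object@loops@loopId)
  if (length(object@edgeClass) != n ||
      length(object@elements1) != n || length(object@elements2) != n)
    return("edgeClass/elements must be parallel to the loops")
  ok <- object@edgeClass %in% c("EE", "EP", "PP", "EO", "PO", "OO")
  if (!all(ok)) return("edgeClass values must be in {EE,EP,PP,EO,PO,OO}")
  TRUE
})
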