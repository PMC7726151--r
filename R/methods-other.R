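#' @rdname connectome-accessors
#' @export
setMethod("promoterPeaks", "ElementSet", function(x) x@promoterPeaks)

#' @rdname connectome-accessors
#' @export
setMethod("enhancerPeaks", "ElementSet", function(x) x@enhancerPeaks)

#' @export
setMethod("length", "ElementSet", function(x)
  length(x@promoterPeaks) + length(x@enhancerPeaks))

#' @export
setMethod("show", "ElementSet", function(object) {
  np <- length(object@promoterPeaks)
  ne <- length(object@enhancerPeaks)
  tot <- np + ne
  cat(sprintf("ElementSet: %d peaks (%d promoter-class [%.1f%%], %d enhancer-class)\n",
              tot, np, if (tot) 100 * np / tot else 0, ne))
  invisible(NULL)
})

#' @rdname connectome-accessors
#' @export
setMethod("seRegions", "SuperEnhancerCalls", function(x) x@regions)

#' @rdname connectome-accessors
#' @export
setMethod("totalSignal", "SuperEnhancerCalls", function(x)
  mcols(x@regions)$totalSignal)

#' @rdname connectome-accessors
#' @export
setMethod("isSuper", "SuperEnhancerCalls", function(x)
  mcols(x@regions)$isSuper)

#' @rdname connectome-accessors
#' @export
setMethod("cutoffSignal", "SuperEnhancerCalls", function(x) x@cutoffSignal)

#' @export
setMethod("length", "SuperEnhancerCalls", function(x) length(x@regions))

#' @export
setMethod("show", "SuperEnhancerCalls", function(object) {
  n <- length(object@regions)
  ns <- sum(mcols(object@regions)$isSuper)
  cat(sprintf("SuperEnhancerCalls: %d stitched regions, %d super-enhancers\n",
              n, ns))
  cat(sprintf("  signal cutoff (rank-curve inflection): %.4g\n",
              object@cutoffSignal))
  invisible(NULL)
})

#' @rdname connectome-accessors
#' @export
setMethod("edgeClass", "ConnectomeEdges", function(x) x@edgeClass)

#' @describeIn connectome-accessors the underlying annotated loops.
#' @param ... passed on.
#' @export
setMethod("anchors", "ConnectomeEdges", function(x, type = "both", ...)
  anchors(x@loops, type = type, ...))

#' @export
setMethod("length", "ConnectomeEdges", function(x) length(x@loops))

#' @rdname connectome-accessors
#' @export
setMethod("loopIds", "ConnectomeEdges", function(x) loopIds(x@loops))

#' Loops underlying an edge set
#' @param x a \code{ConnectomeEdges}.
#' @return the annotated \code{LoopSet}.
#' @export
edgeLoops <- function(x) {
  stopifnot(methods::is(x, "ConnectomeEdges"))
  x@loops
}

#' Element ids overlapped by the loop anchors
#' @param x a \code{ConnectomeEdges}.
#' @param type 1 or 2.
#' @return a \code{CharacterList}, one element vector per loop.
#' @export
edgeElements <- function(x, type = 1) {
  stopifnot(methods::is(x, "ConnectomeEdges"))
  if (type == 1) x@elements1 else x@elements2
}

#' @export
setMethod("show", "ConnectomeEdges", function(object) {
  n <- length(object@loops)
  cat(sprintf("ConnectomeEdges: %d annotated loops (sample '%s')\n",
              n, object@loops@sampleId))
  if (n) {
    tab <- table(factor(object@edgeClass,
                        levels = c("EE", "EP", "PP", "EO", "PO", "OO")))
    cat("  ", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                    collapse = "  "), "\n", sep = "")
  }
  invisible(NULL)
})

#' Coerce ConnectomeEdges to a data.frame
#'
#' @param x a \code{ConnectomeEdges}.
#' @param row.names,optional,... ignored.
#' @return loop coordinates/counts plus \code{class}, \code{elements1},
#'   \code{elements2} (comma-separated).
#' @export
as.data.frame.ConnectomeEdges <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  df <- as.data.frame(x@loops)
  df$class <- x@edgeClass
  df$elements1 <- vapply(as.list(x@elements1), paste, character(1),
                         collapse = ",")
  df$elements2 <- vapply(as.list(x@elements2), paste, character(1),
                         collapse = ",")
  df
}
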