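#' Accessor generics
#'
#' Accessors for the package's S4 containers. \code{anchors()} extracts the
#' loop anchors (one side or both), \code{rawCounts()}/\code{normCounts()} the
#' supporting read-pair counts, \code{loopIds()} and \code{sampleId()} the
#' identifiers. \code{seRegions()}, \code{totalSignal()}, \code{isSuper()} and
#' \code{cutoffSignal()} access super-enhancer calls; \code{edgeClass()} the
#' loop class labels; \code{promoterPeaks()}/\code{enhancerPeaks()} the two
#' halves of an \code{\link{ElementSet}}.
#'
#' @param x the object.
#' @param type which anchor: 1, 2 or \code{"both"}.
#' @param ... further arguments for methods.
#' @return the corresponding component; see the class documentation.
#' @name connectome-accessors
#' @rdname connectome-accessors
NULL

#' @rdname connectome-accessors
#' @export
setGeneric("anchors", function(x, type = "both", ...) standardGeneric("anchors"))

#' @rdname connectome-accessors
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname connectome-accessors
#' @export
setGeneric("normCounts", function(x) standardGeneric("normCounts"))

#' @rdname connectome-accessors
#' @export
setGeneric("loopIds", function(x) standardGeneric("loopIds"))

#' @rdname connectome-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname connectome-accessors
#' @export
setGeneric("loopSpan", function(x) standardGeneric("loopSpan"))

#' @rdname connectome-accessors
#' @export
setGeneric("loopLength", function(x) standardGeneric("loopLength"))

#' @rdname connectome-accessors
#' @export
setGeneric("promoterPeaks", function(x) standardGeneric("promoterPeaks"))

#' @rdname connectome-accessors
#' @export
setGeneric("enhancerPeaks", function(x) standardGeneric("enhancerPeaks"))

#' @rdname connectome-accessors
#' @export
setGeneric("seRegions", function(x) standardGeneric("seRegions"))

#' @rdname connectome-accessors
#' @export
setGeneric("totalSignal", function(x) standardGeneric("totalSignal"))

#' @rdname connectome-accessors
#' @export
setGeneric("isSuper", function(x) standardGeneric("isSuper"))

#' @rdname connectome-accessors
#' @export
setGeneric("cutoffSignal", function(x) standardGeneric("cutoffSignal"))

#' @rdname connectome-accessors
#' @export
setGeneric("edgeClass", function(x) standardGeneric("edgeClass"))
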