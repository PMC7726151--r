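#' Build promoter windows around TSSs
#'
#' One window per gene, spanning TSS +/- \code{window} bp regardless of
#' strand (the window is symmetric), clipped at the chromosome start.
#'
#' @param tss width-1 \code{GRanges} with a \code{geneId} column (from
#'   \code{\link{readTSS}}).
#' @param window half-width in bp (default 2000).
#' @return \code{GRanges} of promoter windows with \code{geneId}.
#' @export
makePromoters <- function(tss, window = 2000) {
  .checkTSS(tss)
  .checkPositiveScalar(window, "window")
  if (!length(tss)) {
    gr <- GRanges(); mcols(gr)$geneId <- character(0); return(gr)
  }
  t0 <- .start0(tss)  # 0-based TSS position
  gr <- .gr0(as.character(seqnames(tss)), pmax(0L, t0 - as.integer(window)),
             t0 + as.integer(window))
  mcols(gr)$geneId <- mcols(tss)$geneId
  gr
}

#' Partition peaks into promoter- and enhancer-class elements
#'
#' A peak overlapping any promoter window by at least 1 bp is
#' promoter-class; every remaining peak is enhancer-class ("identified
#' H3K27ac binding regions except those located at promoter regions").
#'
#' @param peaks \code{GRanges} with \code{signal} and \code{peakId}.
#' @param promoters promoter windows from \code{\link{makePromoters}}.
#' @return an \code{\link{ElementSet}}.
#' @export
classifyElements <- function(peaks, promoters) {
  .checkPeaks(peaks)
  atProm <- overlapsAny(peaks, promoters, ignore.strand = TRUE)
  methods::new("ElementSet",
               promoterPeaks = peaks[atProm],
               enhancerPeaks = peaks[!atProm])
}

.anchorLabels <- function(anchor, elements, promoters) {
  p <- overlapsAny(anchor, promoters, ignore.strand = TRUE)
  e <- overlapsAny(anchor, enhancerPeaks(elements), ignore.strand = TRUE)
  ifelse(p, "P", ifelse(e, "E", "O"))  # precedence P > E > O
}

.anchorElementIds <- function(anchor, labels, elements, promoters) {
  n <- length(anchor)
  out <- vector("list", n)
  hp <- findOverlaps(anchor, promoters, ignore.strand = TRUE)
  he <- findOverlaps(anchor, enhancerPeaks(elements), ignore.strand = TRUE)
  pIds <- split(mcols(promoters)$geneId[subjectHits(hp)],
                factor(queryHits(hp), levels = seq_len(n)))
  eIds <- split(mcols(enhancerPeaks(elements))$peakId[subjectHits(he)],
                factor(queryHits(he), levels = seq_len(n)))
  for (i in seq_len(n)) {
    out[[i]] <- switch(labels[i],
                       P = as.character(pIds[[i]]),
                       E = as.character(eIds[[i]]),
                       O = character(0))
  }
  IRanges::CharacterList(out)
}

#' Classify loops into enhancer/promoter edge classes
#'
#' Each anchor is labeled \code{P} when it overlaps any promoter window,
#' else \code{E} when it overlaps any enhancer-class peak, else \code{O}
#' (precedence P > E > O). The unordered label pair gives the edge class.
#' Per-class counts, and fractions among the \code{EE}/\code{EP}/\code{PP}
#' classes, are stored in the result's metadata.
#'
#' @param loops a filtered \code{\link{LoopSet}}.
#' @param elements the sample's \code{\link{ElementSet}}.
#' @param promoters promoter windows from \code{\link{makePromoters}}.
#' @return a \code{\link{ConnectomeEdges}}.
#' @export
annotateLoops <- function(loops, elements, promoters) {
  stopifnot(methods::is(loops, "LoopSet"), methods::is(elements, "ElementSet"))
  lab1 <- .anchorLabels(loops@anchor1, elements, promoters)
  lab2 <- .anchorLabels(loops@anchor2, elements, promoters)
  ord <- c(E = 1L, P = 2L, O = 3L)  # canonical class strings EP, EO, PO
  cls <- ifelse(ord[lab1] <= ord[lab2],
                paste0(lab1, lab2), paste0(lab2, lab1))
  cls <- unname(cls)
  counts <- as.list(table(factor(cls, levels = c("EE", "EP", "PP",
                                                 "EO", "PO", "OO"))))
  counts <- lapply(counts, as.integer)
  core <- counts$EE + counts$EP + counts$PP
  fractions <- if (core > 0)
    list(EE = counts$EE / core, EP = counts$EP / core, PP = counts$PP / core)
  else list(EE = NA_real_, EP = NA_real_, PP = NA_real_)
  methods::new("ConnectomeEdges",
    loops = loops,
    edgeClass = if (length(loops)) cls else character(0),
    elements1 = .anchorElementIds(loops@anchor1, lab1, elements, promoters),
    elements2 = .anchorElementIds(loops@anchor2, lab2, elements, promoters),
    metadata = list(classCounts = counts, classFractions = fractions))
}

#' Cross-sample shared-peak membership table
#'
#' Peaks from all samples are merged by single-linkage overlap (>= 1 bp) into
#' a universe of merged intervals; each universe interval carries a
#' presence/absence flag per sample, from which counts such as
#' "present in all samples" or "present in subset A but absent in subset B"
#' can be read off for any sample partition.
#'
#' @param peakSets named list (>= 2 entries) of peak \code{GRanges}.
#' @return \code{GRanges} universe with one logical metadata column per
#'   sample; \code{metadata(x)$nCommonAll} counts intervals present in every
#'   sample.
#' @export
sharedPeakMatrix <- function(peakSets) {
  if (!is.list(peakSets) || length(peakSets) < 2L)
    stop("peakSets must be a list of >= 2 per-sample peak GRanges",
         call. = FALSE)
  if (is.null(names(peakSets)) || any(!nzchar(names(peakSets))))
    names(peakSets) <- paste0("sample", seq_along(peakSets))
  pooled <- do.call(c, unname(lapply(peakSets, granges)))
  universe <- GenomicRanges::reduce(pooled, min.gapwidth = 0L,
                                    ignore.strand = TRUE)
  memb <- vapply(peakSets, function(p)
    overlapsAny(universe, p, ignore.strand = TRUE), logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(peakSets)))
  mcols(universe) <- S4Vectors::DataFrame(memb)
  S4Vectors::metadata(universe)$nCommonAll <- sum(rowSums(memb) ==
                                                   length(peakSets))
  universe
}

#' Count universe intervals by sample-presence pattern
#'
#' @param universe result of \code{\link{sharedPeakMatrix}}.
#' @param present sample names that must be present.
#' @param absent sample names that must be absent (default none).
#' @return integer count of universe intervals matching the pattern.
#' @export
countSharedPeaks <- function(universe, present, absent = character(0)) {
  m <- as.matrix(mcols(universe))
  stopifnot(all(present %in% colnames(m)), all(absent %in% colnames(m)))
  ok <- rep(TRUE, nrow(m))
  for (s in present) ok <- ok & m[, s]
  for (s in absent) ok <- ok & !m[, s]
  sum(ok)
}
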