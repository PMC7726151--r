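#' Run the full enhancer-connectome pipeline for one sample
#'
#' Stages run in order: read/concatenate replicate loops, depth-normalize,
#' merge anchors, filter by length and normalized strength; build promoter
#' windows and classify peaks into promoter/enhancer elements; annotate loops
#' into EE/EP/PP (and O-containing) classes; stitch enhancers and call
#' super-enhancers at the rank-curve inflection; link SEs to target genes
#' through the loops and compute the nearest-gene skip fraction; optionally
#' test in-loop factor enrichment (paired signed-rank) and peak-proximity
#' expression association (rank-sum). Any stage error aborts with the stage
#' name.
#'
#' @param peaks peak file path or \code{GRanges} from \code{\link{readPeaks}}.
#' @param loops a loop file path, \code{LoopSet}, or list of either
#'   (replicates; concatenated with counts summed on identical coordinates).
#' @param tss TSS file path or \code{GRanges}.
#' @param sampleId sample name.
#' @param totalValidPairs the sample's total valid interaction read pairs
#'   (sum over replicates).
#' @param referenceDepth reference depth for normalization; \code{"auto"}
#'   (default) uses \code{totalValidPairs} itself, i.e. normalized = raw,
#'   appropriate for a single-sample run.
#' @param factorPeaks optional factor peak file path or \code{GRanges} for
#'   the enrichment test.
#' @param expression optional expression table path or data.frame for the
#'   association test.
#' @param params list of tunable parameters; defaults are
#'   \code{anchorMergeGap = 1500}, \code{minLoopLength = 5000},
#'   \code{minNormCount = 3}, \code{promoterWindow = 2000},
#'   \code{stitchDistance = 12500}, \code{tssExclusion = 0},
#'   \code{upstreamWindow = 20000}.
#' @return list of class \code{ConnectomePipelineResult} with the stage
#'   outputs (\code{loops}, \code{elements}, \code{promoters}, \code{edges},
#'   \code{seCalls}, \code{seLinks}, \code{skip}, \code{enrichment},
#'   \code{expressionTest}) and a validated machine-readable \code{report}.
#' @export
runPipeline <- function(peaks, loops, tss, sampleId,
                        totalValidPairs, referenceDepth = "auto",
                        factorPeaks = NULL, expression = NULL,
                        params = list()) {
  defaults <- list(anchorMergeGap = 1500, minLoopLength = 5000,
                   minNormCount = 3, promoterWindow = 2000,
                   stitchDistance = 12500, tssExclusion = 0,
                   upstreamWindow = 20000)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- utils::modifyList(defaults, params)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (missing(tss) || is.null(tss))
    stop("pipeline stage 'tss' failed: no TSS input supplied", call. = FALSE)

  peaks <- stage("peaks", {
    if (is.character(peaks)) readPeaks(peaks, sampleId) else .checkPeaks(peaks)
  })
  tss <- stage("tss", {
    if (is.character(tss)) readTSS(tss) else .checkTSS(tss)
  })
  loopsIn <- stage("loops", {
    if (!is.list(loops) || methods::is(loops, "LoopSet")) loops <- list(loops)
    sets <- lapply(loops, function(l)
      if (is.character(l)) readLoops(l, sampleId) else l)
    concatLoopSets(sets, sampleId = sampleId)
  })
  .checkPositiveScalar(totalValidPairs, "totalValidPairs")
  refDepth <- if (identical(referenceDepth, "auto")) totalValidPairs
              else referenceDepth
  processed <- stage("loop_processing", {
    l <- normalizeLoops(loopsIn, totalValidPairs, refDepth)
    l <- mergeAnchors(l, gap = params$anchorMergeGap)
    filterLoops(l, minLength = params$minLoopLength,
                minNormCount = params$minNormCount)
  })
  promoters <- stage("promoters", makePromoters(tss, params$promoterWindow))
  elements <- stage("elements", classifyElements(peaks, promoters))
  edges <- stage("annotate", annotateLoops(processed, elements, promoters))
  seCalls <- stage("superenhancers", {
    callSuperEnhancers(enhancerPeaks(elements),
                       stitchDistance = params$stitchDistance,
                       tssExclusion = params$tssExclusion, tss = tss)
  })
  seLinks <- stage("se_links", linkSEToGenes(seCalls, edges, promoters))
  skip <- stage("nearest_gene_skip",
                nearestGeneSkipFraction(seLinks, seCalls, tss))

  enrichment <- NULL
  enrichObs <- NULL
  if (!is.null(factorPeaks)) {
    enrichment <- stage("enrichment", {
      fp <- if (is.character(factorPeaks)) readPeaks(factorPeaks, sampleId)
            else factorPeaks
      seLoopIds <- unique(unlist(strsplit(seLinks$loopIds, ",")))
      seLoops <- processed[loopIds(processed) %in% seLoopIds]
      if (!length(seLoops)) NULL else {
        enrichObs <- loopFactorObservation(seLoops, fp)
        wilcoxonSignedRank(enrichObs, alternative = "greater")
      }
    })
  }
  expressionTest <- NULL
  if (!is.null(expression)) {
    expressionTest <- stage("expression", {
      ex <- if (is.character(expression)) readExpression(expression)
            else expression
      groups <- groupGenesByUpstreamPeak(tss, peaks, params$upstreamWindow)
      a <- ex$expression[ex$geneId %in% groups$withPeak]
      b <- ex$expression[ex$geneId %in% groups$withoutPeak]
      if (!length(a) || !length(b)) NULL
      else rankSumCompare(a, b, alternative = "greater")
    })
  }

  report <- stage("report", {
    cc <- edges@metadata$classCounts
    htestToList <- function(h) if (is.null(h)) NULL else
      list(statistic = unname(h$statistic), pValue = h$p.value,
           n = unname(h$parameter[1]), method = h$method,
           alternative = h$alternative)
    rep <- list(
      sampleId = sampleId,
      parameters = c(params, list(totalValidPairs = totalValidPairs,
                                  referenceDepth = refDepth)),
      nLoopsRaw = length(loopsIn),
      nLoopsFiltered = length(processed),
      filterReport = filterReport(processed),
      classCounts = cc,
      classFractions = edges@metadata$classFractions,
      nPeaks = length(peaks),
      promoterPeakFraction = if (length(peaks))
        length(promoterPeaks(elements)) / length(peaks) else NA_real_,
      nStitched = length(seCalls),
      nSuperEnhancers = sum(isSuper(seCalls)),
      seCutoffSignal = cutoffSignal(seCalls),
      nSEGeneLinks = nrow(seLinks),
      skipFraction = skip$fraction,
      nLinkedSEs = skip$n,
      enrichment = htestToList(enrichment),
      expressionTest = htestToList(expressionTest),
      version = as.character(utils::packageVersion("enhancerConnectome")))
    validateReport(rep)
    rep
  })

  structure(list(report = report, loops = processed, promoters = promoters,
                 elements = elements, edges = edges, seCalls = seCalls,
                 seLinks = seLinks, skip = skip, enrichment = enrichment,
                 enrichmentObservations = enrichObs,
                 expressionTest = expressionTest),
            class = "ConnectomePipelineResult")
}

#' Validate a pipeline report's internal consistency
#'
#' Checks the partition invariants: class counts sum to the filtered loop
#' count, the EE/EP/PP fractions sum to 1 when any such loop exists, the
#' promoter-peak fraction and skip fraction lie in [0, 1], and every p-value
#' lies in [0, 1]. Errors on the first violation.
#'
#' @param report the report list of \code{\link{runPipeline}}.
#' @return \code{TRUE}, invisibly.
#' @export
validateReport <- function(report) {
  cc <- report$classCounts
  if (sum(unlist(cc)) != report$nLoopsFiltered)
    stop("report invariant violated: class counts do not sum to the loop count",
         call. = FALSE)
  fr <- report$classFractions
  core <- cc$EE + cc$EP + cc$PP
  if (core > 0 && abs(sum(unlist(fr)) - 1) > 1e-9)
    stop("report invariant violated: EE/EP/PP fractions do not sum to 1",
         call. = FALSE)
  inUnit <- function(x) is.na(x) || (x >= 0 && x <= 1)
  if (!inUnit(report$promoterPeakFraction))
    stop("report invariant violated: promoterPeakFraction outside [0, 1]",
         call. = FALSE)
  if (!inUnit(report$skipFraction))
    stop("report invariant violated: skipFraction outside [0, 1]",
         call. = FALSE)
  for (tst in list(report$enrichment, report$expressionTest))
    if (!is.null(tst) && !inUnit(tst$pValue))
      stop("report invariant violated: p-value outside [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Print a pipeline result summary
#' @param x a \code{ConnectomePipelineResult}.
#' @param ... ignored.
#' @return \code{x}, invisibly.
#' @export
print.ConnectomePipelineResult <- function(x, ...) {
  r <- x$report
  cat(sprintf("Connectome pipeline result for sample '%s'\n", r$sampleId))
  cat(sprintf("  loops: %d raw -> %d filtered\n", r$nLoopsRaw,
              r$nLoopsFiltered))
  cat(sprintf("  classes: EE %d, EP %d, PP %d (other %d)\n",
              r$classCounts$EE, r$classCounts$EP, r$classCounts$PP,
              r$classCounts$EO + r$classCounts$PO + r$classCounts$OO))
  cat(sprintf("  peaks: %d (%.1f%% at promoters)\n", r$nPeaks,
              100 * r$promoterPeakFraction))
  cat(sprintf("  super-enhancers: %d of %d stitched regions; %d SE-gene links; skip fraction %.2f\n",
              r$nSuperEnhancers, r$nStitched, r$nSEGeneLinks,
              r$skipFraction))
  if (!is.null(r$enrichment))
    cat(sprintf("  in-loop factor enrichment: W = %.1f, p = %.3g\n",
                r$enrichment$statistic, r$enrichment$pValue))
  if (!is.null(r$expressionTest))
    cat(sprintf("  expression association: U = %.1f, p = %.3g\n",
                r$expressionTest$statistic, r$expressionTest$pValue))
  invisible(x)
}
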