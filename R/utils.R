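# Internal coordinate helpers. On disk everything is BED-style 0-based
# half-open; in memory GRanges are 1-based closed. Conversion happens only in
# these helpers and in the IO layer.

# GRanges from 0-based half-open coordinates
.gr0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), ...)
}

# 0-based start / half-open end of a GRanges
.start0 <- function(gr) GenomicRanges::start(gr) - 1L
.end0 <- function(gr) GenomicRanges::end(gr)

# 0-based midpoint, floor((start0 + end0) / 2)
.mid0 <- function(gr) floor((.start0(gr) + .end0(gr)) / 2)

# "chrom:start0-end0" labels (the on-disk coordinate form)
.intervalLabel <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          .start0(gr), .end0(gr))
}

.checkScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty string", call. = FALSE)
  invisible(x)
}

.checkPositiveScalar <- function(x, what, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(what, " must be a ", if (strict) "positive" else "non-negative",
         " number", call. = FALSE)
  invisible(x)
}

# peaks GRanges must carry signal + peakId
.checkPeaks <- function(peaks, what = "peaks") {
  if (!methods::is(peaks, "GRanges"))
    stop(what, " must be a GRanges", call. = FALSE)
  if (length(peaks) &&
      !all(c("signal", "peakId") %in% names(S4Vectors::mcols(peaks))))
    stop(what, " must carry 'signal' and 'peakId' metadata columns",
         call. = FALSE)
  invisible(peaks)
}

.checkTSS <- function(tss, what = "tss") {
  if (!methods::is(tss, "GRanges"))
    stop(what, " must be a GRanges", call. = FALSE)
  if (length(tss) && !("geneId" %in% names(S4Vectors::mcols(tss))))
    stop(what, " must carry a 'geneId' metadata column", call. = FALSE)
  invisible(tss)
}

# Run expr with a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
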