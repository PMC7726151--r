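#' In-loop vs flank factor-peak observations
#'
#' For each loop, the span is the full looped region (left edge of anchor 1
#' to right edge of anchor 2). The inside count is the number of factor peaks
#' whose midpoint lies inside the span; the flank count is the mean of the
#' midpoint counts of two similar-sized regions immediately adjacent on
#' either side (each as wide as the span, clipped at chromosome bounds; when
#' one flank is clipped to zero width the other is used alone). Membership by
#' midpoint keeps a peak from being counted in both the span and a flank.
#'
#' @param loops a \code{\link{LoopSet}} (e.g. the loops linking SEs to their
#'   targets).
#' @param factorPeaks \code{GRanges} of factor (CTCF/SMC1-style) peaks.
#' @param chromLength optional named vector of chromosome lengths used to
#'   clip right flanks.
#' @return data.frame with \code{loopId}, \code{insideCount},
#'   \code{flankCount}, \code{leftClipped}, \code{rightClipped}.
#' @export
loopFactorObservation <- function(loops, factorPeaks, chromLength = NULL) {
  stopifnot(methods::is(loops, "LoopSet"))
  n <- length(loops)
  mids <- .mid0(factorPeaks)
  midChrom <- as.character(seqnames(factorPeaks))
  spanStart <- .start0(loops@anchor1)
  spanEnd <- .end0(loops@anchor2)
  chrom <- as.character(seqnames(loops@anchor1))
  width <- spanEnd - spanStart
  lim <- if (is.null(chromLength)) rep(Inf, n)
         else unname(chromLength[chrom])
  lStart <- pmax(0, spanStart - width); lEnd <- spanStart
  rStart <- spanEnd; rEnd <- pmin(lim, spanEnd + width)
  # midpoints in 0-based half-open [a, b), counted per chromosome via
  # findInterval on sorted midpoints
  midsBy <- split(mids, midChrom)
  midsBy <- lapply(midsBy, sort)
  countIn <- function(c0, a, b) {
    out <- numeric(length(a))
    for (ch in unique(c0)) {
      m <- midsBy[[ch]]
      if (is.null(m)) next
      i <- c0 == ch
      out[i] <- findInterval(b[i] - 1e-9, m) - findInterval(a[i] - 1e-9, m)
    }
    out
  }
  inside <- countIn(chrom, spanStart, spanEnd)
  left <- countIn(chrom, lStart, lEnd)
  right <- countIn(chrom, rStart, rEnd)
  lZero <- (lEnd - lStart) <= 0
  rZero <- (rEnd - rStart) <= 0
  flank <- ifelse(lZero & rZero, 0,
           ifelse(lZero, right, ifelse(rZero, left, (left + right) / 2)))
  data.frame(loopId = loops@loopId,
             insideCount = inside,
             flankCount = flank,
             leftClipped = (spanStart - width) < 0,
             rightClipped = (spanEnd + width) > lim,
             stringsAsFactors = FALSE)
}

# exact null distribution of the positive-rank sum for given |d| ranks:
# enumerate all 2^n sign assignments
.signedRankExactTail <- function(ranks, W, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  n <- length(ranks)
  sums <- 0
  for (r in ranks) sums <- c(sums, sums + r)  # all subset sums, 2^n values
  eps <- sqrt(.Machine$double.eps) * max(1, sum(ranks))
  if (tail == "greater") mean(sums >= W - eps) else mean(sums <= W + eps)
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences \code{inside - flank} are computed per pair; zero differences
#' are discarded; absolute differences are ranked with midranks for ties and
#' the statistic W is the sum of the ranks of the positive differences. The
#' null distribution is enumerated exactly over all sign assignments when the
#' effective n is at most 12 (or when \code{exact = TRUE}); otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param inside numeric vector, or a data.frame/matrix whose first two
#'   columns (or \code{insideCount}/\code{flankCount}) hold the pairs.
#' @param flank numeric vector paired with \code{inside}.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}; "greater" means inside tends to exceed flank.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) exact
#'   enumeration; default \code{NULL} chooses by effective n <= 12.
#' @return an object of class \code{htest} with \code{statistic} (W),
#'   \code{p.value}, \code{parameter} (effective n), \code{method} and
#'   \code{alternative}. All-zero differences give p = 1 with a warning.
#' @examples
#' wilcoxonSignedRank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))$p.value  # 0.0625
#' @export
wilcoxonSignedRank <- function(inside, flank = NULL,
                               alternative = c("two.sided", "greater", "less"),
                               exact = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(flank)) {
    if (is.data.frame(inside) || is.matrix(inside)) {
      df <- as.data.frame(inside)
      cols <- if (all(c("insideCount", "flankCount") %in% names(df)))
        c("insideCount", "flankCount") else names(df)[1:2]
      flank <- df[[cols[2]]]
      inside <- df[[cols[1]]]
    } else stop("supply paired vectors, or a two-column table", call. = FALSE)
  }
  if (length(inside) != length(flank) || !length(inside))
    stop("inside and flank must be non-empty vectors of equal length",
         call. = FALSE)
  d <- inside - flank
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; test is degenerate", call. = FALSE)
    return(structure(list(statistic = c(W = 0), parameter = c(n.effective = 0L),
                          p.value = 1, method = "paired Wilcoxon signed-rank",
                          alternative = alternative,
                          data.name = "inside vs flank"),
                     class = "htest"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  useExact <- if (is.null(exact)) n <= 12L else isTRUE(exact)
  if (useExact) {
    pG <- .signedRankExactTail(r, W, "greater")
    pL <- .signedRankExactTail(r, W, "less")
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pG, pL)),
                greater = pG, less = pL)
    method <- "paired Wilcoxon signed-rank (exact enumeration)"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)  # equals tie-corrected variance
    z <- W - mu
    cc <- 0.5
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm((abs(z) - cc) / sigma, lower.tail = FALSE),
      greater = stats::pnorm((z - cc) / sigma, lower.tail = FALSE),
      less = stats::pnorm((z + cc) / sigma, lower.tail = TRUE))
    p <- min(1, max(0, p))
    method <- "paired Wilcoxon signed-rank (normal approximation)"
  }
  structure(list(statistic = c(W = W), parameter = c(n.effective = n),
                 p.value = p, method = method, alternative = alternative,
                 data.name = "inside vs flank"),
            class = "htest")
}

#' Partition genes by upstream H3K27ac peak presence
#'
#' The upstream region of a gene is strand-aware: for a \code{+} gene the
#' \code{window} bp immediately 5' of the TSS, for a \code{-} gene the
#' \code{window} bp on its 3'-coordinate side (i.e. positions just past the
#' TSS in genome coordinates). A gene is "with peak" when any peak overlaps
#' its upstream region by >= 1 bp.
#'
#' @param tss TSS \code{GRanges} with strand and \code{geneId}.
#' @param peaks peak \code{GRanges}.
#' @param window upstream window in bp (default 20000).
#' @return list with character vectors \code{withPeak} and
#'   \code{withoutPeak}; the two partition all genes.
#' @export
groupGenesByUpstreamPeak <- function(tss, peaks, window = 20000) {
  .checkTSS(tss)
  .checkPositiveScalar(window, "window")
  if (!length(tss)) return(list(withPeak = character(0),
                                withoutPeak = character(0)))
  w <- as.integer(window)
  t0 <- .start0(tss)
  plus <- as.character(strand(tss)) == "+"
  # 0-based half-open upstream windows: + [t0-w, t0), - [t0+1, t0+w+1)
  up0 <- ifelse(plus, pmax(0L, t0 - w), t0 + 1L)
  up1 <- ifelse(plus, t0, t0 + w + 1L)
  nonEmpty <- up1 > up0
  has <- rep(FALSE, length(tss))
  if (any(nonEmpty)) {
    upstream <- .gr0(as.character(seqnames(tss))[nonEmpty],
                     up0[nonEmpty], up1[nonEmpty])
    has[nonEmpty] <- overlapsAny(upstream, peaks, ignore.strand = TRUE)
  }
  ids <- mcols(tss)$geneId
  list(withPeak = ids[has], withoutPeak = ids[!has])
}

#' Mann-Whitney rank-sum comparison of two expression groups
#'
#' U is computed from midranks of the combined sample; the p-value uses the
#' normal approximation with tie correction and continuity correction. With
#' \code{alternative = "greater"} the test asks whether values in \code{a}
#' tend to exceed those in \code{b}.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return an \code{htest} with \code{statistic} (U of a over b),
#'   \code{p.value}, \code{parameter} (group sizes).
#' @examples
#' rankSumCompare(c(3, 4, 5), c(1, 2))$statistic  # U = 6
#' @export
rankSumCompare <- function(a, b,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0) {
    p <- 1  # all values tied
  } else {
    sigma <- sqrt(sigma2)
    z <- U - mu
    cc <- 0.5
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm((abs(z) - cc) / sigma, lower.tail = FALSE),
      greater = stats::pnorm((z - cc) / sigma, lower.tail = FALSE),
      less = stats::pnorm((z + cc) / sigma, lower.tail = TRUE))
    p <- min(1, max(0, p))
  }
  structure(list(statistic = c(U = U),
                 parameter = c(n.a = na, n.b = nb),
                 p.value = p,
                 method = "Mann-Whitney rank-sum (normal approximation)",
                 alternative = alternative,
                 data.name = "a vs b"),
            class = "htest")
}
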