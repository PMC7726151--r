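# Readers/writers for the on-disk formats. Disk coordinates are BED-style
# 0-based half-open throughout; in-memory objects are GRanges (1-based).
# Every input line is parsed, skipped-with-count, or raises an error naming
# its line number.

.readBodyLines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.parseIntStrict <- function(x) {
  ok <- grepl("^-?[0-9]+$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(x[ok])
  out
}

#' Read a peak file (BED3+signal, narrowPeak or broadPeak)
#'
#' For plain BED the fourth column is the signal; for narrowPeak/broadPeak
#' files (>= 7 columns) the name is taken from column 4 and the signal from
#' the signalValue column 7. Coordinates on disk are 0-based half-open.
#' Peak ids are auto-assigned as \code{"chrom:start-end"} when absent.
#'
#' @param path BED-like file with at least 4 tab-separated columns.
#' @param sampleId sample the peaks belong to (stored in
#'   \code{metadata(x)$sampleId}).
#' @return a \code{GRanges} with metadata columns \code{signal} and
#'   \code{peakId}, in input order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t600\t8.5", f)
#' readPeaks(f, "S1")
#' @export
readPeaks <- function(path, sampleId) {
  .checkScalarString(sampleId, "sampleId")
  body <- .readBodyLines(path)
  if (!length(body$lines)) {
    gr <- GRanges()
    mcols(gr)$signal <- numeric(0)
    mcols(gr)$peakId <- character(0)
    S4Vectors::metadata(gr)$sampleId <- sampleId
    return(gr)
  }
  fields <- strsplit(body$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("malformed peak line %d: expected >= 4 columns, got %d",
                 body$lineno[which(nf < 4L)[1]], nf[which(nf < 4L)[1]]),
         call. = FALSE)
  ncols <- min(nf)
  col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- col(1)
  start0 <- .parseIntStrict(col(2))
  end0 <- .parseIntStrict(col(3))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("malformed peak line %d: non-integer coordinates",
                 body$lineno[bad[1]]), call. = FALSE)
  sigcol <- if (ncols >= 7L) 7L else 4L
  signal <- suppressWarnings(as.numeric(col(sigcol)))
  bad <- which(is.na(signal))
  if (length(bad))
    stop(sprintf("malformed peak line %d: non-numeric signal in column %d",
                 body$lineno[bad[1]], sigcol), call. = FALSE)
  bad <- which(start0 >= end0 | start0 < 0L)
  if (length(bad))
    stop(sprintf("invalid peak line %d: requires 0 <= start < end",
                 body$lineno[bad[1]]), call. = FALSE)
  bad <- which(signal < 0)
  if (length(bad))
    stop(sprintf("invalid peak line %d: negative signal",
                 body$lineno[bad[1]]), call. = FALSE)
  peakId <- if (ncols >= 7L) col(4) else rep(".", length(chrom))
  auto <- peakId == "." | !nzchar(peakId)
  gr <- .gr0(chrom, start0, end0)
  peakId[auto] <- .intervalLabel(gr[auto])
  if (anyDuplicated(peakId))
    stop("duplicate peak ids within sample: ",
         paste(unique(peakId[duplicated(peakId)])[1:min(3, sum(duplicated(peakId)))],
               collapse = ", "), call. = FALSE)
  mcols(gr)$signal <- signal
  mcols(gr)$peakId <- peakId
  S4Vectors::metadata(gr)$sampleId <- sampleId
  gr
}

#' Write peaks in a narrowPeak-style layout
#'
#' Emits 7 tab-separated columns (chrom, start, end, peakId, 0, ., signal) so
#' that \code{\link{readPeaks}} round-trips ids and signals exactly.
#'
#' @param peaks \code{GRanges} from \code{\link{readPeaks}} or equivalent.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  .checkPeaks(peaks)
  df <- data.frame(as.character(seqnames(peaks)), .start0(peaks), .end0(peaks),
                   mcols(peaks)$peakId, 0L, ".",
                   format(mcols(peaks)$signal, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a loop file (8/9-column BEDPE)
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, rawCount and
#' optionally normCount (\code{"."} when unset). Anchors are swapped into
#' canonical order; inter-chromosomal rows are skipped with a counted warning
#' (count kept in \code{metadata(x)$interchromosomalSkipped}).
#'
#' @param path BEDPE file.
#' @param sampleId sample the loops belong to.
#' @return a \code{\link{LoopSet}}.
#' @export
readLoops <- function(path, sampleId) {
  .checkScalarString(sampleId, "sampleId")
  body <- .readBodyLines(path)
  if (!length(body$lines))
    return(LoopSet(GRanges(), GRanges(), integer(0), numeric(0), sampleId,
                   metadata = list(interchromosomalSkipped = 0L)))
  fields <- strsplit(body$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L))
    stop(sprintf("malformed loop line %d: expected >= 8 columns",
                 body$lineno[which(nf < 8L)[1]]), call. = FALSE)
  col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom1 <- col(1); chrom2 <- col(4)
  s1 <- .parseIntStrict(col(2)); e1 <- .parseIntStrict(col(3))
  s2 <- .parseIntStrict(col(5)); e2 <- .parseIntStrict(col(6))
  name <- col(7)
  raw <- .parseIntStrict(col(8))
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))
  if (length(bad))
    stop(sprintf("malformed loop line %d: non-integer coordinates",
                 body$lineno[bad[1]]), call. = FALSE)
  bad <- which(is.na(raw))
  if (length(bad))
    stop(sprintf("malformed loop line %d: non-integer read-pair count",
                 body$lineno[bad[1]]), call. = FALSE)
  bad <- which(s1 >= e1 | s2 >= e2 | s1 < 0L | s2 < 0L)
  if (length(bad))
    stop(sprintf("invalid loop line %d: requires 0 <= start < end",
                 body$lineno[bad[1]]), call. = FALSE)
  bad <- which(raw < 1L)
  if (length(bad))
    stop(sprintf("invalid loop line %d: read-pair count must be >= 1",
                 body$lineno[bad[1]]), call. = FALSE)
  nrm <- rep(NA_real_, length(raw))
  has9 <- nf >= 9L
  if (any(has9)) {
    v <- vapply(fields[has9], `[[`, character(1), 9)
    nrm[has9][v != "."] <- suppressWarnings(as.numeric(v[v != "."]))
  }
  intra <- chrom1 == chrom2
  nskip <- sum(!intra)
  if (nskip)
    warning(sprintf("skipped %d inter-chromosomal loop row%s",
                    nskip, if (nskip == 1L) "" else "s"), call. = FALSE)
  keep <- which(intra)
  LoopSet(.gr0(chrom1[keep], s1[keep], e1[keep]),
          .gr0(chrom2[keep], s2[keep], e2[keep]),
          raw[keep], nrm[keep], sampleId,
          loopId = make.unique(name[keep], sep = "_"),
          metadata = list(interchromosomalSkipped = nskip))
}

#' Write loops as 9-column BEDPE
#'
#' Raw and normalized counts go to columns 8 and 9 (\code{"."} when the
#' normalized count is unset).
#'
#' @param loops a \code{\link{LoopSet}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeLoops <- function(loops, path) {
  stopifnot(methods::is(loops, "LoopSet"))
  df <- as.data.frame(loops)
  nrm <- ifelse(is.na(df$normCount), ".",
                format(df$normCount, trim = TRUE, scientific = FALSE))
  out <- data.frame(df$chrom1, df$start1, df$end1, df$chrom2, df$start2,
                    df$end2, df$loopId, df$rawCount, nrm)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcription start sites (BED6 or 4-column TSV)
#'
#' BED6 input is strand-aware: the TSS of a \code{+} gene is the interval
#' start, of a \code{-} gene the last base (\code{end - 1} in 0-based
#' coordinates). TSV input has a single header line and columns
#' \code{gene_id}, \code{chrom}, \code{tss} (0-based), \code{strand}.
#'
#' @param path input file.
#' @return width-1 \code{GRanges} with strand and a \code{geneId} metadata
#'   column.
#' @export
readTSS <- function(path) {
  body <- .readBodyLines(path)
  if (!length(body$lines)) {
    gr <- GRanges()
    mcols(gr)$geneId <- character(0)
    return(gr)
  }
  nf1 <- length(strsplit(body$lines[1], "\t", fixed = TRUE)[[1]])
  if (nf1 == 6L) {
    fields <- strsplit(body$lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 6L))
      stop(sprintf("malformed TSS line %d: expected 6 BED columns",
                   body$lineno[which(lengths(fields) != 6L)[1]]),
           call. = FALSE)
    col <- function(i) vapply(fields, `[[`, character(1), i)
    s0 <- .parseIntStrict(col(2)); e0 <- .parseIntStrict(col(3))
    strand <- col(6)
    bad <- which(is.na(s0) | is.na(e0) | s0 >= e0 | s0 < 0L)
    if (length(bad))
      stop(sprintf("invalid TSS line %d: bad coordinates",
                   body$lineno[bad[1]]), call. = FALSE)
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
      stop(sprintf("invalid TSS line %d: strand must be + or -",
                   body$lineno[bad[1]]), call. = FALSE)
    geneId <- col(4)
    tss0 <- ifelse(strand == "+", s0, e0 - 1L)
    chrom <- col(1)
  } else if (nf1 == 4L) {
    fields <- strsplit(body$lines[-1], "\t", fixed = TRUE)  # drop header
    if (any(lengths(fields) != 4L))
      stop(sprintf("malformed TSS line %d: expected 4 TSV columns",
                   body$lineno[-1][which(lengths(fields) != 4L)[1]]),
           call. = FALSE)
    col <- function(i) vapply(fields, `[[`, character(1), i)
    geneId <- col(1); chrom <- col(2)
    tss0 <- .parseIntStrict(col(3)); strand <- col(4)
    bad <- which(is.na(tss0) | tss0 < 0L)
    if (length(bad))
      stop(sprintf("invalid TSS line %d: tss must be a non-negative integer",
                   body$lineno[-1][bad[1]]), call. = FALSE)
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
      stop(sprintf("invalid TSS line %d: strand must be + or -",
                   body$lineno[-1][bad[1]]), call. = FALSE)
  } else {
    stop("TSS file must be BED6 (6 columns) or TSV (4 columns)", call. = FALSE)
  }
  if (anyDuplicated(geneId))
    stop("duplicate gene ids in TSS file: ",
         paste(unique(geneId[duplicated(geneId)]), collapse = ", "),
         call. = FALSE)
  gr <- .gr0(chrom, tss0, tss0 + 1L, strand = strand)
  mcols(gr)$geneId <- geneId
  gr
}

#' Write transcription start sites as 4-column TSV
#'
#' @param tss width-1 \code{GRanges} with \code{geneId} and strand.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTSS <- function(tss, path) {
  .checkTSS(tss)
  df <- data.frame(gene_id = mcols(tss)$geneId,
                   chrom = as.character(seqnames(tss)),
                   tss = .start0(tss),
                   strand = as.character(strand(tss)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene expression table (2-column TSV with header)
#'
#' @param path TSV with columns gene id and normalized (log-scale) expression.
#' @return data.frame with columns \code{geneId}, \code{expression}.
#' @export
readExpression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  names(df) <- c("geneId", "expression")
  if (anyDuplicated(df$geneId))
    stop("duplicate gene ids in expression table: ",
         paste(unique(df$geneId[duplicated(df$geneId)]), collapse = ", "),
         call. = FALSE)
  df
}

#' Write a gene expression table
#' @param expr data.frame with \code{geneId}, \code{expression}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(expr, path) {
  utils::write.table(
    data.frame(gene_id = expr$geneId, expression = expr$expression),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a machine-readable report as JSON
#'
#' @param report a named list (e.g. from \code{\link{runPipeline}}).
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
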