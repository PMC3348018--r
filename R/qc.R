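#' Statistical summary of a region's log2 ratios
#'
#' The block statistics used to judge whether a candidate CNV region is a
#' spurious signal: mean, median, max, min, sum and sample variance
#' (n - 1 denominator) of the non-missing values, plus counts. The variance
#' is \code{NA} when only one value is available.
#'
#' @param values numeric vector, possibly with \code{NA}s.
#' @return named list with elements \code{mean}, \code{median}, \code{max},
#'   \code{min}, \code{sum}, \code{variance}, \code{n}, \code{n_missing}.
#' @examples
#' regionSummary(c(1, 2, 3))
#' @export
regionSummary <- function(values) {
  nMissing <- sum(is.na(values))
  x <- values[!is.na(values)]
  if (!length(x)) stop("regionSummary: all values missing")
  list(mean = mean(x), median = median(x), max = max(x), min = min(x),
       sum = sum(x), variance = if (length(x) > 1L) var(x) else NA_real_,
       n = length(x), n_missing = nMissing)
}

#' Discard user-defined outliers
#'
#' Keeps values inside \code{[low, high]}; the operation is idempotent and
#' conserves counts (kept + removed = input length, missing values are kept
#' and not counted as removed).
#'
#' @param values numeric vector.
#' @param low,high inclusive bounds, \code{low < high} (infinite bounds
#'   allowed).
#' @return list with \code{values} (the kept vector) and \code{removed}
#'   (count of discarded values).
#' @examples
#' outlierFilter(c(-3, 0, 0.2, 4), -2, 2)
#' @export
outlierFilter <- function(values, low, high) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || is.na(low) || is.na(high))
    stop("outlier bounds must be single numbers")
  if (low >= high) stop("outlier bounds require low < high")
  keep <- is.na(values) | (values >= low & values <= high)
  list(values = values[keep], removed = sum(!keep))
}

#' Flag spurious CNV segments
#'
#' Programmatic stand-in for visual inspection of candidate regions. Each
#' segment's probe values (for its own sample, over
#' \code{first_probe..last_probe} on its chromosome) are summarized and the
#' segment is flagged \code{short}, \code{weak} and/or \code{noisy} per the
#' \code{\link{QcCriteria}}; a segment with no flags gets \code{pass}.
#' Segments are annotated, never removed; use
#' \code{\link{writeSegments}(..., dropFailed = TRUE)} to export only
#' passing segments.
#'
#' The \code{noisy} rule uses the region variance computed after the
#' optional outlier filter; \code{short} uses the segment's recorded probe
#' support and \code{weak} its recorded segmental mean.
#'
#' @param segments segment \code{GRanges} (see \code{\link{CnvSegments}}).
#' @param x the \code{\linkS4class{AcghSet}} the segments were detected in.
#' @param criteria a \code{\link{QcCriteria}} object.
#' @return the segments with \code{qc_flags} populated (comma-separated).
#' @export
qcFlagSegments <- function(segments, x, criteria = QcCriteria()) {
  stopifnot(is(x, "AcghSet"), is(criteria, "QcCriteria"))
  segments <- CnvSegments(segments)
  if (!length(segments)) return(segments)
  gr <- SummarizedExperiment::rowRanges(x)
  chromAll <- as.character(GenomicRanges::seqnames(gr))
  vals <- log2Ratios(x)
  mc <- S4Vectors::mcols(segments)
  flags <- character(length(segments))
  for (i in seq_along(segments)) {
    chrom <- as.character(GenomicRanges::seqnames(segments))[i]
    sample <- mc$sample[i]
    lab <- sprintf("%s:%d-%d/%s", chrom, GenomicRanges::start(segments)[i],
                   GenomicRanges::end(segments)[i], sample)
    if (!sample %in% colnames(vals))
      stop("cannot resolve segment ", lab, ": unknown sample")
    onChrom <- which(chromAll == chrom)
    if (mc$first_probe[i] < 1L || mc$last_probe[i] > length(onChrom))
      stop("cannot resolve segment ", lab, ": probe indices out of range")
    v <- vals[onChrom[mc$first_probe[i]:mc$last_probe[i]], sample]
    v <- v[!is.na(v)]
    if (!length(v))
      stop("cannot resolve segment ", lab, ": no non-missing probes")
    f <- character()
    if (mc$n_probes[i] < criteria@minProbes) f <- c(f, "short")
    if (abs(mc$segmental_mean[i]) < criteria@minAbsSegmentalMean)
      f <- c(f, "weak")
    vv <- v
    if (!is.na(criteria@outlierLow) && !is.na(criteria@outlierHigh))
      vv <- outlierFilter(v, criteria@outlierLow, criteria@outlierHigh)$values
    rv <- if (length(vv) > 1L) var(vv) else NA_real_
    if (!is.na(rv) && rv > criteria@maxRegionVariance) f <- c(f, "noisy")
    flags[i] <- if (length(f)) paste(f, collapse = ",") else "pass"
  }
  S4Vectors::mcols(segments)$qc_flags <- flags
  segments
}
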