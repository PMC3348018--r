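#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' AcghSet: probe-level aCGH log2-ratio data
#'
#' An \code{AcghSet} holds an ordered set of array-CGH probes together with a
#' probes x samples matrix of log2 intensity ratios. It extends
#' \linkS4class{RangedSummarizedExperiment}: probes live in
#' \code{rowRanges()} (a \code{GRanges} with metadata columns
#' \code{probe_id} and \code{probe_name}), the log2 ratios in the
#' \code{"log2ratio"} assay, and an optional probe-to-gene map in
#' \code{metadata()}. Probes are kept in canonical order: chromosomes in
#' natural order, then start, end, probe id.
#'
#' @seealso \code{\link{readAcgh}}, \code{\link{detectCnv}},
#'   \code{\link{simulateAcgh}}
#' @export
setClass("AcghSet", contains = "RangedSummarizedExperiment")

setValidity("AcghSet", function(object) {
  msg <- character()
  if (!"log2ratio" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2ratio' is required")
  mc <- names(S4Vectors::mcols(SummarizedExperiment::rowRanges(object)))
  if (!all(c("probe_id", "probe_name") %in% mc))
    msg <- c(msg, "rowRanges() needs metadata columns 'probe_id' and 'probe_name'")
  cn <- colnames(object)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample names must be present and unique")
  gr <- SummarizedExperiment::rowRanges(object)
  if (length(gr)) {
    if (any(GenomicRanges::start(gr) < 1L))
      msg <- c(msg, "probe start must be >= 1")
    if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
      msg <- c(msg, "probe end must be >= start")
    ord <- acghProbeOrder(gr)
    if (!identical(ord, seq_along(gr)))
      msg <- c(msg, "probes must be in canonical (chromosome, start, end, probe_id) order")
  }
  if (length(msg)) msg else TRUE
})

## Canonical probe order used everywhere: chromosome (natural order of the
## seqlevels), start, end, probe_id.
acghProbeOrder <- function(gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  lev <- chromLevels(chrom)
  order(match(chrom, lev), GenomicRanges::start(gr), GenomicRanges::end(gr),
        S4Vectors::mcols(gr)$probe_id)
}

#' Construct an AcghSet
#'
#' @param probes \code{GRanges} with metadata columns \code{probe_id} and
#'   \code{probe_name}, one range per probe (1-based inclusive coordinates).
#' @param log2ratio numeric matrix, probes x samples; \code{NA} marks a
#'   missing measurement.
#' @param sampleNames character vector of unique sample names; defaults to
#'   the matrix column names.
#' @param geneMap optional named character vector mapping probe ids to gene
#'   names.
#' @return A validated \code{\linkS4class{AcghSet}} with probes in canonical
#'   order.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 60),
#'                              probe_id = c("p1", "p2"), probe_name = c("p1n", "p2n"))
#' AcghSet(gr, matrix(c(0.1, -0.8), ncol = 1, dimnames = list(NULL, "s1")))
#' @export
AcghSet <- function(probes, log2ratio, sampleNames = colnames(log2ratio),
                    geneMap = NULL) {
  log2ratio <- as.matrix(log2ratio)
  storage.mode(log2ratio) <- "double"
  if (length(probes) != nrow(log2ratio))
    stop("nrow(log2ratio) must equal length(probes)")
  if (is.null(sampleNames))
    sampleNames <- paste0("sample_", seq_len(ncol(log2ratio)))
  colnames(log2ratio) <- sampleNames
  ord <- acghProbeOrder(probes)
  probes <- probes[ord]
  log2ratio <- log2ratio[ord, , drop = FALSE]
  GenomeInfoDb::seqlevels(probes) <-
    chromLevels(as.character(GenomicRanges::seqnames(probes)))
  obj <- new("AcghSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = log2ratio),
    rowRanges = probes,
    colData = S4Vectors::DataFrame(row.names = sampleNames)))
  if (!is.null(geneMap)) geneMap(obj) <- geneMap
  validObject(obj)
  obj
}

#' @rdname AcghSet
#' @param x,object an \code{AcghSet}.
#' @export
log2Ratios <- function(x) SummarizedExperiment::assay(x, "log2ratio")

#' @rdname AcghSet
#' @export
probeIds <- function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$probe_id

#' @rdname AcghSet
#' @export
geneMap <- function(x) S4Vectors::metadata(x)$geneMap

#' @rdname AcghSet
#' @param value named character vector (names are probe ids).
#' @export
`geneMap<-` <- function(x, value) {
  if (!is.null(value) && (is.null(names(value)) || !is.character(value)))
    stop("geneMap must be a named character vector")
  S4Vectors::metadata(x)$geneMap <- value
  x
}

#' CNV detection parameters
#'
#' Parameters of the maximum-scoring-island segmentation.
#'
#' @slot madMultiplier positive multiplier \code{k} of the per-chromosome
#'   median absolute deviation; the detection threshold is
#'   \code{median +/- k * MAD}.
#' @slot minIslandProbes minimum island block length, in probes; islands
#'   supported by fewer probes are dropped.
#' @slot direction \code{"gain"}, \code{"loss"} or \code{"both"}.
#' @slot absThreshold optional absolute threshold (log2 units) replacing
#'   \code{k * MAD}; required to segment data whose MAD is zero.
#' @slot minSpanBp optional minimum genomic span (bp) of an island;
#'   0 disables the filter.
#' @export
setClass("CnvParams", representation(
  madMultiplier = "numeric",
  minIslandProbes = "integer",
  direction = "character",
  absThreshold = "numeric",
  minSpanBp = "numeric"))

setValidity("CnvParams", function(object) {
  msg <- character()
  if (length(object@madMultiplier) != 1L || is.na(object@madMultiplier) ||
      object@madMultiplier <= 0)
    msg <- c(msg, "madMultiplier must be a single positive number")
  if (length(object@minIslandProbes) != 1L || is.na(object@minIslandProbes) ||
      object@minIslandProbes < 1L)
    msg <- c(msg, "minIslandProbes must be a single integer >= 1")
  if (!object@direction %in% c("gain", "loss", "both"))
    msg <- c(msg, "direction must be 'gain', 'loss' or 'both'")
  if (length(object@absThreshold) != 1L ||
      (!is.na(object@absThreshold) && object@absThreshold <= 0))
    msg <- c(msg, "absThreshold must be NA or a single positive number")
  if (length(object@minSpanBp) != 1L || is.na(object@minSpanBp) ||
      object@minSpanBp < 0)
    msg <- c(msg, "minSpanBp must be a single number >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname CnvParams-class
#' @param madMultiplier,minIslandProbes,direction,absThreshold,minSpanBp see
#'   slots.
#' @return a validated \code{CnvParams} object.
#' @examples
#' CnvParams(madMultiplier = 3, minIslandProbes = 5)
#' @export
CnvParams <- function(madMultiplier = 3, minIslandProbes = 5L,
                      direction = c("both", "gain", "loss"),
                      absThreshold = NA_real_, minSpanBp = 0) {
  direction <- match.arg(direction)
  obj <- new("CnvParams", madMultiplier = as.numeric(madMultiplier),
             minIslandProbes = as.integer(minIslandProbes),
             direction = direction, absThreshold = as.numeric(absThreshold),
             minSpanBp = as.numeric(minSpanBp))
  validObject(obj)
  obj
}

setMethod("show", "CnvParams", function(object) {
  cat("CnvParams: k =", object@madMultiplier,
      "| min island probes =", object@minIslandProbes,
      "| direction =", object@direction)
  if (!is.na(object@absThreshold))
    cat(" | absolute threshold =", object@absThreshold)
  if (object@minSpanBp > 0)
    cat(" | min span =", object@minSpanBp, "bp")
  cat("\n")
})

#' Segment quality-control criteria
#'
#' Thresholds for the programmatic spurious-signal filter. Segments are
#' flagged, never removed: \code{short} when supported by fewer than
#' \code{minProbes} probes, \code{weak} when the absolute segmental mean is
#' below \code{minAbsSegmentalMean}, \code{noisy} when the region variance
#' (after the optional outlier filter) exceeds \code{maxRegionVariance}, and
#' \code{pass} when none of the three fire.
#'
#' @slot minProbes integer, minimum probe support.
#' @slot minAbsSegmentalMean log2 units.
#' @slot maxRegionVariance sample variance ceiling.
#' @slot outlierLow,outlierHigh optional log2 cutoffs applied before the
#'   variance check; values outside \code{[outlierLow, outlierHigh]} are
#'   discarded as outliers.
#' @export
setClass("QcCriteria", representation(
  minProbes = "integer",
  minAbsSegmentalMean = "numeric",
  maxRegionVariance = "numeric",
  outlierLow = "numeric",
  outlierHigh = "numeric"))

setValidity("QcCriteria", function(object) {
  msg <- character()
  if (object@minProbes < 1L) msg <- c(msg, "minProbes must be >= 1")
  if (object@minAbsSegmentalMean < 0)
    msg <- c(msg, "minAbsSegmentalMean must be >= 0")
  if (object@maxRegionVariance < 0)
    msg <- c(msg, "maxRegionVariance must be >= 0")
  if (!is.na(object@outlierLow) && !is.na(object@outlierHigh) &&
      object@outlierLow >= object@outlierHigh)
    msg <- c(msg, "outlierLow must be < outlierHigh")
  if (length(msg)) msg else TRUE
})

#' @rdname QcCriteria-class
#' @param minProbes,minAbsSegmentalMean,maxRegionVariance,outlierLow,outlierHigh
#'   see slots.
#' @return a validated \code{QcCriteria} object.
#' @examples
#' QcCriteria()
#' @export
QcCriteria <- function(minProbes = 5L, minAbsSegmentalMean = 0.3,
                       maxRegionVariance = 0.25, outlierLow = NA_real_,
                       outlierHigh = NA_real_) {
  obj <- new("QcCriteria", minProbes = as.integer(minProbes),
             minAbsSegmentalMean = as.numeric(minAbsSegmentalMean),
             maxRegionVariance = as.numeric(maxRegionVariance),
             outlierLow = as.numeric(outlierLow),
             outlierHigh = as.numeric(outlierHigh))
  validObject(obj)
  obj
}

setMethod("show", "QcCriteria", function(object) {
  cat("QcCriteria: min probes =", object@minProbes,
      "| min |segmental mean| =", object@minAbsSegmentalMean,
      "| max variance =", object@maxRegionVariance, "\n")
  if (!is.na(object@outlierLow) || !is.na(object@outlierHigh))
    cat("  outlier filter: [", object@outlierLow, ",", object@outlierHigh, "]\n")
})

#' Alignment filtering parameters for pileup
#'
#' @slot minMapq minimum mapping quality of a read.
#' @slot minBaseq minimum base quality (Phred) for an aligned base to be
#'   counted; deletions carry no base quality and are never filtered by it.
#' @slot exclude alignment-record categories removed before counting; any
#'   subset of \code{"unmapped"}, \code{"secondary"}, \code{"duplicate"},
#'   \code{"qc_fail"}.
#' @export
setClass("DepthParams", representation(
  minMapq = "integer", minBaseq = "integer", exclude = "character"))

setValidity("DepthParams", function(object) {
  msg <- character()
  if (object@minMapq < 0L || object@minBaseq < 0L)
    msg <- c(msg, "minMapq and minBaseq must be >= 0")
  bad <- setdiff(object@exclude,
                 c("unmapped", "secondary", "duplicate", "qc_fail"))
  if (length(bad))
    msg <- c(msg, paste0("unknown exclude categories: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname DepthParams-class
#' @param minMapq,minBaseq,exclude see slots.
#' @return a validated \code{DepthParams} object.
#' @examples
#' DepthParams(minMapq = 20)
#' @export
DepthParams <- function(minMapq = 0L, minBaseq = 0L,
                        exclude = c("unmapped", "secondary", "duplicate",
                                    "qc_fail")) {
  obj <- new("DepthParams", minMapq = as.integer(minMapq),
             minBaseq = as.integer(minBaseq),
             exclude = as.character(exclude))
  validObject(obj)
  obj
}

setMethod("show", "DepthParams", function(object) {
  cat("DepthParams: min MAPQ =", object@minMapq,
      "| min base quality =", object@minBaseq,
      "| exclude:", paste(object@exclude, collapse = ","), "\n")
})
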