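#' Unscaled median absolute deviation
#'
#' Robust dispersion used to set the segmentation threshold:
#' \code{median(|x - median(x)|)}, with no 1.4826 Gaussian consistency
#' factor. The median of an even-length vector is the mean of the two
#' central order statistics.
#'
#' @param x numeric vector; missing values must be removed by the caller.
#' @return a single non-negative number.
#' @examples
#' madUnscaled(c(1, 1, 2, 2, 4)) # 1
#' @export
madUnscaled <- function(x) {
  if (!length(x)) stop("cannot compute MAD of an empty vector")
  if (anyNA(x)) stop("remove missing values before computing MAD")
  stats::mad(x, constant = 1)
}

#' Maximum-scoring islands of a score vector
#'
#' The one-dimensional Smith-Waterman reduction underlying the
#' segmentation: the cumulative score \eqn{S_i = \max(0, S_{i-1} + s_i)}
#' (with \eqn{S_0 = 0}) is computed along the probe order, and each maximal
#' run of indices with \eqn{S_i > 0} yields one island, spanning from the
#' run's first index to the first index attaining the run's maximum
#' \eqn{S}, with the island score equal to that maximum. Islands are
#' disjoint and reported left to right; ties in the maximum are broken
#' leftmost. The remainder of a run after its maximum is not re-mined.
#'
#' @param scores numeric vector of finite scores.
#' @return \code{data.frame} with columns \code{start}, \code{end} (1-based
#'   indices into \code{scores}) and \code{score}; zero rows when no
#'   positive-scoring run exists.
#' @examples
#' swIslands(c(0.5, -0.2, 0.8, -1.0, 0.3)) # one island, indices 1..3, score 1.1
#' @export
swIslands <- function(scores) {
  scores <- as.numeric(scores)
  empty <- data.frame(start = integer(), end = integer(), score = numeric())
  if (!length(scores)) return(empty)
  if (any(!is.finite(scores))) stop("scores must be finite")
  ## S_i = P_i - min(0, P_1, ..., P_i), the closed form of the clamped
  ## recurrence S_i = max(0, S_{i-1} + s_i).
  P <- cumsum(scores)
  S <- P - pmin(cummin(P), 0)
  pos <- S > 0
  if (!any(pos)) return(empty)
  r <- rle(pos)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  keep <- r$values
  runStart <- runStart[keep]
  runEnd <- runEnd[keep]
  out <- lapply(seq_along(runStart), function(i) {
    idx <- runStart[i]:runEnd[i]
    peak <- idx[which.max(S[idx])]      # which.max: first maximum
    c(runStart[i], peak, S[peak])
  })
  out <- do.call(rbind, out)
  data.frame(start = as.integer(out[, 1L]), end = as.integer(out[, 2L]),
             score = out[, 3L])
}

## Single-direction detection on a numeric profile already restricted to one
## sample x chromosome, with missing probes excised. `probeIdx` maps the
## compacted positions back to the chromosome's full probe order.
.detectDirection <- function(x, probeIdx, probes, sample, chrom, type,
                             threshold, params) {
  scores <- if (type == "gain") x - threshold else threshold - x
  isl <- swIslands(scores)
  if (!nrow(isl)) return(NULL)
  nProbes <- isl$end - isl$start + 1L
  keep <- nProbes >= params@minIslandProbes
  isl <- isl[keep, , drop = FALSE]
  nProbes <- nProbes[keep]
  if (!nrow(isl)) return(NULL)
  firstIdx <- probeIdx[isl$start]
  lastIdx <- probeIdx[isl$end]
  startBp <- GenomicRanges::start(probes)[firstIdx]
  endBp <- GenomicRanges::end(probes)[lastIdx]
  if (params@minSpanBp > 0) {
    keep <- (endBp - startBp + 1L) >= params@minSpanBp
    isl <- isl[keep, , drop = FALSE]
    if (!nrow(isl)) return(NULL)
    nProbes <- nProbes[keep]
    firstIdx <- firstIdx[keep]; lastIdx <- lastIdx[keep]
    startBp <- startBp[keep]; endBp <- endBp[keep]
  }
  segMean <- vapply(seq_len(nrow(isl)), function(i)
    mean(x[isl$start[i]:isl$end[i]]), numeric(1L))
  data.frame(
    chrom = chrom, start = startBp, end = endBp,
    sample = sample, type = type, n_probes = nProbes,
    first_probe = firstIdx, last_probe = lastIdx,
    sw_score = isl$score, segmental_mean = segMean)
}

#' Detect CNV segments on one sample and chromosome
#'
#' Detection runs on the sample's non-missing log2 ratios along the
#' chromosome's probe order. With \code{m} the median and \code{d} the
#' unscaled MAD of those values, the gain pass scores each probe
#' \code{x - (m + k d)} and the loss pass \code{(m - k d) - x}
#' (\code{k = madMultiplier}); each pass extracts maximum-scoring islands
#' (\code{\link{swIslands}}) and drops islands supported by fewer than
#' \code{minIslandProbes} probes. Raising \code{k} or the island block
#' length makes detection stricter. When the MAD is zero the threshold is
#' degenerate and an error is raised unless \code{absThreshold} supplies an
#' absolute offset to use in place of \code{k d}.
#'
#' @param x an \code{\linkS4class{AcghSet}}.
#' @param sample sample name (must be a column of \code{x}).
#' @param chrom chromosome label (verbatim match against probe chromosomes).
#' @param params a \code{\link{CnvParams}} object.
#' @return segment \code{GRanges} (see \code{\link{CnvSegments}});
#'   \code{first_probe}/\code{last_probe} index the chromosome's full probe
#'   order, while \code{n_probes} counts the non-missing probes supporting
#'   the island.
#' @seealso \code{\link{detectAll}}, \code{\link{qcFlagSegments}}
#' @export
detectCnv <- function(x, sample, chrom, params = CnvParams()) {
  stopifnot(is(x, "AcghSet"), is(params, "CnvParams"))
  if (!sample %in% colnames(x))
    stop("unknown sample: ", sample)
  gr <- SummarizedExperiment::rowRanges(x)
  onChrom <- which(as.character(GenomicRanges::seqnames(gr)) == chrom)
  if (!length(onChrom)) stop("no probes on chromosome ", chrom)
  probes <- gr[onChrom]
  vals <- log2Ratios(x)[onChrom, sample]
  keep <- !is.na(vals)
  if (sum(keep) < 2L)
    stop("need >= 2 non-missing probes on ", chrom, " for sample ", sample)
  xs <- vals[keep]
  probeIdx <- which(keep)
  m <- median(xs)
  d <- madUnscaled(xs)
  offset <- if (d > 0) params@madMultiplier * d else params@absThreshold
  if (is.na(offset) || offset <= 0)
    stop("degenerate dispersion: MAD is 0 on ", chrom, " for sample ",
         sample, " (set absThreshold to segment anyway)")
  dirs <- if (params@direction == "both") c("gain", "loss") else params@direction
  out <- lapply(dirs, function(type) {
    threshold <- if (type == "gain") m + offset else m - offset
    .detectDirection(xs, probeIdx, probes, sample, chrom, type, threshold,
                     params)
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(emptySegments())
  df <- do.call(rbind, out)
  CnvSegments(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    sample = df$sample, type = df$type, n_probes = df$n_probes,
    first_probe = df$first_probe, last_probe = df$last_probe,
    sw_score = df$sw_score, segmental_mean = df$segmental_mean,
    qc_flags = rep("", nrow(df)),
    known_status = rep(NA_character_, nrow(df))))
}

emptySegments <- function() {
  CnvSegments(GenomicRanges::GRanges(
    sample = character(), type = character(), n_probes = integer(),
    first_probe = integer(), last_probe = integer(), sw_score = numeric(),
    segmental_mean = numeric(), qc_flags = character(),
    known_status = character()))
}

#' Detect CNV segments across all samples and chromosomes
#'
#' Applies \code{\link{detectCnv}} to every sample x chromosome pair of the
#' dataset. Per-pair degenerate-dispersion (or too-few-probe) errors are
#' collected rather than fatal: they are recorded in
#' \code{metadata(result)$issues} and raised as a single warning.
#'
#' @inheritParams detectCnv
#' @param scope \code{"chromosome"} (default) estimates median and MAD per
#'   chromosome; \code{"genome"} estimates them once per sample from all its
#'   non-missing values and applies the same threshold to every chromosome.
#' @return segment \code{GRanges} sorted by (chromosome, start, sample),
#'   with a \code{data.frame} of skipped pairs in
#'   \code{S4Vectors::metadata()$issues}.
#' @export
detectAll <- function(x, params = CnvParams(),
                      scope = c("chromosome", "genome")) {
  scope <- match.arg(scope)
  stopifnot(is(x, "AcghSet"))
  chroms <- GenomeInfoDb::seqlevels(SummarizedExperiment::rowRanges(x))
  issues <- list()
  segs <- list()
  for (sample in colnames(x)) {
    p <- params
    if (scope == "genome") {
      allVals <- log2Ratios(x)[, sample]
      allVals <- allVals[!is.na(allVals)]
      d <- if (length(allVals)) madUnscaled(allVals) else 0
      if (d > 0 && is.na(params@absThreshold)) {
        ## freeze the genome-wide k*MAD as an absolute offset; the
        ## per-chromosome median still centers the threshold
        p <- CnvParams(params@madMultiplier, params@minIslandProbes,
                       params@direction,
                       absThreshold = params@madMultiplier * d,
                       minSpanBp = params@minSpanBp)
      }
    }
    for (chrom in chroms) {
      res <- tryCatch(detectCnv(x, sample, chrom, p), error = function(e) e)
      if (is(res, "error")) {
        issues[[length(issues) + 1L]] <-
          data.frame(sample = sample, chrom = chrom,
                     message = conditionMessage(res))
      } else if (length(res)) {
        segs[[length(segs) + 1L]] <- res
      }
    }
  }
  out <- if (length(segs) == 1L) segs[[1L]]
         else if (length(segs))
           CnvSegments(suppressWarnings(do.call(c, unname(segs))))
         else emptySegments()
  issues <- if (length(issues)) do.call(rbind, issues)
            else data.frame(sample = character(), chrom = character(),
                            message = character())
  S4Vectors::metadata(out)$issues <- issues
  if (nrow(issues))
    warning(nrow(issues), " sample/chromosome pair(s) skipped during detection")
  out
}

#' Rasterize segments onto fixed genomic bins
#'
#' The per-sample segment-by-bin matrix behind a multi-sample heat-map
#' style comparison: the chromosome is cut into consecutive bins of
#' \code{binSize} bp and a bin takes a sample's segment type when segments
#' of that type cover at least half of the bin. A bin where both gain and
#' loss reach the coverage rule is marked \code{"conflict"}; otherwise it is
#' \code{"neutral"}.
#'
#' @param segments segment \code{GRanges}.
#' @param chrom chromosome to rasterize.
#' @param binSize bin width in bp (>= 1).
#' @param samples samples to include as rows; defaults to all samples with
#'   segments plus any in \code{allSamples}.
#' @param allSamples optional character vector forcing row order/presence
#'   (samples without segments get all-neutral rows).
#' @param extent optional end coordinate; defaults to the last segment end
#'   on the chromosome.
#' @return list with \code{matrix} (character, samples x bins) and
#'   \code{bins} (\code{GRanges} of bin coordinates).
#' @export
segmentMatrix <- function(segments, chrom, binSize, samples = NULL,
                          allSamples = NULL, extent = NULL) {
  stopifnot(binSize >= 1)
  segments <- segments[as.character(GenomicRanges::seqnames(segments)) == chrom]
  if (is.null(samples))
    samples <- unique(c(allSamples,
                        sort(unique(S4Vectors::mcols(segments)$sample))))
  if (is.null(extent))
    extent <- if (length(segments)) max(GenomicRanges::end(segments)) else binSize
  nBins <- ceiling(extent / binSize)
  binStart <- (seq_len(nBins) - 1L) * binSize + 1L
  ## bins keep their full width (the coverage rule's denominator), even
  ## when the last one extends past the data extent
  bins <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(binStart, binStart + binSize - 1L))
  mat <- matrix("neutral", length(samples), nBins,
                dimnames = list(samples, NULL))
  if (!length(segments) || !length(samples))
    return(list(matrix = mat, bins = bins))
  for (s in samples) {
    sub <- segments[S4Vectors::mcols(segments)$sample == s]
    for (type in c("gain", "loss")) {
      tsub <- sub[S4Vectors::mcols(sub)$type == type]
      if (!length(tsub)) next
      cov <- GenomicRanges::coverage(GenomicRanges::reduce(tsub))[[chrom]]
      covBin <- vapply(seq_len(nBins), function(b) {
        lo <- GenomicRanges::start(bins)[b]; hi <- GenomicRanges::end(bins)[b]
        if (lo > length(cov)) return(0)
        v <- S4Vectors::runValue(S4Vectors::window(cov, lo, min(hi, length(cov))))
        l <- S4Vectors::runLength(S4Vectors::window(cov, lo, min(hi, length(cov))))
        sum(l[v > 0])
      }, numeric(1L))
      hit <- covBin >= 0.5 * GenomicRanges::width(bins)
      prev <- mat[s, ]
      mat[s, hit] <- ifelse(prev[hit] == "neutral", type,
                            ifelse(prev[hit] == type, type, "conflict"))
    }
  }
  list(matrix = mat, bins = bins)
}

#' Write a segment-by-bin matrix to TSV
#'
#' @param sm list returned by \code{\link{segmentMatrix}}.
#' @param file output path; written atomically.
#' @return the file path, invisibly.
#' @export
writeSegmentMatrix <- function(sm, file) {
  header <- paste(c("sample",
                    paste0(as.character(GenomicRanges::seqnames(sm$bins)), ":",
                           GenomicRanges::start(sm$bins), "-",
                           GenomicRanges::end(sm$bins))), collapse = "\t")
  rows <- vapply(rownames(sm$matrix), function(s)
    paste(c(s, sm$matrix[s, ]), collapse = "\t"), character(1L))
  atomicWrite(c(header, rows), file)
}
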