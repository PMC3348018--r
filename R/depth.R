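## Accept a SAM or BAM path and return an indexed BAM path. SAM input is
## converted (sorted + indexed) into a temporary file; BAM input is indexed
## in place when no index is present.
ensureBam <- function(file) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    return(Rsamtools::asBam(file, dest, overwrite = TRUE,
                            indexDestination = TRUE))
  }
  bai <- paste0(file, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", file)))
    Rsamtools::indexBam(file)
  file
}

## Reference bases over a 1-based inclusive window, from a FASTA path or a
## DNAStringSet. FASTA names are matched on their first word.
refWindow <- function(ref, chrom, start, end) {
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  names(ref) <- sub("\\s.*", "", names(ref))
  if (!chrom %in% names(ref))
    stop("reference has no sequence named ", chrom)
  if (end > Biostrings::width(ref[chrom]))
    stop("reference sequence ", chrom, " is shorter than the queried region")
  strsplit(as.character(Biostrings::subseq(ref[[chrom]], start, end)),
           "")[[1L]]
}

.ambiguityCodes <- c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B")

#' Per-locus read depth and nucleotide counts from alignments
#'
#' Builds one pileup column per reference position in \code{[start, end]}:
#' reads overlapping the window are stacked along the reference (CIGAR
#' aware), and each read contributes at most one count per column -- its
#' aligned base under \code{A/C/G/T/N} (IUPAC ambiguity codes are pooled
#' into \code{N}) or \code{DEL} for a deletion (CIGAR \code{D}) spanning
#' the position. Insertions do not consume reference positions and create
#' no columns; reference skips (CIGAR \code{N}) and soft clips contribute
#' nothing. Depth is the sum of the six counts. Reads excluded by
#' \code{\link{DepthParams}} (flag categories, mapping quality) are removed
#' before counting, and aligned bases below \code{minBaseq} are dropped
#' individually (deletions carry no quality and are kept).
#'
#' @param bam path to a BAM file (or SAM, converted on the fly).
#' @param chrom reference sequence name; must be in the BAM header.
#' @param start,end 1-based inclusive window, \code{start <= end}.
#' @param params a \code{\link{DepthParams}} object.
#' @param ref optional FASTA path or \code{DNAStringSet}; fills the
#'   \code{ref} column.
#' @return \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{depth}, \code{A}, \code{C}, \code{G}, \code{T},
#'   \code{N}, \code{DEL}; positions with no covering read have depth 0.
#' @seealso \code{\link{callSnps}}, \code{\link{depthDeletionScan}}
#' @export
pileupColumns <- function(bam, chrom, start, end, params = DepthParams(),
                          ref = NULL) {
  stopifnot(start >= 1, start <= end, is(params, "DepthParams"))
  bam <- ensureBam(bam)
  bf <- Rsamtools::BamFile(bam)
  targets <- Rsamtools::scanBamHeader(bf)$targets
  if (!chrom %in% names(targets))
    stop("BAM header has no reference sequence named ", chrom)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = if ("unmapped" %in% params@exclude) FALSE else NA,
    isSecondaryAlignment = if ("secondary" %in% params@exclude) FALSE else NA,
    isDuplicate = if ("duplicate" %in% params@exclude) FALSE else NA,
    isNotPassingQualityControls =
      if ("qc_fail" %in% params@exclude) FALSE else NA)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  sbp <- Rsamtools::ScanBamParam(which = which, flag = flag,
                                 mapqFilter = params@minMapq)
  width <- end - start + 1L
  stack <- GenomicAlignments::stackStringsFromBam(
    bf, param = sbp, what = "seq", D.letter = "-", N.letter = ".")
  letters <- c("A", "C", "G", "T", "N", "DEL")
  counts <- matrix(0L, width, 6L, dimnames = list(NULL, letters))
  if (length(stack)) {
    if (params@minBaseq > 0L) {
      quals <- GenomicAlignments::stackStringsFromBam(
        bf, param = sbp, what = "qual", D.letter = "-", N.letter = ".")
      sm <- as.matrix(stack)
      qm <- t(vapply(as.character(quals), function(q)
        as.integer(charToRaw(q)) - 33L, integer(width), USE.NAMES = FALSE))
      drop <- qm < params@minBaseq & sm != "-" & sm != "+" & sm != "."
      sm[drop] <- "+"
      for (b in c("A", "C", "G", "T", "N"))
        counts[, b] <- colSums(sm == b)
      counts[, "DEL"] <- colSums(sm == "-")
      for (b in .ambiguityCodes)
        counts[, "N"] <- counts[, "N"] + colSums(sm == b)
    } else {
      cm <- Biostrings::consensusMatrix(stack)
      pick <- function(b) if (b %in% rownames(cm)) cm[b, ] else rep(0L, width)
      for (b in c("A", "C", "G", "T", "N")) counts[, b] <- pick(b)
      counts[, "DEL"] <- pick("-")
      for (b in .ambiguityCodes)
        counts[, "N"] <- counts[, "N"] + pick(b)
    }
  }
  refBase <- if (is.null(ref)) rep(NA_character_, width)
             else refWindow(ref, chrom, start, end)
  data.frame(chrom = chrom, pos = seq.int(start, end), ref = refBase,
             depth = as.integer(rowSums(counts)),
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
             T = counts[, "T"], N = counts[, "N"], DEL = counts[, "DEL"])
}

#' Allele frequencies at one pileup column
#'
#' @param column a single-row slice of the \code{\link{pileupColumns}}
#'   output (or any list with the six count fields and \code{depth}).
#' @return named numeric vector of base frequencies (only observed bases),
#'   summing to 1.
#' @examples
#' cols <- data.frame(chrom = "ref", pos = 1, ref = NA, depth = 3L,
#'                    A = 2L, C = 0L, G = 1L, T = 0L, N = 0L, DEL = 0L)
#' alleleFrequency(cols[1, ])
#' @export
alleleFrequency <- function(column) {
  depth <- column$depth
  if (is.null(depth) || length(depth) != 1L)
    stop("alleleFrequency expects a single pileup column")
  if (depth < 1L) stop("cannot compute allele frequencies at depth 0")
  counts <- unlist(column[c("A", "C", "G", "T", "N", "DEL")])
  counts[counts > 0] / depth
}

#' Frequency-threshold SNP calling
#'
#' A deliberately simple caller: at each column with \code{depth >=
#' minDepth}, the most frequent non-reference substitution base (among
#' \code{A/C/G/T}; \code{N} and \code{DEL} never produce calls, though both
#' count toward depth) is emitted when its fraction of the column depth is
#' at least \code{minAltFraction}. At most one call per position; ties
#' between alternate bases are broken by count, then alphabetically. This
#' is an allele-frequency rule, not a genotype-likelihood model.
#'
#' @param columns output of \code{\link{pileupColumns}}; the \code{ref}
#'   column must be filled (pass a reference to \code{pileupColumns}).
#' @param minDepth minimum column depth (default 5).
#' @param minAltFraction minimum alternate allele fraction (default 0.2).
#' @param sample sample label recorded with each call.
#' @return \code{data.frame} with columns \code{sample}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{depth}, \code{alt_fraction}.
#' @export
callSnps <- function(columns, minDepth = 5L, minAltFraction = 0.2,
                     sample = "sample") {
  if (anyNA(columns$ref))
    stop("reference bases required: run pileupColumns() with 'ref'")
  empty <- data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      depth = integer(), alt_fraction = numeric())
  calls <- empty
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(columns))) {
    depth <- columns$depth[i]
    if (depth < minDepth) next
    refb <- toupper(columns$ref[i])
    alt <- setdiff(bases, refb)
    cnt <- unlist(columns[i, alt])
    if (!any(cnt > 0)) next
    best <- alt[order(-cnt, alt)][1L]
    frac <- columns[[best]][i] / depth
    if (frac >= minAltFraction)
      calls <- rbind(calls, data.frame(
        sample = sample, chrom = columns$chrom[i], pos = columns$pos[i],
        ref = refb, alt = best, depth = depth, alt_fraction = frac))
  }
  calls
}

#' Scan pileup depth for deletion candidates
#'
#' Reports maximal runs of at least \code{minSpan} consecutive positions
#' whose depth does not exceed \code{depthFloor}. By default the scan uses
#' the sequenced-base depth (\code{depth - DEL}): reads bridging a
#' homozygous deletion align with a \code{D} CIGAR across it, so their
#' deletion marks would otherwise keep the total depth high inside the
#' deleted interval. Set \code{depthType = "total"} to scan raw depth.
#'
#' @param columns contiguous output of \code{\link{pileupColumns}}.
#' @param depthFloor depth ceiling defining "low" (default 0).
#' @param minSpan minimum run length in bp.
#' @param depthType \code{"base"} (default) or \code{"total"}.
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{mean_depth}; intervals are disjoint and each spans
#'   >= \code{minSpan} bp.
#' @export
depthDeletionScan <- function(columns, depthFloor = 0L, minSpan,
                              depthType = c("base", "total")) {
  depthType <- match.arg(depthType)
  stopifnot(minSpan >= 1)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_depth = numeric())
  if (!nrow(columns)) return(empty)
  if (any(diff(columns$pos) != 1L))
    stop("pileup columns must be contiguous")
  d <- if (depthType == "base") columns$depth - columns$DEL else columns$depth
  low <- d <= depthFloor
  r <- rle(low)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  keep <- r$values & r$lengths >= minSpan
  if (!any(keep)) return(empty)
  startIdx <- startIdx[keep]; endIdx <- endIdx[keep]
  data.frame(
    chrom = columns$chrom[startIdx],
    start = columns$pos[startIdx], end = columns$pos[endIdx],
    mean_depth = vapply(seq_along(startIdx), function(i)
      mean(d[startIdx[i]:endIdx[i]]), numeric(1L)))
}

#' SNP differences between two samples
#'
#' A site differs when it is called in exactly one sample, or in both with
#' different alternate alleles. Candidate CNV regions are maximal runs of
#' at least \code{windowSnps} consecutive differing sites, where
#' "consecutive" means adjacent in the merged, position-sorted list of all
#' sites called in either sample (a site called identically in both breaks
#' a run). \code{maxGapBp} optionally also breaks runs at large genomic
#' gaps between neighboring differing sites.
#'
#' @param callsA,callsB call tables from \code{\link{callSnps}} on the same
#'   reference coordinates.
#' @param windowSnps minimum number of consecutive differing sites for a
#'   candidate region.
#' @param maxGapBp optional maximum bp distance between neighboring
#'   differing sites within one region (\code{Inf} disables).
#' @return list with \code{site_differences} (\code{data.frame}:
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt_a}, \code{alt_b},
#'   \code{status} in \code{only_a}/\code{only_b}/\code{allele_mismatch})
#'   and \code{candidate_regions} (\code{data.frame}: \code{chrom},
#'   \code{start}, \code{end}, \code{n_sites}).
#' @export
compareSamples <- function(callsA, callsB, windowSnps = 3L, maxGapBp = Inf) {
  keyA <- paste(callsA$chrom, callsA$pos)
  keyB <- paste(callsB$chrom, callsB$pos)
  allKey <- union(keyA, keyB)
  chrom <- sub(" .*", "", allKey)
  pos <- as.integer(sub(".* ", "", allKey))
  altA <- callsA$alt[match(allKey, keyA)]
  altB <- callsB$alt[match(allKey, keyB)]
  refAll <- ifelse(is.na(match(allKey, keyA)),
                   callsB$ref[match(allKey, keyB)],
                   callsA$ref[match(allKey, keyA)])
  status <- ifelse(is.na(altB), "only_a",
            ifelse(is.na(altA), "only_b",
            ifelse(altA != altB, "allele_mismatch", "same")))
  ord <- order(match(chrom, chromLevels(chrom)), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; altA <- altA[ord]; altB <- altB[ord]
  refAll <- refAll[ord]; status <- status[ord]
  differing <- status != "same"
  siteDiff <- data.frame(chrom = chrom, pos = pos, ref = refAll,
                         alt_a = altA, alt_b = altB,
                         status = status)[differing, , drop = FALSE]
  rownames(siteDiff) <- NULL

  regions <- data.frame(chrom = character(), start = integer(),
                        end = integer(), n_sites = integer())
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos[sel]; diffCh <- differing[sel]
    ## break runs at non-differing sites, and optionally at large gaps
    grp <- cumsum(!diffCh)
    if (is.finite(maxGapBp)) {
      gapBreak <- c(FALSE, diff(p) > maxGapBp)
      grp <- grp + cumsum(gapBreak)
    }
    for (g in unique(grp[diffCh])) {
      idx <- which(diffCh & grp == g)
      if (length(idx) >= windowSnps)
        regions <- rbind(regions, data.frame(
          chrom = ch, start = p[idx[1L]], end = p[idx[length(idx)]],
          n_sites = length(idx)))
    }
  }
  list(site_differences = siteDiff, candidate_regions = regions)
}

#' Write a pileup table to TSV
#' @param columns output of \code{\link{pileupColumns}}.
#' @param file output path; written atomically.
#' @return the file path, invisibly.
#' @export
writePileup <- function(columns, file) {
  df <- columns
  df$ref[is.na(df$ref)] <- "."
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                            sep = "\t")))
  atomicWrite(lines, file)
}

#' Write / read SNP call tables
#' @param calls call table from \code{\link{callSnps}}.
#' @param file path to the TSV.
#' @return \code{writeCalls}: the path, invisibly; \code{readCalls}: the
#'   call \code{data.frame}.
#' @export
writeCalls <- function(calls, file) {
  df <- calls
  if (nrow(df)) df$alt_fraction <- fmtNum(df$alt_fraction, 6L)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                            sep = "\t")))
  atomicWrite(lines, file)
}

#' @rdname writeCalls
#' @export
readCalls <- function(file) {
  df <- read.delim(file, sep = "\t", header = TRUE,
                   colClasses = c(sample = "character", chrom = "character",
                                  ref = "character", alt = "character"))
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  df$alt_fraction <- as.numeric(df$alt_fraction)
  df
}
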