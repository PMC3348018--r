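#' Read a DGV-style table of known CNV regions
#'
#' TAB-delimited with a header; required columns \code{variant_id},
#' \code{chrom}, \code{start}, \code{end}, \code{variation_type}
#' (coordinates 1-based inclusive). Extra columns (e.g. \code{genes},
#' \code{reference}) are preserved as metadata columns.
#'
#' @param file path to the TSV.
#' @return \code{GRanges} sorted within chromosome by start, one range per
#'   record.
#' @seealso \code{\link{annotateSegments}}
#' @export
readDgv <- function(file) {
  df <- read.delim(file, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  need <- c("variant_id", "chrom", "start", "end", "variation_type")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(file, ": missing required DGV column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(df))
    return(GenomicRanges::GRanges(variant_id = character(),
                                  variation_type = character()))
  start <- as.integer(df$start); end <- as.integer(df$end)
  if (anyNA(start) || anyNA(end))
    stop(file, ": line ", which(is.na(start) | is.na(end))[1L] + 1L,
         ": non-numeric coordinate")
  if (any(end < start))
    stop(file, ": line ", which(end < start)[1L] + 1L, ": end < start")
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(start, end))
  extra <- df[setdiff(names(df), c("chrom", "start", "end"))]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(extra, check.names = FALSE)
  GenomeInfoDb::seqlevels(gr) <- chromLevels(df$chrom)
  sort(gr)
}

#' Read a dbSNP-style table of known SNPs
#'
#' TAB-delimited with a header; required columns \code{rsid}, \code{chrom},
#' \code{pos} (1-based), \code{alleles}.
#'
#' @param file path to the TSV.
#' @return width-1 \code{GRanges} sorted by position, with metadata columns
#'   \code{rsid} and \code{alleles}.
#' @export
readDbsnp <- function(file) {
  df <- read.delim(file, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  need <- c("rsid", "chrom", "pos", "alleles")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(file, ": missing required dbSNP column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(df))
    return(GenomicRanges::GRanges(rsid = character(), alleles = character()))
  pos <- as.integer(df$pos)
  if (anyNA(pos) || any(pos < 1L))
    stop(file, ": invalid SNP position")
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(pos, pos),
                               rsid = df$rsid, alleles = df$alleles)
  GenomeInfoDb::seqlevels(gr) <- chromLevels(df$chrom)
  sort(gr)
}

#' Classify detected segments as known or novel
#'
#' A segment is \code{known} when at least one record on the same
#' chromosome overlaps it by >= 1 bp with reciprocal overlap of at least
#' \code{minReciprocal}, where the reciprocal overlap of two intervals is
#' \code{min(overlap / length(segment), overlap / length(record))} (a
#' symmetric quantity in [0, 1]). With the default \code{minReciprocal = 0}
#' any 1-bp overlap makes a segment known. All qualifying hits are listed,
#' sorted per segment by overlap (bp) descending, ties by variant id.
#'
#' @param segments segment \code{GRanges} (see \code{\link{CnvSegments}}).
#' @param dgv \code{GRanges} of known regions from \code{\link{readDgv}}.
#' @param minReciprocal required reciprocal overlap in [0, 1].
#' @param matchType if \code{TRUE}, a record only supports a segment when
#'   its \code{variation_type} equals the segment's type (records typed
#'   \code{"cnv"}, case-insensitively, match either); default matches
#'   regardless of type.
#' @return list with \code{segments} (input with \code{known_status} set to
#'   \code{"known"}/\code{"novel"}) and \code{hits} (a
#'   \code{S4Vectors::DataFrame} with one row per qualifying segment-record
#'   pair: segment index and coordinates, \code{variant_id},
#'   \code{variation_type}, \code{overlap_bp}, \code{reciprocal_overlap},
#'   plus any extra record columns such as genes and reference).
#' @examples
#' seg <- CnvSegments(GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200),
#'   sample = "s1", type = "gain", n_probes = 5L, first_probe = 1L,
#'   last_probe = 5L, sw_score = 2, segmental_mean = 0.8))
#' dgv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 300),
#'   variant_id = "v1", variation_type = "gain")
#' annotateSegments(seg, dgv)$segments
#' @export
annotateSegments <- function(segments, dgv, minReciprocal = 0,
                             matchType = FALSE) {
  stopifnot(minReciprocal >= 0, minReciprocal <= 1)
  segments <- CnvSegments(segments)
  ## harmonize seqlevels so findOverlaps compares labels verbatim without
  ## cross-object seqinfo warnings
  segLev <- GenomeInfoDb::seqlevels(segments)
  dgvLev <- GenomeInfoDb::seqlevels(dgv)
  if (!identical(segLev, dgvLev)) {
    lev <- union(segLev, dgvLev)
    GenomeInfoDb::seqlevels(segments) <- lev
    GenomeInfoDb::seqlevels(dgv) <- lev
  }
  ov <- GenomicRanges::findOverlaps(segments, dgv, minoverlap = 1L)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (length(ov)) {
    overlapBp <- pmin(GenomicRanges::end(segments)[qh],
                      GenomicRanges::end(dgv)[sh]) -
      pmax(GenomicRanges::start(segments)[qh],
           GenomicRanges::start(dgv)[sh]) + 1L
    recip <- pmin(overlapBp / GenomicRanges::width(segments)[qh],
                  overlapBp / GenomicRanges::width(dgv)[sh])
    keep <- recip >= minReciprocal
    if (matchType) {
      recType <- tolower(S4Vectors::mcols(dgv)$variation_type[sh])
      segType <- S4Vectors::mcols(segments)$type[qh]
      keep <- keep & (recType == segType | recType == "cnv")
    }
    qh <- qh[keep]; sh <- sh[keep]
    overlapBp <- overlapBp[keep]; recip <- recip[keep]
  } else {
    overlapBp <- integer(); recip <- numeric()
  }
  vid <- S4Vectors::mcols(dgv)$variant_id[sh]
  ord <- order(qh, -overlapBp, vid)
  qh <- qh[ord]; sh <- sh[ord]; overlapBp <- overlapBp[ord]; recip <- recip[ord]
  hits <- S4Vectors::DataFrame(
    segment = qh,
    chrom = as.character(GenomicRanges::seqnames(segments))[qh],
    start = GenomicRanges::start(segments)[qh],
    end = GenomicRanges::end(segments)[qh],
    sample = S4Vectors::mcols(segments)$sample[qh],
    type = S4Vectors::mcols(segments)$type[qh],
    overlap_bp = overlapBp, reciprocal_overlap = recip)
  recCols <- S4Vectors::mcols(dgv)[sh, , drop = FALSE]
  hits <- cbind(hits, recCols)
  status <- rep("novel", length(segments))
  status[unique(qh)] <- "known"
  S4Vectors::mcols(segments)$known_status <- status
  list(segments = segments, hits = hits)
}

#' Known SNPs in a locus range
#'
#' @param snps \code{GRanges} from \code{\link{readDbsnp}}.
#' @param chrom chromosome label (verbatim match).
#' @param start,end 1-based inclusive query bounds, \code{start <= end}.
#' @return the records with position in \code{[start, end]} on
#'   \code{chrom}, sorted by position.
#' @export
snpsInRange <- function(snps, chrom, start, end) {
  stopifnot(start <= end)
  pos <- GenomicRanges::start(snps)
  hit <- as.character(GenomicRanges::seqnames(snps)) == chrom &
    pos >= start & pos <= end
  out <- snps[hit]
  out[order(GenomicRanges::start(out))]
}

#' Write annotation hits to TSV
#'
#' @param hits the \code{hits} element returned by
#'   \code{\link{annotateSegments}}.
#' @param file output path; written atomically.
#' @return the file path, invisibly.
#' @export
writeHits <- function(hits, file) {
  df <- as.data.frame(hits)
  if ("reciprocal_overlap" %in% names(df))
    df$reciprocal_overlap <- fmtNum(df$reciprocal_overlap, 6L)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste,
               c(lapply(df, as.character), sep = "\t")))
  atomicWrite(lines, file)
}
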