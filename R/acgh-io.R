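#' Read a tab-delimited aCGH file
#'
#' The expected format has one probe per row: columns 1-5 are probe id,
#' probe name, chromosome, start locus and end locus (1-based inclusive, bp),
#' and columns 6 onwards carry one log2 intensity ratio per sample. An
#' optional header row names the samples in columns 6+. Empty fields,
#' \code{NA} and \code{NaN} (case-insensitive) in value columns are stored as
#' missing.
#'
#' @param file path to the TAB-delimited file (or a connection).
#' @param headerPolicy \code{"auto"} treats a first row whose 4th field is
#'   non-numeric as a header; \code{"header"}/\code{"none"} force the choice.
#' @return an \code{\linkS4class{AcghSet}}; probes are sorted per chromosome
#'   by start (ties by end then probe id), so row order in the file does not
#'   matter.
#' @examples
#' f <- tempfile()
#' writeLines(c("p1\tp1n\tchr1\t100\t160\t0.10",
#'              "p2\tp2n\tchr1\t200\t260\t-0.80"), f)
#' readAcgh(f)
#' @seealso \code{\link{writeAcgh}}
#' @export
readAcgh <- function(file, headerPolicy = c("auto", "header", "none")) {
  headerPolicy <- match.arg(headerPolicy)
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) stop(file, ": empty aCGH file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)

  hasHeader <- switch(headerPolicy,
    header = TRUE,
    none = FALSE,
    auto = {
      f4 <- if (nf[1L] >= 4L) fields[[1L]][4L] else ""
      is.na(suppressWarnings(as.numeric(f4)))
    })
  sampleNames <- NULL
  lineno <- seq_along(lines)
  if (hasHeader) {
    if (nf[1L] >= 6L) sampleNames <- fields[[1L]][-(1:5)]
    fields <- fields[-1L]
    nf <- nf[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(fields)) stop(file, ": no data rows")
  ncol <- nf[1L]
  if (ncol < 6L)
    stop(sprintf("%s: line %d: expected at least 6 TAB-delimited fields, got %d",
                 file, lineno[1L], ncol))
  if (any(nf != ncol)) {
    bad <- which(nf != ncol)[1L]
    stop(sprintf("%s: line %d: ragged row (%d fields, expected %d)",
                 file, lineno[bad], nf[bad], ncol))
  }
  m <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  nSamples <- ncol - 5L
  if (is.null(sampleNames)) sampleNames <- paste0("sample_", seq_len(nSamples))
  if (length(sampleNames) != nSamples)
    stop(file, ": header names ", length(sampleNames),
         " samples but data rows have ", nSamples, " value columns")

  start <- parseNumericField(m[, 4L], file, lineno, "start coordinate")
  end <- parseNumericField(m[, 5L], file, lineno, "end coordinate")
  if (anyNA(start) || anyNA(end))
    stop(file, ": line ", lineno[which(is.na(start) | is.na(end))[1L]],
         ": missing probe coordinate")
  if (any(start < 1)) {
    bad <- which(start < 1)[1L]
    stop(sprintf("%s: line %d: start locus %s < 1", file, lineno[bad],
                 m[bad, 4L]))
  }
  if (any(end < start)) {
    bad <- which(end < start)[1L]
    stop(sprintf("%s: line %d: end locus %s < start locus %s", file,
                 lineno[bad], m[bad, 5L], m[bad, 4L]))
  }
  values <- matrix(NA_real_, nrow(m), nSamples,
                   dimnames = list(NULL, sampleNames))
  for (j in seq_len(nSamples))
    values[, j] <- parseNumericField(m[, 5L + j], file, lineno, "log2 ratio")

  chrom <- m[, 3L]
  if (any(!nzchar(trimws(chrom))))
    stop(file, ": line ", lineno[which(!nzchar(trimws(chrom)))[1L]],
         ": empty chromosome field")
  probes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(as.integer(start), as.integer(end)),
    probe_id = m[, 1L], probe_name = m[, 2L])
  AcghSet(probes, values)
}

#' Write an AcghSet to the tab-delimited aCGH format
#'
#' Writes a header row (\code{probe_id probe_name chrom start end} followed
#' by sample names) and one probe per row. Missing log2 values are written as
#' \code{NA}. Values are written with enough significant digits (default 12)
#' for a read/write round trip to reproduce them to well below 1e-9.
#'
#' @param x an \code{\linkS4class{AcghSet}}.
#' @param file output path; written atomically.
#' @param digits significant digits for log2 values.
#' @return the file path, invisibly.
#' @export
writeAcgh <- function(x, file, digits = 12L) {
  gr <- SummarizedExperiment::rowRanges(x)
  vals <- log2Ratios(x)
  header <- paste(c("probe_id", "probe_name", "chrom", "start", "end",
                    colnames(x)), collapse = "\t")
  valTxt <- apply(vals, 1L, function(r) paste(fmtNum(r, digits), collapse = "\t"))
  rows <- paste(probeIds(x), S4Vectors::mcols(gr)$probe_name,
                as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr), GenomicRanges::end(gr),
                valTxt, sep = "\t")
  atomicWrite(c(header, rows), file)
}

#' Read a probe-to-gene mapping table
#'
#' Two TAB-delimited columns: probe id, gene name. A duplicated probe id
#' keeps the last occurrence and raises a warning.
#'
#' @param file path to the two-column TSV.
#' @return named character vector (names = probe ids, values = gene names);
#'   empty input yields an empty vector.
#' @examples
#' f <- tempfile(); writeLines("p1\tBRCA2", f)
#' readGeneMap(f)
#' @export
readGeneMap <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) return(setNames(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(sprintf("%s: line %d: expected 2 TAB-delimited fields, got %d",
                 file, bad, nf[bad]))
  }
  ids <- vapply(fields, `[`, character(1L), 1L)
  genes <- vapply(fields, `[`, character(1L), 2L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicated probe id(s) in gene map, keeping last occurrence: ",
            paste(dup, collapse = ", "))
  }
  setNames(genes, ids)[!duplicated(ids, fromLast = TRUE)]
}

segmentMcols <- c("sample", "type", "n_probes", "first_probe", "last_probe",
                  "sw_score", "segmental_mean", "qc_flags", "known_status")

#' Construct a CNV segment container
#'
#' Detected segments are plain \code{GRanges} with a fixed set of metadata
#' columns: \code{sample}, \code{type} (\code{gain}/\code{loss}),
#' \code{n_probes}, \code{first_probe}/\code{last_probe} (1-based indices
#' into the chromosome's probe order), \code{sw_score} (the island's
#' maximum cumulative threshold-subtracted score), \code{segmental_mean}
#' (mean log2 ratio over the island's probes), \code{qc_flags}
#' (comma-separated, \code{""} before QC) and \code{known_status}
#' (\code{NA}, \code{"known"} or \code{"novel"}). This constructor validates
#' and canonically orders such an object.
#'
#' @param gr \code{GRanges} carrying the metadata columns above (missing QC /
#'   annotation columns are initialized).
#' @return validated \code{GRanges} sorted by (chromosome, start, sample).
#' @export
CnvSegments <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  changed <- FALSE
  if (!"qc_flags" %in% names(mc)) { mc$qc_flags <- ""; changed <- TRUE }
  if (!"known_status" %in% names(mc)) {
    mc$known_status <- NA_character_; changed <- TRUE
  }
  missing <- setdiff(segmentMcols, names(mc))
  if (length(missing))
    stop("segment GRanges lacks metadata column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("n_probes", "first_probe", "last_probe"))
    if (!is.integer(mc[[col]])) {
      mc[[col]] <- as.integer(mc[[col]]); changed <- TRUE
    }
  if (length(gr)) {
    if (any(mc$n_probes < 1L)) stop("segments must span >= 1 probe")
    if (!all(mc$type %in% c("gain", "loss")))
      stop("segment type must be 'gain' or 'loss'")
    if (any(mc$sw_score <= 0)) stop("segment sw_score must be positive")
  }
  if (!identical(names(mc), segmentMcols)) {
    mc <- mc[segmentMcols]; changed <- TRUE
  }
  if (changed) S4Vectors::mcols(gr) <- mc
  chrom <- as.character(GenomicRanges::seqnames(gr))
  ord <- order(match(chrom, chromLevels(chrom)), GenomicRanges::start(gr),
               mc$sample)
  if (identical(ord, seq_along(gr))) gr else gr[ord]
}

#' Write detected CNV segments to TSV
#'
#' One row per segment with header \code{chrom start end sample type
#' n_probes sw_score segmental_mean qc_flags known_status first_probe
#' last_probe}; coordinates are 1-based inclusive, floating-point columns
#' carry 6 significant digits, rows are sorted by (chrom, start, sample).
#' Empty flag sets and unset known status are written as \code{.}.
#'
#' @param segments segment \code{GRanges} (see \code{\link{CnvSegments}}).
#' @param file output path; written atomically.
#' @param digits significant digits for \code{sw_score}/\code{segmental_mean}.
#' @param dropFailed if \code{TRUE}, rows whose QC flags contain anything
#'   other than \code{pass} are omitted.
#' @return the file path, invisibly.
#' @seealso \code{\link{readSegments}}
#' @export
writeSegments <- function(segments, file, digits = 6L, dropFailed = FALSE) {
  segments <- CnvSegments(segments)
  if (dropFailed) {
    keep <- S4Vectors::mcols(segments)$qc_flags %in% c("", "pass")
    segments <- segments[keep]
  }
  header <- paste(c("chrom", "start", "end", "sample", "type", "n_probes",
                    "sw_score", "segmental_mean", "qc_flags", "known_status",
                    "first_probe", "last_probe"), collapse = "\t")
  mc <- S4Vectors::mcols(segments)
  flags <- ifelse(nzchar(mc$qc_flags), mc$qc_flags, ".")
  status <- ifelse(is.na(mc$known_status), ".", mc$known_status)
  rows <- paste(as.character(GenomicRanges::seqnames(segments)),
                GenomicRanges::start(segments), GenomicRanges::end(segments),
                mc$sample, mc$type, mc$n_probes,
                fmtNum(mc$sw_score, digits),
                fmtNum(mc$segmental_mean, digits), flags, status,
                mc$first_probe, mc$last_probe, sep = "\t")
  atomicWrite(c(header, rows), file)
}

#' Read a segment TSV written by \code{\link{writeSegments}}
#'
#' @param file path to the TSV.
#' @return segment \code{GRanges} (empty for a header-only file).
#' @export
readSegments <- function(file) {
  df <- read.delim(file, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  need <- c("chrom", "start", "end", segmentMcols)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(file, ": missing segment column(s): ", paste(missing, collapse = ", "))
  gr <- GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(as.integer(df$start), as.integer(df$end)),
    sample = df$sample, type = df$type, n_probes = as.integer(df$n_probes),
    first_probe = as.integer(df$first_probe),
    last_probe = as.integer(df$last_probe),
    sw_score = as.numeric(df$sw_score),
    segmental_mean = as.numeric(df$segmental_mean),
    qc_flags = ifelse(df$qc_flags == ".", "", df$qc_flags),
    known_status = ifelse(df$known_status == ".", NA_character_,
                          df$known_status))
  CnvSegments(gr)
}
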