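## Independent oracles used across the suite. Each re-derives a quantity by
## brute force / direct enumeration, never through the code path it checks.

## Best contiguous-subarray sum by enumeration of all (i, j) pairs over the
## prefix sums; returns 0 when every subarray sums <= 0.
bruteMaxSubarray <- function(s) {
  n <- length(s)
  if (!n) return(0)
  P <- c(0, cumsum(s))
  sums <- outer(P[-1L], P[-(n + 1L)], "-")   # sums[j, i] = sum(s[i..j])
  max(0, sums[lower.tri(sums, diag = TRUE)])
}

## All-pairs quadratic overlap scan on plain integer intervals (1-based
## inclusive); returns a known/novel verdict per segment.
oracleKnownNovel <- function(seg, rec, minReciprocal) {
  vapply(seq_len(nrow(seg)), function(i) {
    known <- FALSE
    for (j in seq_len(nrow(rec))) {
      if (seg$chrom[i] != rec$chrom[j]) next
      ov <- min(seg$end[i], rec$end[j]) - max(seg$start[i], rec$start[j]) + 1L
      if (ov < 1L) next
      recip <- min(ov / (seg$end[i] - seg$start[i] + 1L),
                   ov / (rec$end[j] - rec$start[j] + 1L))
      if (recip >= minReciprocal) { known <- TRUE; break }
    }
    if (known) "known" else "novel"
  }, character(1L))
}

## Naive pileup from SAM text: one read at a time, walking the CIGAR along
## the reference. Counts A/C/G/T/N (other letters pooled into N) and DEL.
oraclePileup <- function(samLines, chrom, start, end) {
  width <- end - start + 1L
  letters <- c("A", "C", "G", "T", "N", "DEL")
  counts <- matrix(0L, width, 6L, dimnames = list(NULL, letters))
  for (line in samLines) {
    if (startsWith(line, "@")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) > 0L) next          # unmapped
    if (f[3L] != chrom) next
    pos <- as.integer(f[4L])
    cigar <- f[6L]
    seq <- f[10L]
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
    refp <- pos; readp <- 1L
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          if (refp >= start && refp <= end) {
            b <- toupper(substr(seq, readp, readp))
            col <- if (b %in% c("A", "C", "G", "T")) b else "N"
            counts[refp - start + 1L, col] <- counts[refp - start + 1L, col] + 1L
          }
          refp <- refp + 1L; readp <- readp + 1L
        }
      } else if (type == "D") {
        for (k in seq_len(len)) {
          if (refp >= start && refp <= end)
            counts[refp - start + 1L, "DEL"] <-
              counts[refp - start + 1L, "DEL"] + 1L
          refp <- refp + 1L
        }
      } else if (type == "N") {
        refp <- refp + len
      } else if (type %in% c("I", "S")) {
        readp <- readp + len
      }                                        # H, P: no-op
    }
  }
  data.frame(pos = seq.int(start, end), counts,
             depth = as.integer(rowSums(counts)), check.names = FALSE)
}

## Compact builder for a single-chromosome AcghSet from raw values.
makeAcgh <- function(values, chrom = "chr1", spacing = 100L, width = 60L,
                     samples = NULL) {
  values <- as.matrix(values)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  colnames(values) <- samples
  start <- (seq_len(nrow(values)) - 1L) * spacing + 1L
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, start + width - 1L),
    probe_id = sprintf("p%03d", seq_len(nrow(values))),
    probe_name = sprintf("pn%03d", seq_len(nrow(values))))
  AcghSet(gr, values)
}

## Reciprocal overlap of two 1-based inclusive intervals on one chromosome.
recipOverlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  if (ov < 1L) return(0)
  min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
}

## Random segment/record tables for annotation oracle checks.
randomIntervalSet <- function(n, chroms = c("chr1", "chr2"), span = 100000L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(5000L, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width)
}

segGrFromDf <- function(df, sample = "s1") {
  CnvSegments(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    sample = sample, type = "gain", n_probes = 5L, first_probe = 1L,
    last_probe = 5L, sw_score = 1, segmental_mean = 0.5))
}

dgvGrFromDf <- function(df) {
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    variant_id = sprintf("v%04d", seq_len(nrow(df))),
    variation_type = rep("cnv", nrow(df)))
}
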