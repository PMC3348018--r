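#' Simulate an aCGH dataset with planted CNVs
#'
#' Probes are laid out at fixed spacing along each chromosome; every log2
#' ratio is \code{baseline + sum(applicable event deltas) + N(0, noiseSd)}.
#' Events are rectangular shifts over a probe span, applied to one sample
#' (\code{sample} column) or to all samples (\code{sample = NA}). The
#' output is a pure function of the arguments including \code{seed}.
#'
#' @param nProbes named integer vector: probes per chromosome, e.g.
#'   \code{c(chr1 = 120)}.
#' @param probeSpacing distance between consecutive probe starts, bp.
#' @param probeLength probe width, bp (<= \code{probeSpacing}).
#' @param baseline baseline log2 ratio (0 = copy-neutral).
#' @param noiseSd standard deviation of i.i.d. Gaussian probe noise (>= 0).
#' @param events \code{data.frame} with columns \code{chrom},
#'   \code{first_probe}, \code{last_probe} (1-based probe indices within
#'   the chromosome), \code{delta} (log2 shift) and optionally
#'   \code{sample}; \code{NULL} for an event-free dataset. Events
#'   overlapping in probe span on the same sample are an error.
#' @param nSamples number of samples (\code{sample_1}, ...).
#' @param seed RNG seed; same spec + seed gives bit-identical output.
#' @return list with \code{acgh} (an \code{\linkS4class{AcghSet}}) and
#'   \code{truth} (\code{data.frame}: \code{chrom}, \code{start},
#'   \code{end}, \code{first_probe}, \code{last_probe}, \code{delta},
#'   \code{sample}).
#' @examples
#' sim <- simulateAcgh(c(chr1 = 50), noiseSd = 0.15,
#'   events = data.frame(chrom = "chr1", first_probe = 20, last_probe = 29,
#'                       delta = 1), seed = 1)
#' sim$truth
#' @export
simulateAcgh <- function(nProbes, probeSpacing = 5000L, probeLength = 60L,
                         baseline = 0, noiseSd = 0.15, events = NULL,
                         nSamples = 1L, seed = 1L) {
  stopifnot(noiseSd >= 0, probeLength >= 1, probeLength <= probeSpacing,
            all(nProbes >= 1))
  if (is.null(names(nProbes)))
    names(nProbes) <- paste0("chr", seq_along(nProbes))
  sampleNames <- paste0("sample_", seq_len(nSamples))
  if (!is.null(events) && nrow(events)) {
    if (!"sample" %in% names(events)) events$sample <- NA_character_
    bad <- !events$chrom %in% names(nProbes) |
      events$first_probe < 1L | events$last_probe < events$first_probe |
      events$last_probe > nProbes[events$chrom]
    if (any(bad)) stop("event probe span out of bounds (row ",
                       which(bad)[1L], ")")
    ## per-sample overlap check; sample = NA applies to every sample
    for (s in sampleNames) {
      e <- events[is.na(events$sample) | events$sample == s, , drop = FALSE]
      for (ch in unique(e$chrom)) {
        ee <- e[e$chrom == ch, , drop = FALSE]
        if (nrow(ee) > 1L) {
          ord <- order(ee$first_probe)
          if (any(ee$first_probe[ord][-1L] <=
                  ee$last_probe[ord][-nrow(ee)]))
            stop("overlapping planted events on sample ", s, " (", ch, ")")
        }
      }
    }
  }
  chrom <- rep(names(nProbes), nProbes)
  within <- unlist(lapply(nProbes, seq_len), use.names = FALSE)
  start <- (within - 1L) * probeSpacing + 1L
  probes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, start + probeLength - 1L),
    probe_id = sprintf("p%05d", seq_along(chrom)),
    probe_name = sprintf("probe_%s_%d", chrom, within))
  signal <- matrix(baseline, length(chrom), nSamples,
                   dimnames = list(NULL, sampleNames))
  truth <- data.frame(chrom = character(), start = integer(),
                      end = integer(), first_probe = integer(),
                      last_probe = integer(), delta = numeric(),
                      sample = character())
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ch <- events$chrom[i]
      rows <- which(chrom == ch &
                    within >= events$first_probe[i] &
                    within <= events$last_probe[i])
      cols <- if (is.na(events$sample[i])) sampleNames else events$sample[i]
      signal[rows, cols] <- signal[rows, cols] + events$delta[i]
      truth <- rbind(truth, data.frame(
        chrom = ch, start = min(start[rows]),
        end = max(start[rows]) + probeLength - 1L,
        first_probe = events$first_probe[i],
        last_probe = events$last_probe[i], delta = events$delta[i],
        sample = if (is.na(events$sample[i])) "all" else events$sample[i]))
    }
  }
  values <- withSeed(seed, {
    signal + matrix(rnorm(length(signal), 0, noiseSd), nrow(signal))
  })
  list(acgh = AcghSet(probes, values), truth = truth)
}

#' Simulate single-end reads with planted SNPs and a deletion
#'
#' A random reference of \code{refLength} bp is drawn from \code{baseComp};
#' the donor genome is the reference with the optional homozygous
#' \code{deletion} excised. Fixed-length reads are placed uniformly along
#' the donor, so the deleted interval receives no read bases and reads
#' crossing the deletion junction align with a \code{D} CIGAR operation
#' across it. At each planted SNP, every read covering the site carries the
#' alternate base with probability equal to the planted allele fraction;
#' sequencing errors substitute a random different base per sequenced base
#' with probability \code{errorRate}. Reads are emitted coordinate-sorted
#' as SAM text.
#'
#' @param refLength reference length, bp.
#' @param readLength read length, bp.
#' @param meanDepth target mean sequenced depth over the donor genome.
#' @param snps \code{data.frame} with columns \code{pos}, \code{alt},
#'   \code{fraction} (allele fraction in (0, 1]); \code{NULL} for none.
#'   \code{alt = NA} draws a base different from the (random) reference.
#'   Planting a SNP inside the deletion, or with \code{alt} equal to the
#'   reference base, is an error.
#' @param deletion \code{c(start, end)} (1-based inclusive) or \code{NULL};
#'   deleting the whole reference is an error.
#' @param errorRate per-base substitution error probability.
#' @param baseComp probabilities for A, C, G, T in the reference.
#' @param chromName reference sequence name in FASTA and SAM.
#' @param seed RNG seed; same spec + seed gives bit-identical output.
#' @return list with \code{reference} (\code{DNAStringSet}), \code{sam}
#'   (character vector of SAM lines) and \code{truth} (list with
#'   \code{snps} and \code{deletion} tables).
#' @seealso \code{\link{writeSimulatedReads}}
#' @export
simulateReads <- function(refLength = 10000L, readLength = 100L,
                          meanDepth = 30, snps = NULL, deletion = NULL,
                          errorRate = 0, baseComp = rep(0.25, 4),
                          chromName = "ref", seed = 1L) {
  stopifnot(refLength >= readLength, errorRate >= 0, errorRate < 1,
            meanDepth > 0)
  delLen <- 0L
  if (!is.null(deletion)) {
    deletion <- as.integer(deletion)
    stopifnot(length(deletion) == 2L, deletion[1L] >= 1L,
              deletion[2L] >= deletion[1L], deletion[2L] <= refLength)
    delLen <- deletion[2L] - deletion[1L] + 1L
    if (delLen >= refLength)
      stop("planted deletion covers the whole reference")
  }
  donorLen <- refLength - delLen
  if (donorLen < readLength)
    stop("donor genome shorter than the read length")
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    refChars <- sample(bases, refLength, replace = TRUE, prob = baseComp)
    if (!is.null(snps) && nrow(snps)) {
      snps$pos <- as.integer(snps$pos)
      stopifnot(all(snps$pos >= 1L), all(snps$pos <= refLength),
                all(snps$fraction > 0), all(snps$fraction <= 1),
                all(is.na(snps$alt) | snps$alt %in% bases))
      ## alt = NA: draw a base different from the reference
      for (j in which(is.na(snps$alt)))
        snps$alt[j] <- sample(setdiff(bases, refChars[snps$pos[j]]), 1L)
      if (anyDuplicated(snps$pos)) stop("duplicate planted SNP positions")
      if (!is.null(deletion) &&
          any(snps$pos >= deletion[1L] & snps$pos <= deletion[2L]))
        stop("planted SNP inside the planted deletion is unobservable")
      if (any(refChars[snps$pos] == snps$alt))
        stop("planted alt equals the reference base at that position")
      snps$ref <- refChars[snps$pos]
    }
    donorChars <- if (delLen)
      refChars[-(deletion[1L]:deletion[2L])] else refChars
    ## donor coordinate -> reference coordinate
    donor2ref <- if (delLen == 0L) identity else
      function(d) ifelse(d < deletion[1L], d, d + delLen)
    nReads <- max(1L, round(meanDepth * donorLen / readLength))
    starts <- sample.int(donorLen - readLength + 1L, nReads, replace = TRUE)
    seqs <- character(nReads); cigars <- character(nReads)
    refPos <- integer(nReads)
    for (i in seq_len(nReads)) {
      d0 <- starts[i]
      readChars <- donorChars[d0:(d0 + readLength - 1L)]
      dPos <- d0:(d0 + readLength - 1L)
      rPos <- donor2ref(dPos)
      refPos[i] <- rPos[1L]
      if (delLen && d0 < deletion[1L] &&
          d0 + readLength - 1L >= deletion[1L]) {
        a <- deletion[1L] - d0
        cigars[i] <- sprintf("%dM%dD%dM", a, delLen, readLength - a)
      } else {
        cigars[i] <- sprintf("%dM", readLength)
      }
      if (!is.null(snps) && nrow(snps)) {
        hit <- match(snps$pos, rPos)
        for (j in which(!is.na(hit)))
          if (runif(1L) < snps$fraction[j])
            readChars[hit[j]] <- snps$alt[j]
      }
      if (errorRate > 0) {
        err <- which(runif(readLength) < errorRate)
        for (j in err)
          readChars[j] <- sample(setdiff(bases, readChars[j]), 1L)
      }
      seqs[i] <- paste(readChars, collapse = "")
    }
    ord <- order(refPos)
    qual <- strrep("I", readLength)
    sam <- c(
      "@HD\tVN:1.6\tSO:coordinate",
      sprintf("@SQ\tSN:%s\tLN:%d", chromName, refLength),
      sprintf("read%05d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
              seq_len(nReads)[ord], chromName, refPos[ord], cigars[ord],
              seqs[ord], qual))
    reference <- Biostrings::DNAStringSet(
      setNames(paste(refChars, collapse = ""), chromName))
    truth <- list(
      snps = if (!is.null(snps) && nrow(snps))
        snps[, c("pos", "ref", "alt", "fraction")]
      else data.frame(pos = integer(), ref = character(),
                      alt = character(), fraction = numeric()),
      deletion = if (delLen)
        data.frame(chrom = chromName, start = deletion[1L],
                   end = deletion[2L])
      else data.frame(chrom = character(), start = integer(),
                      end = integer()))
    list(reference = reference, sam = sam, truth = truth)
  })
}

#' Write a simulated read set to disk
#'
#' Writes \code{<prefix>.fa} (reference), \code{<prefix>.sam} (alignments)
#' and \code{<prefix>.snps.tsv} / \code{<prefix>.deletion.tsv} (truth).
#'
#' @param sim result of \code{\link{simulateReads}}.
#' @param prefix output path prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulatedReads <- function(sim, prefix) {
  fa <- paste0(prefix, ".fa")
  Biostrings::writeXStringSet(sim$reference, fa)
  samFile <- atomicWrite(sim$sam, paste0(prefix, ".sam"))
  writeTruthTable <- function(df, path) {
    atomicWrite(c(paste(names(df), collapse = "\t"),
                  if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                                 sep = "\t"))), path)
  }
  snpFile <- writeTruthTable(sim$truth$snps, paste0(prefix, ".snps.tsv"))
  delFile <- writeTruthTable(sim$truth$deletion,
                             paste0(prefix, ".deletion.tsv"))
  invisible(c(fasta = fa, sam = samFile, snps = snpFile,
              deletion = delFile))
}

#' Build DGV/dbSNP-style annotation fixtures from simulation truth
#'
#' One DGV-style record is produced per planted CNV (coordinates jittered
#' independently by up to \code{jitterBp} at each side), plus
#' \code{nDecoys} decoy records placed so that they overlap no truth
#' interval; dbSNP-style records mirror the planted SNP positions plus
#' decoy positions.
#'
#' @param cnvTruth \code{data.frame} with \code{chrom}, \code{start},
#'   \code{end} and optionally \code{type}; may have zero rows.
#' @param snpTruth \code{data.frame} with \code{chrom}, \code{pos} and
#'   optionally \code{ref}, \code{alt}; may have zero rows.
#' @param chromLengths named vector giving each chromosome's length, used
#'   to place decoys.
#' @param jitterBp maximum absolute jitter per boundary, bp.
#' @param nDecoys decoy records per table.
#' @param seed RNG seed.
#' @return list with \code{dgv} and \code{dbsnp} \code{data.frame}s in the
#'   fixture formats read by \code{\link{readDgv}} / \code{\link{readDbsnp}}.
#' @export
makeAnnotationFixtures <- function(cnvTruth, snpTruth, chromLengths,
                                   jitterBp = 0L, nDecoys = 0L, seed = 1L) {
  withSeed(seed, {
    dgv <- data.frame(variant_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      variation_type = character(), genes = character(),
                      reference = character())
    if (!is.null(cnvTruth) && nrow(cnvTruth)) {
      js <- if (jitterBp > 0)
        sample.int(2L * jitterBp + 1L, nrow(cnvTruth), replace = TRUE) -
          jitterBp - 1L else integer(nrow(cnvTruth))
      je <- if (jitterBp > 0)
        sample.int(2L * jitterBp + 1L, nrow(cnvTruth), replace = TRUE) -
          jitterBp - 1L else integer(nrow(cnvTruth))
      s <- pmax(1L, cnvTruth$start + js)
      e <- pmax(s, cnvTruth$end + je)
      dgv <- data.frame(
        variant_id = sprintf("dgv%04d", seq_len(nrow(cnvTruth))),
        chrom = cnvTruth$chrom, start = s, end = e,
        variation_type = if ("type" %in% names(cnvTruth)) cnvTruth$type
                         else "cnv",
        genes = "", reference = "synthetic_truth")
    }
    truthGr <- if (!is.null(cnvTruth) && nrow(cnvTruth))
      GenomicRanges::GRanges(cnvTruth$chrom,
                             IRanges::IRanges(cnvTruth$start, cnvTruth$end))
    else GenomicRanges::GRanges()
    n <- 0L; guard <- 0L
    while (n < nDecoys && guard < 1000L * max(1L, nDecoys)) {
      guard <- guard + 1L
      ch <- sample(names(chromLengths), 1L)
      w <- sample(200:2000, 1L)
      if (chromLengths[ch] <= w + 1L) next
      s <- sample.int(chromLengths[ch] - w, 1L)
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + w - 1L))
      lev <- union(GenomeInfoDb::seqlevels(cand),
                   GenomeInfoDb::seqlevels(truthGr))
      GenomeInfoDb::seqlevels(cand) <- lev
      GenomeInfoDb::seqlevels(truthGr) <- lev
      if (length(truthGr) &&
          length(GenomicRanges::findOverlaps(cand, truthGr))) next
      n <- n + 1L
      dgv <- rbind(dgv, data.frame(
        variant_id = sprintf("decoy%04d", n), chrom = ch, start = s,
        end = s + w - 1L, variation_type = sample(c("gain", "loss"), 1L),
        genes = "", reference = "synthetic_decoy"))
    }

    dbsnp <- data.frame(rsid = character(), chrom = character(),
                        pos = integer(), alleles = character())
    if (!is.null(snpTruth) && nrow(snpTruth)) {
      alleles <- if (all(c("ref", "alt") %in% names(snpTruth)))
        paste0(snpTruth$ref, "/", snpTruth$alt) else "N/N"
      dbsnp <- data.frame(
        rsid = sprintf("rs%06d", seq_len(nrow(snpTruth))),
        chrom = snpTruth$chrom, pos = as.integer(snpTruth$pos),
        alleles = alleles)
    }
    if (nDecoys > 0L) {
      used <- paste(dbsnp$chrom, dbsnp$pos)
      m <- 0L; guard <- 0L
      while (m < nDecoys && guard < 1000L * nDecoys) {
        guard <- guard + 1L
        ch <- sample(names(chromLengths), 1L)
        p <- sample.int(chromLengths[ch], 1L)
        if (paste(ch, p) %in% used) next
        m <- m + 1L
        used <- c(used, paste(ch, p))
        dbsnp <- rbind(dbsnp, data.frame(
          rsid = sprintf("rsdecoy%04d", m), chrom = ch, pos = p,
          alleles = paste(sample(c("A", "C", "G", "T"), 2L), collapse = "/")))
      }
    }
    list(dgv = dgv, dbsnp = dbsnp)
  })
}

#' Write annotation fixture tables
#'
#' @param fixtures list from \code{\link{makeAnnotationFixtures}}.
#' @param dgvFile,dbsnpFile output paths (either may be \code{NULL}).
#' @return invisibly, the written paths.
#' @export
writeAnnotationFixtures <- function(fixtures, dgvFile = NULL,
                                    dbsnpFile = NULL) {
  writeTab <- function(df, path) {
    atomicWrite(c(paste(names(df), collapse = "\t"),
                  if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                                 sep = "\t"))), path)
  }
  out <- character()
  if (!is.null(dgvFile)) out["dgv"] <- writeTab(fixtures$dgv, dgvFile)
  if (!is.null(dbsnpFile)) out["dbsnp"] <- writeTab(fixtures$dbsnp, dbsnpFile)
  invisible(out)
}
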