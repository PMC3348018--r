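## Small SAM builder for hand-crafted alignment cases.
writeSam <- function(lines, refLen = 100L, chrom = "ref") {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, refLen), lines), f)
  f
}
samRead <- function(name, pos, cigar, seq, flag = 0L, mapq = 60L,
                    qual = NULL, chrom = "ref") {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          name, flag, chrom, pos, mapq, cigar, seq, qual)
}

test_that("pileup counts bases, deletions and CIGAR semantics correctly", {
  sam <- writeSam(c(
    samRead("r1", 10L, "5M", "AAAAA"),
    samRead("r2", 10L, "5M", "AACAA"),
    samRead("r3", 10L, "2M1D2M", "GGGG"),
    samRead("r4", 8L, "2M2I3M", "TTGGAAA")))  # insertion consumes no ref
  cols <- pileupColumns(sam, "ref", 8, 16)
  expect_equal(cols$pos, 8:16)
  ## position 10: A (r1), A (r2), G (r3), A (r4, third M base after 2M2I)
  p10 <- cols[cols$pos == 10L, ]
  expect_equal(p10$depth, 4L)
  expect_equal(p10$A, 3L)
  expect_equal(p10$G, 1L)
  ## position 12 falls in r3's deletion
  p12 <- cols[cols$pos == 12L, ]
  expect_equal(p12$DEL, 1L)
  expect_equal(p12$A, 2L)   # r1, r2 carry A at offset 3
  expect_equal(p12$C, 1L)   # r2's third base
  expect_equal(p12$depth, 4L)
  ## conservation on every column
  expect_equal(rowSums(cols[, c("A", "C", "G", "T", "N", "DEL")]),
               as.double(cols$depth), ignore_attr = TRUE)
  ## uncovered positions have zero depth
  expect_equal(cols$depth[cols$pos == 16L], 0L)
})

test_that("pileup respects flag, mapping-quality and base-quality filters", {
  sam <- writeSam(c(
    samRead("ok", 5L, "4M", "AAAA"),
    samRead("dup", 5L, "4M", "CCCC", flag = 1024L),
    samRead("second", 5L, "4M", "GGGG", flag = 256L),
    samRead("unmapped", 5L, "*", "TTTT", flag = 4L),
    samRead("lowmapq", 5L, "4M", "TTTT", mapq = 5L),
    samRead("lowbq", 5L, "4M", "TTTT", qual = "!!!!")))  # Phred 0
  cols <- pileupColumns(sam, "ref", 5, 8)
  ## defaults exclude duplicate/secondary/unmapped but keep low qualities
  expect_equal(unique(cols$T), 2L)
  expect_equal(unique(cols$A), 1L)
  expect_equal(unique(cols$C), 0L)

  strict <- pileupColumns(sam, "ref", 5, 8, DepthParams(minMapq = 30L))
  expect_equal(unique(strict$T), 1L)
  stricter <- pileupColumns(sam, "ref", 5, 8,
                            DepthParams(minMapq = 30L, minBaseq = 10L))
  expect_equal(unique(stricter$T), 0L)
  expect_equal(unique(stricter$A), 1L)

  expect_error(pileupColumns(sam, "nosuchref", 1, 5), "no reference sequence")
})

test_that("pileup matches the naive CIGAR-walking oracle on random read sets", {
  set.seed(5)
  for (rep in 1:15) {
    refLen <- sample(200:400, 1L)
    rl <- sample(30:50, 1L)
    del <- if (runif(1) < 0.5) {
      s <- sample.int(refLen - 80L, 1L); c(s, s + sample(20:60, 1L))
    } else NULL
    snps <- if (runif(1) < 0.5)
      data.frame(pos = sample(setdiff(seq_len(refLen),
                   if (is.null(del)) integer() else del[1L]:del[2L]), 2L),
                 alt = NA, fraction = runif(2, 0.3, 1)) else NULL
    sim <- simulateReads(refLength = refLen, readLength = rl,
                         meanDepth = runif(1, 2, 6), snps = snps,
                         deletion = del, errorRate = 0.005,
                         seed = 5000 + rep)
    pre <- tempfile()
    writeSimulatedReads(sim, pre)
    got <- pileupColumns(paste0(pre, ".sam"), "ref", 1, refLen)
    want <- oraclePileup(sim$sam, "ref", 1, refLen)
    expect_equal(got$depth, want$depth)
    for (b in c("A", "C", "G", "T", "N", "DEL"))
      expect_equal(got[[b]], want[[b]], label = b)
    unlink(Sys.glob(paste0(pre, "*")))
  }
})

test_that("alleleFrequency normalizes counts to frequencies", {
  col <- data.frame(chrom = "ref", pos = 1L, ref = NA, depth = 3L,
                    A = 2L, C = 0L, G = 1L, T = 0L, N = 0L, DEL = 0L)
  expect_equal(alleleFrequency(col[1, ]), c(A = 2 / 3, G = 1 / 3))
  single <- within(col, {depth <- 1L; A <- 1L; G <- 0L})
  expect_equal(alleleFrequency(single[1, ]), c(A = 1))
  half <- within(col, {depth <- 10L; A <- 5L; G <- 0L; DEL <- 5L})
  expect_equal(alleleFrequency(half[1, ]), c(A = 0.5, DEL = 0.5))
  expect_equal(sum(alleleFrequency(col[1, ])), 1, tolerance = 1e-12)
  zero <- within(col, {depth <- 0L; A <- 0L; G <- 0L})
  expect_error(alleleFrequency(zero[1, ]), "depth 0")
})

test_that("callSnps applies depth, fraction and tie-break rules", {
  mkcol <- function(ref, A = 0L, C = 0L, G = 0L, T = 0L, N = 0L, DEL = 0L)
    data.frame(chrom = "ref", pos = 1L, ref = ref,
               depth = A + C + G + T + N + DEL,
               A = A, C = C, G = G, T = T, N = N, DEL = DEL)
  call1 <- callSnps(mkcol("A", A = 2L, G = 8L), 5L, 0.2)
  expect_equal(call1$alt, "G")
  expect_equal(call1$alt_fraction, 0.8)
  expect_equal(nrow(callSnps(mkcol("A", A = 9L, G = 1L), 5L, 0.2)), 0L)
  expect_equal(nrow(callSnps(mkcol("A", A = 1L, G = 2L), 5L, 0.2)), 0L)
  ## alt ties break by count then alphabetically
  tie <- callSnps(mkcol("A", A = 2L, C = 4L, T = 4L), 5L, 0.2)
  expect_equal(tie$alt, "C")
  ## DEL and N add depth but never calls; they dilute the fraction
  dil <- callSnps(mkcol("A", G = 4L, DEL = 6L), 5L, 0.2)
  expect_equal(dil$alt_fraction, 0.4)
  expect_equal(nrow(callSnps(mkcol("A", N = 10L), 5L, 0.2)), 0L)
  ## unanimity at minAltFraction = 1
  expect_equal(nrow(callSnps(mkcol("A", A = 1L, G = 9L), 5L, 1)), 0L)
  expect_equal(nrow(callSnps(mkcol("A", G = 10L), 5L, 1)), 1L)
  expect_error(callSnps(mkcol(NA_character_, A = 5L)), "reference")
})

test_that("depthDeletionScan reports maximal low-depth runs", {
  cols <- data.frame(chrom = "ref", pos = 1:6, ref = NA,
                     depth = c(10L, 10L, 0L, 0L, 0L, 10L),
                     A = c(10L, 10L, 0L, 0L, 0L, 10L),
                     C = 0L, G = 0L, T = 0L, N = 0L, DEL = 0L)
  run <- depthDeletionScan(cols, 0L, 3L)
  expect_equal(run, data.frame(chrom = "ref", start = 3L, end = 5L,
                               mean_depth = 0))
  expect_equal(nrow(depthDeletionScan(cols, 0L, 4L)), 0L)
  ## intervals are disjoint and each at least minSpan wide
  set.seed(8)
  d <- sample(0:3, 300, replace = TRUE)
  cols2 <- data.frame(chrom = "ref", pos = seq_along(d), ref = NA,
                      depth = d, A = d, C = 0L, G = 0L, T = 0L, N = 0L,
                      DEL = 0L)
  runs <- depthDeletionScan(cols2, 1L, 3L)
  if (nrow(runs) > 1L)
    expect_true(all(runs$start[-1L] > runs$end[-nrow(runs)]))
  expect_true(all(runs$end - runs$start + 1L >= 3L))
})

test_that("compareSamples finds site differences and consecutive runs", {
  mkCalls <- function(pos, alt, sample = "a")
    data.frame(sample = sample, chrom = "ref", pos = pos, ref = "A",
               alt = alt, depth = 20L, alt_fraction = 0.9)
  a <- mkCalls(c(10L, 20L, 30L, 40L), c("G", "G", "G", "G"))
  expect_equal(nrow(compareSamples(a, a, 2L)$site_differences), 0L)

  ## 3 consecutive only-in-a sites form one candidate region
  b <- mkCalls(40L, "G", "b")
  res <- compareSamples(a, b, 3L)
  expect_equal(res$site_differences$status, rep("only_a", 3L))
  expect_equal(res$candidate_regions,
               data.frame(chrom = "ref", start = 10L, end = 30L,
                          n_sites = 3L))

  ## same alt at same position is not a difference and breaks runs
  c2 <- mkCalls(c(10L, 20L, 30L, 40L), c("G", "T", "G", "G"))
  res2 <- compareSamples(a, c2, 1L)
  expect_equal(res2$site_differences$pos, 20L)
  expect_equal(res2$site_differences$status, "allele_mismatch")

  ## a shared identical call inside a run splits it below the window
  d <- mkCalls(20L, "G", "b")
  res3 <- compareSamples(a, d, 3L)
  expect_equal(nrow(res3$candidate_regions), 0L)
  res4 <- compareSamples(a, d, 1L)
  expect_equal(res4$candidate_regions$n_sites, c(1L, 2L))
})

test_that("planted SNPs are recovered from simulated alignments end to end", {
  sim <- simulateReads(refLength = 1500L, readLength = 80L, meanDepth = 25,
                       snps = data.frame(pos = c(300L, 700L, 1100L),
                                         alt = NA,
                                         fraction = c(1, 1, 0.5)),
                       errorRate = 0.001, seed = 77)
  pre <- tempfile()
  writeSimulatedReads(sim, pre)
  cols <- pileupColumns(paste0(pre, ".sam"), "ref", 1, 1500,
                        ref = paste0(pre, ".fa"))
  calls <- callSnps(cols, 5L, 0.2, "s1")
  expect_true(all(sim$truth$snps$pos %in% calls$pos))
  hom <- calls[calls$pos %in% c(300L, 700L), ]
  expect_true(all(hom$alt_fraction > 0.9))
  expect_equal(calls$alt[match(sim$truth$snps$pos, calls$pos)],
               sim$truth$snps$alt)
  ## few spurious calls at this error rate
  expect_lte(nrow(calls), 6L)
  unlink(Sys.glob(paste0(pre, "*")))
})
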