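test_that("madUnscaled matches hand-computed medians of deviations", {
  expect_equal(madUnscaled(c(1, 1, 2, 2, 4)), 1.0)
  expect_equal(madUnscaled(c(3, 3, 3)), 0.0)
  ## deviations from the median 5 are 4,3,2,1,0,1,2,3,4; their median is 2
  expect_equal(madUnscaled(1:9), 2.0)
  ## even length: median is the mean of the central order statistics
  expect_equal(madUnscaled(c(1, 2, 3, 10)), 1.0)
  expect_error(madUnscaled(numeric()), "empty")
})

test_that("swIslands reports run-start to first-argmax islands", {
  expect_equal(nrow(swIslands(c(-1, -0.5, -2))), 0L)
  expect_equal(nrow(swIslands(numeric())), 0L)
  expect_equal(swIslands(2.0),
               data.frame(start = 1L, end = 1L, score = 2.0))
  ## brute-force best subarray over indices 1..3 sums to 1.1
  isl <- swIslands(c(0.5, -0.2, 0.8, -1.0, 0.3))
  expect_equal(isl, data.frame(start = 1L, end = 3L, score = 1.1))
  ## two separated positive runs give two islands, left to right
  isl2 <- swIslands(c(1, -5, 2))
  expect_equal(isl2$start, c(1L, 3L))
  expect_equal(isl2$score, c(1, 2))
  ## a score of exactly 0 ends the run, giving two islands
  isl3 <- swIslands(c(1, -1, 1))
  expect_equal(isl3, data.frame(start = c(1L, 3L), end = c(1L, 3L),
                                score = c(1, 1)))
  ## within a run, argmax ties break leftmost: S = 2, 1, 2
  isl4 <- swIslands(c(2, -1, 1))
  expect_equal(isl4, data.frame(start = 1L, end = 1L, score = 2))
})

test_that("top island score equals the brute-force subarray maximum", {
  set.seed(42)
  for (rep in 1:200) {
    s <- runif(sample(1:60, 1L), -1, 1)
    best <- bruteMaxSubarray(s)
    isl <- swIslands(s)
    if (best > 0) {
      expect_equal(max(isl$score), best, tolerance = 1e-12)
    } else {
      expect_equal(nrow(isl), 0L)
    }
  }
})

test_that("detectCnv reproduces the hand-worked gain example", {
  x <- makeAcgh(c(0.1, -0.1, 1.0, 1.1, 0.9, 0.0, -0.2))
  ## median 0.1, MAD 0.3, gain threshold 0.4, island over probes 3..5
  seg <- detectCnv(x, "s1", "chr1", CnvParams(1, 2L, "gain"))
  expect_length(seg, 1L)
  mc <- S4Vectors::mcols(seg)
  expect_equal(mc$first_probe, 3L)
  expect_equal(mc$last_probe, 5L)
  expect_equal(mc$n_probes, 3L)
  expect_equal(mc$sw_score, 1.8, tolerance = 1e-12)
  expect_equal(mc$segmental_mean, 1.0, tolerance = 1e-12)
  expect_equal(GenomicRanges::start(seg), 201L)  # probe 3 starts at 201
  expect_equal(GenomicRanges::end(seg), 460L)    # probe 5 ends at 460

  ## island block length above the island size suppresses it
  expect_length(detectCnv(x, "s1", "chrom" = "chr1", CnvParams(1, 4L, "gain")), 0L)

  ## constant profile: degenerate dispersion unless absThreshold overrides
  flat <- makeAcgh(rep(0.2, 6))
  expect_error(detectCnv(flat, "s1", "chr1", CnvParams(1, 2L, "gain")),
               "degenerate dispersion")
  expect_length(
    detectCnv(flat, "s1", "chr1",
              CnvParams(1, 2L, "gain", absThreshold = 0.5)), 0L)
})

test_that("gain/loss detection is symmetric under negation", {
  set.seed(7)
  vals <- rnorm(80, 0, 0.2)
  vals[30:41] <- vals[30:41] + 1
  vals[60:66] <- vals[60:66] - 0.9
  p <- CnvParams(2, 3L, "both")
  a <- detectCnv(makeAcgh(vals), "s1", "chr1", p)
  b <- detectCnv(makeAcgh(-vals), "s1", "chr1", p)
  expect_equal(length(a), length(b))
  swap <- c(gain = "loss", loss = "gain")
  ma <- S4Vectors::mcols(a); mb <- S4Vectors::mcols(b)
  ord <- order(GenomicRanges::start(b))
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b)[ord])
  expect_equal(unname(swap[ma$type]), mb$type[ord])
  expect_equal(ma$sw_score, mb$sw_score[ord], tolerance = 1e-9)
  expect_equal(ma$segmental_mean, -mb$segmental_mean[ord], tolerance = 1e-9)
  expect_equal(ma$n_probes, mb$n_probes[ord])
})

test_that("missing probes are excised without breaking islands", {
  vals <- c(0, 0.05, 1, NA, 1.1, 0.9, 0.02, -0.05, 0.04, -0.03)
  seg <- detectCnv(makeAcgh(vals), "s1", "chr1", CnvParams(2, 3L, "gain"))
  expect_length(seg, 1L)
  mc <- S4Vectors::mcols(seg)
  ## probe indices refer to the full chromosome order; the NA probe is
  ## inside the island span but does not count toward probe support
  expect_equal(mc$first_probe, 3L)
  expect_equal(mc$last_probe, 6L)
  expect_equal(mc$n_probes, 3L)
  expect_equal(mc$segmental_mean, mean(c(1, 1.1, 0.9)), tolerance = 1e-12)
})

test_that("detectAll covers samples x chromosomes and collects issues", {
  sim <- simulateAcgh(
    c(chr1 = 60, chr2 = 60), noiseSd = 0.15, nSamples = 2L,
    events = data.frame(chrom = c("chr1", "chr2"),
                        first_probe = c(10, 30), last_probe = c(21, 41),
                        delta = c(1, -1), sample = "sample_1"),
    seed = 5)
  segs <- suppressWarnings(detectAll(sim$acgh, CnvParams(3, 5L, "both")))
  mc <- S4Vectors::mcols(segs)
  s1 <- segs[mc$sample == "sample_1"]
  expect_equal(sort(as.character(GenomicRanges::seqnames(s1))),
               c("chr1", "chr2"))
  expect_setequal(S4Vectors::mcols(s1)$type, c("gain", "loss"))
  expect_equal(nrow(S4Vectors::metadata(segs)$issues), 0L)

  ## an all-flat dataset yields no segments, all pairs degenerate
  flat <- makeAcgh(matrix(0, 20, 2))
  expect_warning(res <- detectAll(flat, CnvParams(3, 5L, "both")),
                 "skipped")
  expect_length(res, 0L)
  expect_equal(nrow(S4Vectors::metadata(res)$issues), 2L)
  expect_match(S4Vectors::metadata(res)$issues$message[1L], "degenerate")
})

test_that("stricter parameters never increase the segment count", {
  for (s in 1:8) {
    sim <- simulateAcgh(
      c(chr1 = 150), noiseSd = 0.15,
      events = data.frame(chrom = "chr1", first_probe = 40,
                          last_probe = 51, delta = 1),
      seed = 400 + s)
    counts_k <- vapply(c(1, 2, 3), function(k)
      length(suppressWarnings(detectAll(sim$acgh, CnvParams(k, 4L, "both")))),
      numeric(1L))
    expect_true(all(diff(counts_k) <= 0))
    segsByL <- lapply(c(2L, 5L, 8L), function(L)
      suppressWarnings(detectAll(sim$acgh, CnvParams(2, L, "both"))))
    expect_true(all(diff(lengths(segsByL)) <= 0))
    ## larger L only filters: every stricter segment is one of the looser ones
    looser <- segsByL[[1L]]; stricter <- segsByL[[3L]]
    if (length(stricter)) {
      ml <- S4Vectors::mcols(looser); ms <- S4Vectors::mcols(stricter)
      for (i in seq_along(stricter))
        expect_true(any(ml$first_probe == ms$first_probe[i] &
                        ml$last_probe == ms$last_probe[i] &
                        ml$sample == ms$sample[i]))
    }
  }
})

test_that("segmentMatrix applies the half-coverage bin rule", {
  seg <- segGrFromDf(data.frame(chrom = "chr1",
                                start = c(201L, 1001L), end = c(500L, 1039L)))
  S4Vectors::mcols(seg)$type <- c("gain", "loss")
  sm <- segmentMatrix(seg, "chr1", binSize = 100L)
  ## gain covers bins 3-5 fully; the 39-bp loss covers <50% of bin 11
  expect_equal(unname(sm$matrix["s1", 3:5]), rep("gain", 3))
  expect_equal(unname(sm$matrix["s1", 11L]), "neutral")
  expect_equal(sum(sm$matrix == "gain"), 3L)
  expect_equal(length(sm$bins), ncol(sm$matrix))

  ## two samples with disjoint segments differ exactly at their own bins
  seg2 <- suppressWarnings(c(
    segGrFromDf(data.frame(chrom = "chr1", start = 1L, end = 200L), "a"),
    segGrFromDf(data.frame(chrom = "chr1", start = 401L, end = 600L), "b")))
  sm2 <- segmentMatrix(seg2, "chr1", binSize = 100L)
  expect_equal(unname(sm2$matrix["a", ]),
               c("gain", "gain", rep("neutral", 4)))
  expect_equal(unname(sm2$matrix["b", ]),
               c(rep("neutral", 4), "gain", "gain"))

  ## overlapping gain and loss in one bin flags a conflict
  seg3 <- segGrFromDf(data.frame(chrom = "chr1",
                                 start = c(1L, 1L), end = c(100L, 100L)))
  S4Vectors::mcols(seg3)$type <- c("gain", "loss")
  sm3 <- segmentMatrix(seg3, "chr1", binSize = 100L)
  expect_equal(unname(sm3$matrix["s1", 1L]), "conflict")
})
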