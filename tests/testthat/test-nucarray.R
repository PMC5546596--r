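test_that("nuc-array curve matches the brute-force oracle", {
  # single delta
  x1 <- numeric(1000); x1[500] <- 5
  # phased deltas every 194 bp plus scattered background
  x2 <- numeric(2000)
  x2[seq(200, 1800, by = 194)] <- 8
  set.seed(9)
  x2[sample.int(2000, 60)] <- x2[sample.int(2000, 60)] + 1
  # random counts
  set.seed(10)
  x3 <- rpois(1500, 0.05)
  for (x in list(x1, x2, x3)) {
    got <- nuc_array_curve(x)$curve$chr1
    want <- brute_nucarray(x)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a single center delta yields marked maxima flanking the center", {
  x <- numeric(1000); x[500] <- 5
  # the |dS| profile of a Gaussian bump has two symmetric lobes (the
  # derivative extrema at about +/- sd from the center) and a zero at the
  # center itself
  s <- mnaseqc:::smooth_zeropad(x, mnaseqc:::gaussian_kernel(73L, 30))
  d <- abs(diff(s))
  lobes <- which(d == max(d))
  expect_true(any(lobes < 500) && any(lobes > 500))
  expect_lt(d[500], max(d))
  expect_lte(abs((500 - min(lobes)) - (max(lobes) - 500)), 1)
  # connecting the two equal lobes makes the curve flat at the lobe height
  nac <- nuc_array_curve(x, normalize = FALSE)
  v <- nac$curve$chr1
  expect_equal(max(v), max(d))
  expect_equal(v[500], max(d))
})

test_that("the fold curve has genome-wide mean 1; all-zero input is safe", {
  set.seed(4)
  x <- rpois(3000, 0.1)
  nac <- nuc_array_curve(x)
  expect_equal(mean(nac$curve$chr1), 1, tolerance = 1e-9)
  expect_warning(z <- nuc_array_curve(numeric(500)), "all-zero")
  expect_warning(segs <- detect_arrays(z), "not normalized")
  expect_length(segs, 0L)
})

test_that("array segmentation applies strict length and fold thresholds", {
  v <- rep(1, 3000)
  v[1001:1700] <- 3          # 700-bp run above fold 2
  nac <- make_nucarray(v)
  segs <- detect_arrays(nac)
  expect_length(segs, 1L)
  expect_equal(start(segs), 1001L)
  expect_equal(end(segs), 1700L)
  expect_equal(S4Vectors::mcols(segs)$nuc_array_value, 3)
  # a run of exactly 600 bp is rejected (strictly greater required)
  v600 <- rep(1, 3000); v600[1001:1600] <- 3
  expect_warning(expect_length(detect_arrays(make_nucarray(v600)), 0L))
  # one sub-threshold bp splits a run into two segments (no merging)
  v2 <- rep(1, 3000)
  v2[101:800] <- 3; v2[801] <- 1.5; v2[802:1501] <- 3
  segs2 <- detect_arrays(make_nucarray(v2))
  expect_length(segs2, 2L)
  expect_equal(start(segs2), c(101L, 802L))
})

test_that("every emitted segment satisfies the published filters", {
  fx <- simulate_barrier_fixture(chrom_length = 3e5, n_sites = 6L,
                                 n_reads = 3e4, seed = 12)
  ctr <- build_center_profile(to_fragments(fx$sim$reads))
  nac <- nuc_array_curve(ctr)
  segs <- detect_arrays(nac)
  expect_gt(length(segs), 0L)
  expect_true(all(width(segs) > 600))
  expect_true(all(S4Vectors::mcols(segs)$nuc_array_value > 2))
  # recompute each segment mean from the curve itself
  for (i in seq_along(segs)) {
    expect_equal(S4Vectors::mcols(segs)$nuc_array_value[i],
                 mean(nac$curve$chr1[start(segs)[i]:end(segs)[i]]))
  }
})

test_that("phased centers raise the curve over random centers", {
  set.seed(30)
  x <- numeric(4000)
  phased <- seq(1100, 2900, by = 194)           # phased span [1000, 3000]
  x[phased] <- 20                               # 10 x 20 = 200 reads
  rnd <- sample(3001:4000, 200, replace = TRUE) # equal count, random span
  x[3001:4000] <- tabulate(rnd, 4000)[3001:4000]
  nac <- nuc_array_curve(x, normalize = FALSE)
  expect_gt(positioning_score_region(nac, "chr1", 1000, 3000),
            positioning_score_region(nac, "chr1", 3001, 4000))
})

test_that("positioning score of a region is the curve mean over it", {
  nac <- make_nucarray(rep(2.5, 1000), genome_mean = 4, normalized = TRUE)
  expect_equal(positioning_score_region(nac, "chr1", 101, 400,
                                        scale = "fold"), 2.5)
  expect_equal(positioning_score_region(nac, "chr1", 101, 400,
                                        scale = "raw"), 10)
  expect_error(positioning_score_region(nac, "chr1", 900, 1100), "bounds")
})

test_that("raising the phased fraction never lowers the span score", {
  ctrs <- data.frame(chrom = "chr1", center = seq(5100, 7000, by = 194))
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  for (s in 1:10) {
    v <- vapply(fracs, function(f) {
      sim <- simulate_reads(c(chr1 = 20000), 4000, "single",
                            positioning_fraction = f, phased_centers = ctrs,
                            jitter_sd = 10, seed = s)
      nac <- nuc_array_curve(build_center_profile(to_fragments(sim$reads)),
                             normalize = FALSE)
      positioning_score_region(nac, "chr1", 5000, 7100)
    }, numeric(1))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("enrichment fold follows the observed/expected definition", {
  sl <- c(chr1 = 1e6)
  segs <- GRanges("chr1", IRanges(seq(1000, 9100, by = 900), width = 700),
                  seqlengths = sl)  # 10 segments within [0, 10000)
  regions <- GRanges("chr1", IRanges(1, width = 10000), seqlengths = sl)
  en <- enrichment_fold(segs, regions, 1e6)
  expect_equal(en$observed_proportion, 1)
  expect_equal(en$expected_proportion, 0.01)
  expect_equal(en$fold, 100)
  # no overlap -> fold 0; DHS judgment Fail
  far <- GRanges("chr1", IRanges(5e5, width = 700), seqlengths = sl)
  en0 <- enrichment_fold(far, regions, 1e6, region_set_name = "union_DHS")
  expect_equal(en0$fold, 0)
  expect_equal(en0$judgment, "Fail")
  # empty segment set: fold undefined, Fail with reason
  skip <- enrichment_fold(mnaseqc:::empty_segments(), regions, 1e6,
                          region_set_name = "union_DHS")
  expect_true(is.na(skip$fold))
  expect_equal(skip$judgment, "Fail")
  expect_error(enrichment_fold(segs, GRanges(), 1e6), "zero length")
})

test_that("uniformly placed segments give enrichment fold near 1", {
  sl <- c(chr1 = 1e6)
  regions <- GRanges("chr1", IRanges(seq(1, 1e6 - 5e4, by = 5e4),
                                     width = 1e4), seqlengths = sl)
  folds <- vapply(1:50, function(s) {
    set.seed(s)
    segs <- GRanges("chr1",
                    IRanges(sample.int(1e6 - 700L, 200), width = 700),
                    seqlengths = sl)
    enrichment_fold(segs, regions, 1e6)$fold
  }, numeric(1))
  # observed overlap probability for a 700-bp segment slightly exceeds the
  # per-bp expectation; the null fold stays near 1
  expect_lt(abs(mean(folds) - 1), 0.15)
})

test_that("gene annotation sums promoter overlaps with a -1 sentinel", {
  sl <- c(chr1 = 1e5)
  tss <- GRanges("chr1", IRanges(c(3001, 50001), width = 1),
                 strand = c("+", "-"), seqlengths = sl)
  mcols(tss)$transcript_id <- c("txA", "txB")
  # promoter A (0-based [0, 6000)): one segment overlapping 900 bp
  segs <- GRanges("chr1", IRanges(501, 1400), seqlengths = sl)
  ann <- annotate_genes(segs, tss)
  expect_equal(S4Vectors::mcols(ann)$score, c(900, -1))
  expect_equal(S4Vectors::mcols(ann)$name, c("txA", "txB"))
  # two segments on one promoter: overlaps add up
  segs2 <- GRanges("chr1", IRanges(c(101, 1001), width = c(200, 300)),
                   seqlengths = sl)
  ann2 <- annotate_genes(segs2, tss)
  expect_equal(S4Vectors::mcols(ann2)$score[1], 500)
})

test_that("downstream promoters extend 3 kb in the direction of the gene", {
  sl <- c(chr1 = 1e5)
  tss <- GRanges("chr1", IRanges(c(10001, 50000), width = 1),
                 strand = c("+", "-"), seqlengths = sl)
  dp <- downstream_promoters(tss)
  expect_equal(start(dp), c(10001L, 47001L))
  expect_equal(end(dp), c(13000L, 50000L))
  expect_equal(width(dp), c(3000L, 3000L))
})
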