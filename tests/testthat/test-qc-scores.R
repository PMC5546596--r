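test_that("sequencing coverage follows the 194-bp formula exactly", {
  expect_equal(sequencing_coverage(0, 2.7e9)$coverage, 0)
  # inverting the formula: n = G/194 reads gives 1-fold coverage
  n <- 2.7e9 / 194
  expect_equal(sequencing_coverage(n, 2.7e9)$coverage, 1.0)
  # linearity
  c1 <- sequencing_coverage(1.5e7, 1.87e9)$coverage
  c2 <- sequencing_coverage(3e7, 1.87e9)$coverage
  expect_identical(c2, 2 * c1)
  expect_error(sequencing_coverage(100, 0), "> 0")
})

test_that("dinucleotide frequency reads footprints 5'->3' on their strand", {
  # all-A genome: AA everywhere
  gA <- make_genome(chr1 = strrep("A", 2000))
  rd <- make_reads("chr1", start = c(101L, 401L), width = 36L, strand = "+",
                   chrom_len = 2000, mapq = 60L)
  cv <- dinuc_frequency(to_fragments(rd), gA)
  expect_equal(cv$position, 4:143)
  expect_true(all(cv$frequency == 1))
  # ACGT repeats: dinucleotides AC, CG, GT, TA only
  gR <- make_genome(chr1 = strrep("ACGT", 500))
  cvR <- dinuc_frequency(to_fragments(rd), gR)
  expect_true(all(cvR$frequency == 0))
  # minus-strand footprints are reverse-complemented: over an all-T genome
  # a minus read sees all-A, so the frequency is 1 either way (AA vs TT),
  # while a C/G-alternating genome stays at 0
  gT <- make_genome(chr1 = strrep("T", 2000))
  rdm <- make_reads("chr1", start = 301L, width = 36L, strand = "-",
                    chrom_len = 2000)
  expect_true(all(dinuc_frequency(to_fragments(rdm), gT)$frequency == 1))
  # footprints overrunning the chromosome end are excluded
  short <- make_genome(chr1 = strrep("A", 150))
  rdo <- make_reads("chr1", start = c(2L, 30L), width = 36L, strand = "+",
                    chrom_len = 150)
  cvo <- dinuc_frequency(suppressMessages(to_fragments(rdo)), short)
  expect_equal(attr(cvo, "n_footprints"), 1L)
  expect_error(dinuc_frequency(to_fragments(
    make_reads("chr1", start = 100L, width = 36L, chrom_len = 2000)),
    make_genome(chr2 = strrep("A", 500))), "no usable footprints")
})

test_that("periodic AA planting produces period-10 spikes in the curve", {
  g <- simulate_periodic_genome(20000, period = 10, phase = 0, seed = 5)
  # reads phase-locked to the planted comb (starts on the 10-bp grid)
  rd <- make_reads("chr1", start = seq(1L, 19000L, by = 30L), width = 36L,
                   strand = "+", chrom_len = 20000)
  cv <- dinuc_frequency(to_fragments(rd), g)
  planted <- cv$frequency[cv$position %% 10 == 1]
  rest <- cv$frequency[cv$position %% 10 != 1]
  expect_true(min(planted) > max(rest))
})

test_that("rotational score isolates the 10-bp spectral bin", {
  p <- 4:143
  pure10 <- 0.3 + 0.1 * cos(2 * pi * p / 10)
  r10 <- rotational_score(pure10)
  expect_equal(r10$rotational_score, 1.0, tolerance = 1e-10)
  expect_equal(r10$judgment, "Pass")
  expect_equal(r10$dominant_period, 10)
  expect_warning(r0 <- rotational_score(rep(0.25, 140)), "constant")
  expect_equal(r0$rotational_score, 0)
  expect_equal(r0$judgment, "Fail")
  pure20 <- 0.3 + 0.1 * cos(2 * pi * p / 20)
  r20 <- rotational_score(pure20)
  expect_lt(r20$rotational_score, 1e-10)
  expect_equal(r20$judgment, "Fail")
  expect_equal(r20$dominant_period, 20)
})

test_that("rotational score is invariant to affine rescaling of the curve", {
  set.seed(7)
  f <- 0.3 + 0.05 * cos(2 * pi * (4:143) / 10) + rnorm(140, 0, 0.01)
  s0 <- rotational_score(f)$rotational_score
  expect_equal(rotational_score(f + 0.2)$rotational_score, s0)
  expect_equal(rotational_score(3.5 * f)$rotational_score, s0)
  expect_equal(rotational_score(2 * f + 1)$rotational_score, s0)
})

test_that("periodic genomes outscore uniform genomes across 50 seeds", {
  starts <- seq(1L, 9800L, by = 30L)
  wins <- vapply(1:50, function(s) {
    gp <- simulate_periodic_genome(10000, period = 10, seed = s)
    gu <- simulate_random_genome(10000, seed = s + 500)
    rd <- make_reads("chr1", start = starts, width = 36L, strand = "+",
                     chrom_len = 10000)
    fp <- to_fragments(rd)
    rotational_score(dinuc_frequency(fp, gp))$rotational_score >
      rotational_score(dinuc_frequency(fp, gu))$rotational_score
  }, logical(1))
  expect_gte(sum(wins), 49)
})

test_that("fragment-length estimation matches paired and single-end rules", {
  # paired, all template lengths 147 -> 147, Pass
  pr <- make_reads("chr1", start = 1000L + (0:99) * 50L, width = 147L,
                   strand = "*", chrom_len = 10000, read_mode = "paired",
                   is_paired = TRUE, template_length = 147L)
  fl <- estimate_fragment_length(pr)
  expect_equal(fl$estimated_length, 147)
  expect_equal(fl$judgment, "Pass")
  # paired, all 120 -> Fail (over-digestion)
  pr120 <- make_reads("chr1", start = 1000L + (0:99) * 50L, width = 120L,
                      strand = "*", chrom_len = 10000, read_mode = "paired",
                      is_paired = TRUE, template_length = 120L)
  fl120 <- estimate_fragment_length(pr120)
  expect_equal(fl120$estimated_length, 120)
  expect_equal(fl120$judgment, "Fail")
  # single-end reads planted as exact footprint ends 147 apart
  nuc_starts <- 500L + (0:49) * 200L
  plus <- make_reads("chr1", start = nuc_starts, width = 36L, strand = "+",
                     chrom_len = 20000)
  minus <- make_reads("chr1", start = nuc_starts + 147L - 36L, width = 36L,
                      strand = "-", chrom_len = 20000)
  rd <- suppressWarnings(c(plus, minus))
  S4Vectors::metadata(rd) <- list(read_mode = "single")
  fls <- estimate_fragment_length(rd, read_mode = "single")
  expect_equal(fls$estimated_length, 147)
  expect_equal(fls$judgment, "Pass")
  expect_error(estimate_fragment_length(plus, read_mode = "single"),
               "insufficient reads")
})

test_that("the start-to-end histogram matches brute-force pair enumeration", {
  set.seed(21)
  n <- 80
  starts <- sample.int(3000L, n) + 100L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  rd <- make_reads("chr1", start = starts, width = 36L, strand = strands,
                   chrom_len = 5000)
  got <- mnaseqc:::start_to_end_histogram(rd, 250L)
  # brute force: every (plus, minus) pair, distance = minus 5' - plus 5' + 1
  p5 <- starts[strands == "+"]
  m5 <- starts[strands == "-"] + 35L
  want <- integer(250)
  for (s in p5) for (e in m5) {
    d <- e - s + 1L
    if (d >= 1 && d <= 250) want[d] <- want[d] + 1L
  }
  expect_equal(got, want)
})

test_that("single-end estimator recovers planted lengths 120/147/180", {
  ctrs <- data.frame(chrom = "chr1", center = seq(500, 99500, by = 194))
  for (L in c(120L, 147L, 180L)) {
    s <- simulate_reads(c(chr1 = 1e5), 20000, "single",
                        fragment_length = L, positioning_fraction = 1,
                        phased_centers = ctrs, jitter_sd = 5, seed = L)
    fl <- estimate_fragment_length(s$reads, read_mode = "single")
    expect_equal(fl$estimated_length, L)
  }
})
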