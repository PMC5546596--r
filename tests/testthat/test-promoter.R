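test_that("region matrix bins occupancy around anchors with strand flips", {
  # one fragment centered at TSS+100: occupancy on [TSS+64, TSS+137) 0-based
  L <- 10000L
  tss0 <- 5000L  # 0-based TSS
  rd <- make_reads("chr1", start = tss0 + 100L - 73L + 1L, width = 36L,
                   strand = "+", chrom_len = L)
  fp <- to_fragments(rd)
  expect_equal(fragment_centers(fp), tss0 + 100L + 1L)
  occ <- build_occupancy(fp)
  tss <- GRanges("chr1", IRanges(tss0 + 1L, width = 1L), strand = "+",
                 seqlengths = c(chr1 = L))
  mcols(tss)$transcript_id <- "txA"
  rm <- region_matrix(occ, tss)
  nz <- which(rm$matrix[1, ] > 0)
  # occupied bins cover relative offsets [64, 137): bins 107..114 of 300
  expect_equal(nz, 107:114)
  expect_equal(sum(rm$matrix[1, ]), 73)
  # a minus-strand TSS with the fragment at TSS-100 mirrors to the same bins
  rdm <- make_reads("chr1", start = tss0 - 100L - 73L + 1L, width = 36L,
                    strand = "+", chrom_len = L)
  occm <- build_occupancy(to_fragments(rdm))
  tssm <- tss
  strand(tssm) <- "-"
  rmm <- region_matrix(occm, tssm)
  expect_equal(which(rmm$matrix[1, ] > 0), 107:114)
  expect_equal(rmm$matrix[1, nz], rm$matrix[1, nz])
})

test_that("region matrix rows are sorted by within-region signal", {
  L <- 10000L
  rd <- make_reads("chr1",
                   start = c(rep(1001L, 5), rep(7001L, 9)), width = 36L,
                   strand = "+", chrom_len = L)
  occ <- build_occupancy(to_fragments(rd))
  tss <- GRanges("chr1", IRanges(c(1101L, 7101L), width = 1L),
                 strand = "+", seqlengths = c(chr1 = L))
  mcols(tss)$transcript_id <- c("low", "high")
  rm <- region_matrix(occ, tss)
  expect_equal(rownames(rm$matrix), c("high", "low"))
  expect_equal(rm$row_order, c(2L, 1L))
})

test_that("aggregate smoothing preserves constants, mass, and cuts variance", {
  pos <- seq(-995, 1995, by = 10)
  const <- rep(2.5, length(pos))
  cv <- aggregate_and_smooth(const, positions = pos)
  expect_equal(cv$smoothed, const)
  spike <- numeric(length(pos)); spike[150] <- 10
  cs <- aggregate_and_smooth(spike, positions = pos)
  expect_equal(sum(cs$smoothed), sum(spike), tolerance = 0.01)
  expect_lt(max(cs$smoothed), 10)
  set.seed(3)
  noise <- rnorm(length(pos))
  cn <- aggregate_and_smooth(noise, positions = pos)
  expect_lt(var(cn$smoothed), var(cn$raw))
})

test_that("landmark detection finds NFR, -1/+1 and downstream peaks", {
  cv <- simulate_promoter_curve(noise_sd = 0, peak_spacing = 190)
  lm <- find_landmarks(cv)
  expect_true(lm$ok)
  expect_lt(abs(lm$pos_nfr - (-50)), 15)
  expect_lt(abs(lm$pos_minus1 - (-215)), 15)
  expect_lt(abs(lm$pos_plus1 - 65), 15)
  expect_length(lm$downstream_peaks, 4L)
  expect_true(all(diff(lm$downstream_peaks) > 0))
  expect_lt(lm$pos_nfr, lm$pos_plus1)
  expect_lt(lm$pos_minus1, lm$pos_nfr)
  # degenerate curves hit the error path
  pos <- seq(-995, 1995, by = 10)
  mono <- aggregate_and_smooth(seq_along(pos) * 0.01, positions = pos)
  expect_false(find_landmarks(mono)$ok)
  flat <- aggregate_and_smooth(rep(1, length(pos)), positions = pos)
  expect_false(find_landmarks(flat)$ok)
})

test_that("NFR score matches the range-normalized formula", {
  # +1/-1 at the maximum, NFR at the minimum -> 1
  lm1 <- make_landmarks(c(65, 259, 453, 647), s_plus1 = 1, s_minus1 = 1,
                        s_nfr = 0, s_range = c(0, 1))
  expect_equal(nfr_score(lm1)$nfr_score, 1.0)
  expect_equal(nfr_score(lm1)$judgment, "Pass")
  # all equal -> 0
  lm0 <- make_landmarks(c(65, 259, 453, 647), s_plus1 = 0.5, s_minus1 = 0.5,
                        s_nfr = 0.5, s_range = c(0, 1))
  expect_equal(nfr_score(lm0)$nfr_score, 0)
  # hand-computed: (mean(0.8, 0.6) - 0.2) / 1 = 0.5
  lmh <- make_landmarks(c(65, 259, 453, 647), s_plus1 = 0.8, s_minus1 = 0.6,
                        s_nfr = 0.2, s_range = c(0, 1))
  expect_equal(nfr_score(lmh)$nfr_score, 0.5)
  expect_equal(nfr_score(lmh, numerator = "sum")$nfr_score, 1.2)
})

test_that("NFR score is invariant to affine rescaling of the signal", {
  lm <- make_landmarks(c(65, 259, 453, 647), s_plus1 = 0.8, s_minus1 = 0.6,
                       s_nfr = 0.2, s_range = c(0.1, 1.1))
  base <- nfr_score(lm)$nfr_score
  a <- 3.2; b <- 0.7
  lm2 <- make_landmarks(c(65, 259, 453, 647), s_plus1 = a * 0.8 + b,
                        s_minus1 = a * 0.6 + b, s_nfr = a * 0.2 + b,
                        s_range = a * c(0.1, 1.1) + b)
  expect_equal(nfr_score(lm2)$nfr_score, base)
})

test_that("positioning score is the population CV of the peak spacings", {
  # equal 194-bp spacing -> 0, Pass
  eq <- make_landmarks(c(65, 259, 453, 647))
  ps <- positioning_score(eq)
  expect_equal(ps$positioning_score, 0)
  expect_equal(ps$judgment, "Pass")
  # spacings {100, 200, 300}: population SD 81.65 / mean 200 = 0.408, Fail
  un <- make_landmarks(c(0, 100, 300, 600))
  pu <- positioning_score(un)
  expect_equal(pu$positioning_score, sqrt(20000 / 3) / 200,
               tolerance = 1e-12)
  expect_equal(round(pu$positioning_score, 3), 0.408)
  expect_equal(pu$judgment, "Fail")
  # spacings {180, 190, 200} -> ~0.0430, Pass
  ok <- make_landmarks(c(0, 180, 370, 570))
  po <- positioning_score(ok)
  expect_equal(po$positioning_score, sqrt(200 / 3) / 190, tolerance = 1e-12)
  expect_equal(round(po$positioning_score, 4), 0.043)
  expect_equal(po$judgment, "Pass")
  # invariance: translation and common scaling of the peaks
  sh <- make_landmarks(c(0, 100, 300, 600) + 500)
  expect_equal(positioning_score(sh)$positioning_score,
               pu$positioning_score)
  sc <- make_landmarks(c(0, 100, 300, 600) * 2.5)
  expect_equal(positioning_score(sc)$positioning_score,
               pu$positioning_score)
  # fewer than four peaks: undefined, Fail with reason
  few <- make_landmarks(c(65, 259, 453))
  few$downstream_peaks <- c(65, 259, 453)
  pf <- positioning_score(few)
  expect_true(is.na(pf$positioning_score))
  expect_equal(pf$judgment, "Fail")
})

test_that("good promoter fixture passes; shuffling destroys the NFR signal", {
  cv <- simulate_promoter_curve(noise_sd = 0.01, seed = 2)
  lm <- find_landmarks(cv)
  expect_gte(nfr_score(lm)$nfr_score, 0.4)
  expect_lte(positioning_score(lm)$positioning_score, 0.4)
  # shuffling the aggregate curve drops the expected NFR score well below
  # the pass cutoff (mean over 20 shuffles), and below the intact score
  shuffled <- vapply(1:20, function(s) {
    set.seed(s)
    sc <- aggregate_and_smooth(sample(cv$raw), positions = cv$position)
    nfr_score(find_landmarks(sc))$nfr_score
  }, numeric(1))
  expect_lt(mean(shuffled, na.rm = TRUE), 0.4)
  expect_lt(mean(shuffled, na.rm = TRUE), nfr_score(lm)$nfr_score)
})

test_that("promoter positioning noise sweep is monotone in expectation", {
  levels <- c(0, 0.005, 0.02, 0.05)
  mean_cv <- vapply(levels, function(ns) {
    mean(vapply(1:20, function(s) {
      cv <- simulate_promoter_curve(noise_sd = ns, seed = s,
                                    peak_spacing = 190)
      p <- positioning_score(find_landmarks(cv))$positioning_score
      if (is.na(p)) 1 else p
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cv) >= 0))
})
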