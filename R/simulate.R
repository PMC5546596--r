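#' Simulate the perfect-positioning / no-positioning region
#'
#' The coverage simulation design: a 1200-bp region with five potential
#' nucleosome centers spaced 194 bp apart (the nucleosomal + linker repeat
#' length). Simulated reads are 1-bp reads marking nucleosome centers. In
#' the perfect-positioning region reads are assigned evenly to the five
#' centers, each with a uniform perturbation of up to 5 bp; in the
#' no-positioning region reads land uniformly over the region with the
#' same perturbation. The read count for a coverage fold uses the region
#' length in place of the effective genome size, so 1-fold means one
#' 194-bp-repeat pass over the region.
#'
#' @param coverage Coverage fold of the region.
#' @param kind `"perfect"` or `"none"`.
#' @param region_length Region length in bp (default 1200).
#' @param n_centers Number of potential nucleosome centers (5).
#' @param center_spacing Spacing between adjacent centers in bp (194).
#' @param perturbation Maximum perturbation in bp, uniform on
#'   `-perturbation..perturbation` (5).
#' @param repeat_length Repeat length for the coverage-to-read-count
#'   conversion (194).
#' @param seed Integer seed.
#' @return A list of class `mn_possim`: `positions` (1-based 1-bp read
#'   positions), `centers` (the marked centers), `n_reads`, `kind`,
#'   `region_length`.
#' @export
simulate_positioning_region <- function(coverage, kind = c("perfect", "none"),
                                        region_length = 1200L, n_centers = 5L,
                                        center_spacing = 194L,
                                        perturbation = 5L,
                                        repeat_length = 194L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(coverage > 0)
  span <- (n_centers - 1L) * center_spacing
  stopifnot(span < region_length)
  first <- (region_length - span) %/% 2L
  centers <- first + (seq_len(n_centers) - 1L) * center_spacing
  n_reads <- max(1L, round(coverage * region_length / repeat_length))
  positions <- with_seed(seed, {
    jitter <- sample(seq(-perturbation, perturbation), n_reads,
                     replace = TRUE)
    base <- if (kind == "perfect") {
      per <- rep(n_reads %/% n_centers, n_centers)
      extra <- n_reads - sum(per)
      if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
      rep(centers, per)
    } else {
      sample.int(region_length, n_reads, replace = TRUE)
    }
    pmin(pmax(base + jitter, 1L), region_length)
  })
  structure(list(positions = positions, centers = centers,
                 n_reads = n_reads, kind = kind,
                 region_length = region_length),
            class = "mn_possim")
}

#' Per-bp center counts of simulated 1-bp reads
#'
#' @param sim An `mn_possim`, or an integer vector of positions.
#' @param region_length Region length (taken from the simulation object
#'   when omitted).
#' @return Numeric vector of per-bp counts.
#' @export
center_counts <- function(sim, region_length = NULL) {
  if (inherits(sim, "mn_possim")) {
    region_length <- sim$region_length
    sim <- sim$positions
  }
  stopifnot(!is.null(region_length))
  as.numeric(tabulate(sim, nbins = region_length))
}

#' Simulate a genome with planted dinucleotide periodicity
#'
#' Builds an i.i.d. random-base genome and overwrites a motif (AA, TT or
#' AT) at every position congruent to `phase` modulo `period`, emulating
#' the ~10-bp rotational periodicity of nucleosomal DNA. Planting happens
#' after the background draw, so the planted phases are never disturbed.
#'
#' @param length Genome length in bp.
#' @param period Planting period in bp (default 10).
#' @param motif `"AA"`, `"TT"` or `"AT"`.
#' @param phase 0-based phase of the planted starts within the period.
#' @param base_prob Background base probabilities for A, C, G, T.
#' @param chrom Chromosome name (default `"chr1"`).
#' @param seed Integer seed.
#' @return An `mn_genome`.
#' @export
simulate_periodic_genome <- function(length, period = 10L,
                                     motif = c("AA", "TT", "AT"),
                                     phase = 0L,
                                     base_prob = rep(0.25, 4),
                                     chrom = "chr1", seed = 1L) {
  motif <- match.arg(motif)
  stopifnot(length >= period)
  chars <- with_seed(seed,
    sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = base_prob))
  mchars <- strsplit(motif, "")[[1]]
  starts <- seq(phase + 1L, length - 1L, by = period)
  chars[starts] <- mchars[1]
  chars[starts + 1L] <- mchars[2]
  seq <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(seq) <- chrom
  structure(list(seq = seq,
                 chrom_lengths = stats::setNames(length, chrom)),
            class = "mn_genome")
}

#' Simulate a uniform-base genome with no planted periodicity
#'
#' @inheritParams simulate_periodic_genome
#' @return An `mn_genome`.
#' @export
simulate_random_genome <- function(length, base_prob = rep(0.25, 4),
                                   chrom = "chr1", seed = 1L) {
  chars <- with_seed(seed,
    sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = base_prob))
  seq <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(seq) <- chrom
  structure(list(seq = seq,
                 chrom_lengths = stats::setNames(length, chrom)),
            class = "mn_genome")
}

#' Simulate MNase-seq reads from planted nucleosome positions
#'
#' Draws fragments whose centers come either from a set of planted
#' (phased) nucleosome centers, with Gaussian jitter controlling
#' positioning strength, or from a uniform background over the
#' chromosomes. Fragment length is a point mass or a discretized normal.
#' Single-end mode emits one read per fragment (random strand, 5' end at
#' the fragment boundary, so extending 147 bp in the 3' direction
#' recovers a footprint centered on the planted center when the fragment
#' length is 147). Paired mode records the whole fragment with its
#' template length.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_reads Number of fragments to draw.
#' @param read_mode `"single"` or `"paired"`.
#' @param fragment_length Scalar point mass, or `c(mean, sd)` for a
#'   discretized normal (minimum 40 bp).
#' @param positioning_fraction Share of fragments drawn from the planted
#'   centers (0..1); the rest are uniform background.
#' @param phased_centers A data.frame with columns `chrom` and `center`
#'   (1-based) of planted nucleosome centers; required when
#'   `positioning_fraction > 0`.
#' @param jitter_sd Standard deviation in bp of the Gaussian jitter
#'   applied to planted centers (positioning strength; smaller = tighter).
#' @param read_length Sequenced read length in bp for single-end reads and
#'   SAM output (default 36).
#' @param mapq MAPQ assigned to simulated reads (default 60).
#' @param seed Integer seed.
#' @return A list of class `mn_simreads`: `reads` (a `GRanges` shaped like
#'   [load_alignments()] output) and `truth` (planted centers, per-read
#'   origin flags, fragment lengths, parameters).
#' @export
simulate_reads <- function(chrom_lengths, n_reads,
                           read_mode = c("single", "paired"),
                           fragment_length = 147,
                           positioning_fraction = 0,
                           phased_centers = NULL, jitter_sd = 15,
                           read_length = 36L, mapq = 60L, seed = 1L) {
  read_mode <- match.arg(read_mode)
  stopifnot(positioning_fraction >= 0, positioning_fraction <= 1,
            n_reads >= 1, !is.null(names(chrom_lengths)))
  if (positioning_fraction > 0 && is.null(phased_centers)) {
    stop("phased_centers required when positioning_fraction > 0")
  }
  out <- with_seed(seed, {
    n_phased <- round(positioning_fraction * n_reads)
    n_bg <- n_reads - n_phased
    chrom <- character(0); ctr <- integer(0); phased <- logical(0)
    if (n_phased > 0) {
      i <- sample.int(nrow(phased_centers), n_phased, replace = TRUE)
      chrom <- as.character(phased_centers$chrom)[i]
      ctr <- as.integer(round(phased_centers$center[i] +
                                stats::rnorm(n_phased, 0, jitter_sd)))
      phased <- rep(TRUE, n_phased)
    }
    if (n_bg > 0) {
      ci <- sample.int(length(chrom_lengths), n_bg, replace = TRUE,
                       prob = chrom_lengths / sum(chrom_lengths))
      chrom <- c(chrom, names(chrom_lengths)[ci])
      ctr <- c(ctr, as.integer(ceiling(stats::runif(n_bg) *
                                         unname(chrom_lengths[ci]))))
      phased <- c(phased, rep(FALSE, n_bg))
    }
    flen <- if (length(fragment_length) == 1) {
      rep(as.integer(fragment_length), n_reads)
    } else {
      pmax(40L, as.integer(round(stats::rnorm(n_reads, fragment_length[1],
                                              fragment_length[2]))))
    }
    # clamp centers so the whole fragment fits on the chromosome
    half_lo <- flen %/% 2L
    half_hi <- flen - half_lo
    L <- unname(chrom_lengths[chrom])
    ctr <- pmin(pmax(ctr, half_lo + 1L), L - half_hi + 1L)
    s1 <- ctr - half_lo              # 1-based fragment start
    e1 <- s1 + flen - 1L             # 1-based fragment end
    str <- sample(c("+", "-"), n_reads, replace = TRUE)
    list(chrom = chrom, s1 = s1, e1 = e1, flen = flen, strand = str,
         phased = phased)
  })
  sl <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  if (read_mode == "paired") {
    gr <- GenomicRanges::GRanges(
      out$chrom, IRanges::IRanges(out$s1, out$e1), strand = "*",
      seqlengths = sl)
    S4Vectors::mcols(gr)$template_length <- out$flen
    S4Vectors::mcols(gr)$is_paired <- TRUE
  } else {
    rs <- ifelse(out$strand == "+", out$s1, out$e1 - read_length + 1L)
    gr <- GenomicRanges::GRanges(
      out$chrom, IRanges::IRanges(rs, width = read_length),
      strand = out$strand, seqlengths = sl)
    S4Vectors::mcols(gr)$template_length <- NA_integer_
    S4Vectors::mcols(gr)$is_paired <- FALSE
  }
  S4Vectors::mcols(gr)$mapq <- as.integer(mapq)
  S4Vectors::mcols(gr)$read_id <- sprintf("sim_%d", seq_along(gr))
  S4Vectors::metadata(gr) <- list(n_input_records = length(gr),
                                  n_skipped = 0L, read_mode = read_mode)
  structure(list(
    reads = gr,
    truth = list(phased = out$phased, fragment_start = out$s1,
                 fragment_end = out$e1, fragment_length = out$flen,
                 phased_centers = phased_centers,
                 positioning_fraction = positioning_fraction,
                 jitter_sd = jitter_sd, seed = seed)),
    class = "mn_simreads")
}

#' Simulate a phased-array fixture with barrier sites
#'
#' Plants `n_sites` barrier sites on one chromosome; downstream of each
#' site, nucleosome centers are phased every `spacing` bp across
#' `site_span` bp (the barrier-adjacent array). A `positioning_fraction`
#' share of the reads comes from those centers, the rest is uniform
#' background, so array detection should recover the barrier-adjacent
#' spans and the enrichment judgment over the barrier regions should
#' pass; with `positioning_fraction = 0` the fixture is a pure null.
#'
#' @param chrom_length Chromosome length in bp (default 1e6).
#' @param n_sites Number of barrier sites (default 20).
#' @param site_span Phased span downstream of each site in bp (1500).
#' @param spacing Nucleosome repeat within an array in bp (194).
#' @param offset First center's offset from the site in bp (100).
#' @param n_reads Total reads (default 1e5).
#' @param positioning_fraction Share of reads from the phased centers
#'   (default 0.5).
#' @param jitter_sd Center jitter in bp (default 15).
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A list of class `mn_barrier_fixture`: `sim` (an `mn_simreads`),
#'   `barrier_regions` (`GRanges` of the phased spans), `centers`,
#'   `chrom_lengths`.
#' @export
simulate_barrier_fixture <- function(chrom_length = 1e6, n_sites = 20L,
                                     site_span = 1500L, spacing = 194L,
                                     offset = 100L, n_reads = 1e5,
                                     positioning_fraction = 0.5,
                                     jitter_sd = 15, chrom = "chr1",
                                     seed = 1L) {
  stopifnot(n_sites >= 1, site_span > spacing)
  # evenly spread sites, away from the chromosome ends
  gap <- chrom_length %/% (n_sites + 1L)
  sites <- gap * seq_len(n_sites)
  ks <- seq(0L, site_span - offset - 1L, by = spacing)
  centers <- data.frame(
    chrom = chrom,
    center = as.vector(outer(sites, offset + ks, `+`)))
  sim <- simulate_reads(
    chrom_lengths = stats::setNames(chrom_length, chrom),
    n_reads = n_reads, read_mode = "single",
    positioning_fraction = positioning_fraction,
    phased_centers = centers, jitter_sd = jitter_sd, seed = seed)
  regions <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = sites + 1L, width = site_span),
    seqlengths = stats::setNames(as.integer(chrom_length), chrom))
  structure(list(sim = sim, barrier_regions = regions, centers = centers,
                 chrom_lengths = stats::setNames(chrom_length, chrom)),
            class = "mn_barrier_fixture")
}

#' Simulate a parametric promoter aggregate curve
#'
#' Deterministic stand-in for a TSS aggregate profile: a baseline with a
#' nucleosome-depleted trough at -50 bp, a -1 nucleosome crest upstream of
#' it, and `n_peaks` downstream crests starting at +65 bp spaced
#' `peak_spacing` bp apart, plus optional additive Gaussian noise. Used to
#' exercise promoter landmark detection and both promoter scores under
#' controlled conditions.
#'
#' @param nfr_depth Depth of the trough (default 0.5; the trough is the
#'   curve minimum for depths comparable to the crest amplitude).
#' @param peak_spacing Downstream crest spacing in bp (default 194).
#' @param n_peaks Number of downstream crests (>= 4 for the positioning
#'   score).
#' @param noise_sd Additive noise standard deviation (default 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param window Window in bp relative to the TSS (default
#'   `c(-1000, 2000)`).
#' @param bin Bin width in bp (default 10).
#' @param bandwidth Smoothing bandwidth in bins for the returned smoothed
#'   column (default 3).
#' @param baseline,crest_height Baseline level and crest amplitude.
#' @param feature_sd Width (sd, bp) of the Gaussian crests and trough.
#' @return An `mn_curve` data.frame (`position`, `raw`, `smoothed`).
#' @export
simulate_promoter_curve <- function(nfr_depth = 0.5, peak_spacing = 194,
                                    n_peaks = 4L, noise_sd = 0, seed = 1L,
                                    window = c(-1000L, 2000L), bin = 10L,
                                    bandwidth = 3, baseline = 0.6,
                                    crest_height = 0.4, feature_sd = 40) {
  stopifnot(n_peaks >= 1)
  n_bins <- (window[2] - window[1]) %/% bin
  pos <- window[1] + (seq_len(n_bins) - 0.5) * bin
  crests <- c(-215, 65 + (seq_len(n_peaks) - 1) * peak_spacing)
  y <- rep(baseline, n_bins)
  for (ck in crests) {
    y <- y + crest_height * exp(-(pos - ck)^2 / (2 * feature_sd^2))
  }
  y <- y - nfr_depth * exp(-(pos + 50)^2 / (2 * feature_sd^2))
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(n_bins, 0, noise_sd))
  }
  aggregate_and_smooth(y, bandwidth = bandwidth, positions = pos)
}

#' Write simulated reads as SAM
#'
#' Emits a minimal SAM file (header with the simulated chromosome lengths,
#' one line per single-end read or two proper-pair lines per fragment) that
#' round-trips through [load_alignments()].
#'
#' @param sim An `mn_simreads` from [simulate_reads()].
#' @param path Output path.
#' @param read_length Read length for the CIGAR/SEQ fields (default 36).
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path, read_length = 36L) {
  stopifnot(inherits(sim, "mn_simreads"))
  gr <- sim$reads
  sl <- GenomeInfoDb::seqlengths(gr)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  mapq <- S4Vectors::mcols(gr)$mapq
  id <- S4Vectors::mcols(gr)$read_id
  seqf <- strrep("N", read_length)
  cig <- paste0(read_length, "M")
  if (isTRUE(S4Vectors::mcols(gr)$is_paired[1])) {
    s1 <- GenomicRanges::start(gr)
    e1 <- GenomicRanges::end(gr)
    tlen <- e1 - s1 + 1L
    p2 <- e1 - read_length + 1L
    lines <- c(
      sprintf("%s\t99\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t*",
              id, chrom, s1, mapq, cig, p2, tlen, seqf),
      sprintf("%s\t147\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t*",
              id, chrom, p2, mapq, cig, s1, -tlen, seqf))
  } else {
    flag <- ifelse(as.character(GenomicRanges::strand(gr)) == "-", 16L, 0L)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     id, flag, chrom, GenomicRanges::start(gr), mapq, cig,
                     seqf)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write simulated single-end reads as BED6
#'
#' @param sim An `mn_simreads` (single-end).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_reads <- function(sim, path) {
  stopifnot(inherits(sim, "mn_simreads"))
  gr <- sim$reads
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = S4Vectors::mcols(gr)$read_id,
                   score = S4Vectors::mcols(gr)$mapq,
                   strand = as.character(GenomicRanges::strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the simulation truth record as JSON lines
#'
#' One JSON object per planted quantity, sufficient to recompute every
#' planted feature independently of the pipeline.
#'
#' @param sim An `mn_simreads`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "mn_simreads"))
  tr <- sim$truth
  lines <- c(
    jsonlite::toJSON(list(record = "params",
                          positioning_fraction = tr$positioning_fraction,
                          jitter_sd = tr$jitter_sd, seed = tr$seed),
                     auto_unbox = TRUE),
    jsonlite::toJSON(list(record = "phased_centers",
                          centers = tr$phased_centers), auto_unbox = TRUE),
    jsonlite::toJSON(list(record = "fragments",
                          start = tr$fragment_start, end = tr$fragment_end,
                          length = tr$fragment_length, phased = tr$phased),
                     auto_unbox = TRUE))
  writeLines(lines, path)
  invisible(path)
}
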