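#' Sequencing coverage of an MNase-seq sample
#'
#' Coverage (fold) = (number of reads x 194 bp) / effective genome size,
#' where 194 bp is the nucleosomal + linker DNA repeat length and the read
#' count is the number of mappable reads after MAPQ filtering (single-end)
#' or the number of fragments (paired-end).
#'
#' @param n_reads Mappable read (or fragment) count.
#' @param effective_genome_size Effective genome size in bp; see
#'   [effective_genome_size()].
#' @param repeat_length Nucleosome repeat length in bp (default 194).
#' @return A list of class `mn_coverage` with the inputs and the `coverage`
#'   fold value (unrounded).
#' @examples
#' sequencing_coverage(1e7, effective_genome_size("hg19"))
#' @export
sequencing_coverage <- function(n_reads, effective_genome_size,
                                repeat_length = 194) {
  stopifnot(n_reads >= 0)
  if (!is.numeric(effective_genome_size) || effective_genome_size <= 0) {
    stop("effective genome size must be > 0")
  }
  structure(list(n_reads = n_reads, repeat_length = repeat_length,
                 effective_genome_size = effective_genome_size,
                 coverage = n_reads * repeat_length / effective_genome_size),
            class = "mn_coverage")
}

#' Aggregate AA/TT/AT dinucleotide frequency along the footprint
#'
#' For every 147-bp footprint the genomic sequence is read 5' to 3' on the
#' read's strand (reverse-complemented for minus-strand reads), and for each
#' position p in 4..143 the fraction of footprints whose dinucleotide at
#' (p, p+1) is AA, TT or AT is recorded. Nucleosomal DNA shows a ~10-bp
#' periodicity in this curve when reads truly cover rotationally positioned
#' nucleosomes. Footprints overrunning a chromosome end are excluded;
#' positions containing N are excluded for that footprint only.
#'
#' @param fragments Footprint `GRanges` from [to_fragments()] (downsample
#'   the reads beforehand for large samples; the published cap is 10 M).
#' @param genome An `mn_genome`.
#' @param positions Integer positions scored within the footprint
#'   (1-based; default 4:143).
#' @return A data.frame of class `mn_dinuc_curve` with columns `position`
#'   and `frequency`, and attribute `n_footprints`.
#' @export
dinuc_frequency <- function(fragments, genome, positions = 4:143) {
  stopifnot(inherits(genome, "mn_genome"))
  L <- S4Vectors::metadata(fragments)$footprint_length
  if (is.null(L)) L <- 147L
  stopifnot(all(positions >= 1), all(positions < L))
  chroms <- as.character(GenomicRanges::seqnames(fragments))
  known <- chroms %in% names(genome$seq)
  inb <- known
  inb[known] <- GenomicRanges::start(fragments)[known] >= 1L &
    GenomicRanges::end(fragments)[known] <=
      genome$chrom_lengths[chroms[known]]
  fragments <- fragments[inb]
  if (length(fragments) == 0) stop("no usable footprints for the dinucleotide curve")
  chroms <- chroms[inb]
  chr_order <- intersect(names(genome$seq), unique(chroms))
  strand <- as.character(GenomicRanges::strand(fragments))
  seqs <- do.call(c, lapply(chr_order, function(chr) {
    i <- chroms == chr
    Biostrings::extractAt(
      genome$seq[[chr]],
      IRanges::IRanges(GenomicRanges::start(fragments)[i],
                       GenomicRanges::end(fragments)[i]))
  }))
  minus <- unlist(lapply(chr_order, function(chr) strand[chroms == chr] == "-"),
                  use.names = FALSE)
  if (any(minus)) {
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  }
  m <- as.matrix(seqs)
  freq <- vapply(positions, function(p) {
    a <- m[, p]
    b <- m[, p + 1L]
    usable <- a != "N" & b != "N"
    if (!any(usable)) return(NA_real_)
    hit <- (a == "A" & b == "A") | (a == "T" & b == "T") |
      (a == "A" & b == "T")
    sum(hit & usable) / sum(usable)
  }, numeric(1))
  structure(data.frame(position = positions, frequency = freq),
            class = c("mn_dinuc_curve", "data.frame"),
            n_footprints = length(fragments))
}

#' Rotational score: spectral energy at the 10-bp period
#'
#' The dinucleotide frequency curve is mean-centered and its discrete
#' Fourier power spectrum computed; the rotational score is the power in
#' the frequency bin nearest 0.1 cycles/bp divided by the total power over
#' the positive-frequency half spectrum, so a pure 10-bp cosine scores 1.
#' Samples with scores above the cutoff (0.08) pass; the cutoff derives
#' from the distribution over a historical reference atlas.
#'
#' @param curve An `mn_dinuc_curve` (or numeric frequency vector).
#' @param period Target period in bp (default 10).
#' @param cutoff Pass threshold (default 0.08).
#' @return A list of class `mn_rotational` with the `rotational_score`, the
#'   power `spectrum` (data.frame `period_bp`, `power`), the
#'   `dominant_period` among non-DC bins, `judgment` and `cutoff`.
#' @export
rotational_score <- function(curve, period = 10, cutoff = 0.08) {
  f <- if (is.data.frame(curve)) curve$frequency else as.numeric(curve)
  f <- f[!is.na(f)]
  n <- length(f)
  if (n < 4) stop("dinucleotide curve too short for a spectrum")
  x <- f - mean(f)
  if (all(x == 0)) {
    warning("constant dinucleotide curve: rotational score 0")
    return(structure(list(rotational_score = 0, spectrum = NULL,
                          dominant_period = NA_real_, judgment = "Fail",
                          cutoff = cutoff),
                     class = "mn_rotational"))
  }
  pw <- Mod(stats::fft(x))^2
  k <- seq_len(n %/% 2)                       # positive-frequency bins
  half <- pw[k + 1L]
  target <- k[which.min(abs(k / n - 1 / period))]
  score <- half[target] / sum(half)
  spectrum <- data.frame(period_bp = n / k, power = half)
  structure(list(rotational_score = score, spectrum = spectrum,
                 dominant_period = n / k[which.max(half)],
                 judgment = if (score > cutoff) "Pass" else "Fail",
                 cutoff = cutoff),
            class = "mn_rotational")
}

#' @export
print.mn_rotational <- function(x, ...) {
  cat("Rotational score:", format(x$rotational_score, digits = 4),
      paste0("(", x$judgment, ", cutoff ", x$cutoff, ")"), "\n")
  invisible(x)
}

#' Estimate the nucleosomal DNA length
#'
#' Paired-end: the template-length distribution of all mappable fragments.
#' Single-end: reads are deduplicated, then for every plus-strand 5' end
#' the distances to all minus-strand 5' ends within 250 bp downstream on
#' the same chromosome (the start-to-end distance) are histogrammed. In
#' both modes the estimated nucleosomal DNA length is the distribution
#' mode; estimates within 140-155 bp pass (shorter indicates
#' over-digestion, longer partial digestion). Ties in the mode are resolved
#' toward 147 bp.
#'
#' @param reads Reads `GRanges` (single-end) or fragment `GRanges`
#'   (paired-end, `template_length` column).
#' @param read_mode `"single"` or `"paired"`; defaults to the recorded mode.
#' @param max_distance Single-end search window in bp (default 250).
#' @param pass_range Pass interval in bp (default `c(140, 155)`).
#' @param params [preprocess_params()]; supplies the downsampling cap and
#'   seed for the single-end path.
#' @return A list of class `mn_fraglen`: `length_distribution` (data.frame
#'   `length`, `count`), `estimated_length`, `judgment`, `pass_range`.
#' @export
estimate_fragment_length <- function(reads, read_mode = NULL,
                                     max_distance = 250L,
                                     pass_range = c(140L, 155L),
                                     params = preprocess_params()) {
  if (is.null(read_mode)) read_mode <- S4Vectors::metadata(reads)$read_mode
  read_mode <- match.arg(read_mode, c("single", "paired"))
  if (read_mode == "paired") {
    tl <- S4Vectors::mcols(reads)$template_length
    if (is.null(tl)) tl <- GenomicRanges::width(reads)
    tl <- tl[!is.na(tl) & tl > 0]
    if (length(tl) == 0) stop("insufficient reads: no template lengths")
    counts <- tabulate(tl)
    dist <- data.frame(length = seq_along(counts), count = counts)
  } else {
    reads <- deduplicate(reads)
    reads <- downsample(reads, params$downsample_n, seed = params$rng_seed)
    counts <- start_to_end_histogram(reads, max_distance)
    if (sum(counts) == 0) {
      stop("insufficient reads: empty start-to-end distance histogram")
    }
    dist <- data.frame(length = seq_len(max_distance), count = counts)
  }
  est <- argmax_near(dist$count, dist$length, target = 147)
  structure(list(
    length_distribution = dist,
    estimated_length = est,
    judgment = if (est >= pass_range[1] && est <= pass_range[2])
      "Pass" else "Fail",
    pass_range = pass_range, read_mode = read_mode),
    class = "mn_fraglen")
}

# Histogram of distances from plus-strand 5' ends to minus-strand 5' ends
# within (0, max_distance] downstream, per chromosome.
start_to_end_histogram <- function(reads, max_distance = 250L) {
  counts <- integer(max_distance)
  strand <- as.character(GenomicRanges::strand(reads))
  chroms <- as.character(GenomicRanges::seqnames(reads))
  for (chr in unique(chroms)) {
    i <- chroms == chr
    p <- sort(GenomicRanges::start(reads)[i & strand == "+"])
    m <- GenomicRanges::end(reads)[i & strand == "-"]
    if (length(p) == 0 || length(m) == 0) next
    # for each minus-strand 5' end e, plus starts s with 1 <= e-s+1 <= max
    lo <- findInterval(m - max_distance, p) + 1L
    hi <- findInterval(m, p)
    n <- hi - lo + 1L
    ok <- n > 0L
    if (!any(ok)) next
    idx <- sequence(n[ok], from = lo[ok])
    d <- rep(m[ok], n[ok]) - p[idx] + 1L
    counts <- counts + tabulate(d[d >= 1L & d <= max_distance], max_distance)
  }
  counts
}

#' @export
print.mn_fraglen <- function(x, ...) {
  cat("Estimated nucleosomal DNA length:", x$estimated_length, "bp",
      paste0("(", x$judgment, ", pass range ", x$pass_range[1], "-",
             x$pass_range[2], " bp)"), "\n")
  invisible(x)
}
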