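# Fixtures are built in code at test time; nothing binary is stored.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# A reads GRanges shaped like load_alignments() output.
make_reads <- function(chrom, start, width = 36L, strand = "+", mapq = 60L,
                       chrom_len = NULL, read_mode = "single",
                       is_paired = FALSE, template_length = NA_integer_) {
  n <- length(start)
  gr <- if (n == 0) {
    g <- GRanges()
    seqlevels(g) <- unique(chrom)
    mcols(g) <- DataFrame(mapq = integer(0), read_id = character(0),
                          is_paired = logical(0),
                          template_length = integer(0))
    if (!is.null(chrom_len)) {
      seqlengths(g) <- setNames(as.integer(chrom_len), seqlevels(g))
    }
    metadata(g) <- list(n_input_records = 0L, n_skipped = 0L,
                        read_mode = read_mode)
    return(g)
  } else {
    GRanges(rep(chrom, length.out = n),
            IRanges(start = start, width = width),
            strand = rep(strand, length.out = n))
  }
  if (!is.null(chrom_len)) {
    seqlengths(gr) <- setNames(as.integer(chrom_len),
                               seqlevels(gr))
  }
  mcols(gr)$mapq <- rep(as.integer(mapq), length.out = n)
  mcols(gr)$read_id <- paste0("r", seq_len(n))
  mcols(gr)$is_paired <- rep(is_paired, length.out = n)
  mcols(gr)$template_length <- rep(as.integer(template_length),
                                   length.out = n)
  metadata(gr) <- list(n_input_records = n, n_skipped = 0L,
                       read_mode = read_mode)
  gr
}

# An mn_genome directly from character sequences (no file round trip).
make_genome <- function(...) {
  seqs <- c(...)
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  structure(list(seq = ss,
                 chrom_lengths = setNames(Biostrings::width(ss), names(seqs))),
            class = "mn_genome")
}

# Hand-written SAM text for I/O tests.
write_test_sam <- function(lines, chrom_lengths = c(chr1 = 10000L),
                           path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      chrom_lengths))
  writeLines(c(header, lines), path)
  path
}

# An mn_landmarks object built directly, for score-formula tests.
make_landmarks <- function(downstream_peaks, s_plus1 = 1, s_minus1 = 1,
                           s_nfr = 0, s_range = c(0, 1),
                           pos_minus1 = -200, pos_nfr = -50) {
  structure(list(ok = TRUE, reason = NULL,
                 pos_plus1 = downstream_peaks[1], pos_minus1 = pos_minus1,
                 pos_nfr = pos_nfr, downstream_peaks = downstream_peaks,
                 s_plus1 = s_plus1, s_minus1 = s_minus1, s_nfr = s_nfr,
                 s_range = s_range),
            class = "mn_landmarks")
}

# An mn_nucarray built directly from a fold curve.
make_nucarray <- function(v, genome_mean = 1, normalized = TRUE) {
  structure(list(curve = list(chr1 = as.numeric(v)),
                 genome_mean = genome_mean, normalized = normalized,
                 params = array_params()),
            class = "mn_nucarray")
}

# Independent brute-force nuc-array curve: explicit convolution loop,
# exhaustive windowed max, explicit interpolation. Used only as an oracle.
brute_nucarray <- function(x, hw_s = 73L, sd = 30, hw_m = 73L,
                           normalize = TRUE) {
  L <- length(x)
  w <- exp(-((-hw_s):hw_s)^2 / (2 * sd^2))
  w <- w / sum(w)
  S <- numeric(L)
  for (i in seq_len(L)) {
    acc <- 0
    for (j in (-hw_s):hw_s) {
      k <- i + j
      if (k >= 1 && k <= L) acc <- acc + x[k] * w[j + hw_s + 1]
    }
    S[i] <- acc
  }
  M <- L - 1L
  D <- numeric(M)
  for (i in seq_len(M)) D[i] <- abs(S[i + 1] - S[i])
  marked <- integer(0)
  for (i in seq_len(M)) {
    lo <- max(1L, i - hw_m)
    hi <- min(M, i + hw_m)
    if (D[i] > 0 && D[i] == max(D[lo:hi])) {
      if (length(marked) > 0) {
        last <- marked[length(marked)]
        if (i - last <= hw_m && D[i] == D[last]) next
      }
      marked <- c(marked, i)
    }
  }
  curve <- numeric(L)
  if (length(marked) == 0) return(curve)
  for (i in seq_len(M)) {
    if (i <= marked[1]) {
      curve[i] <- D[marked[1]]
    } else if (i >= marked[length(marked)]) {
      curve[i] <- D[marked[length(marked)]]
    } else {
      b <- min(which(marked >= i))
      a <- b - 1L
      ia <- marked[a]; ib <- marked[b]
      curve[i] <- D[ia] + (D[ib] - D[ia]) * (i - ia) / (ib - ia)
    }
  }
  curve[L] <- curve[M]
  if (normalize && mean(curve) > 0) curve <- curve / mean(curve)
  curve
}

# End-to-end "good sample": phased nucleosome arrays up- and downstream of
# TSS-like barrier sites on a 10-bp-periodic genome, fragment length 147.
make_good_sample <- function(chrom_len = 2e5, n_sites = 20L, spacing = 190L,
                             n_down = 8L, n_up = 3L, n_reads = 40000L,
                             frac = 0.6, jitter = 2, flen = 147, seed = 1L) {
  gap <- chrom_len %/% (n_sites + 1L)
  sites <- (gap %/% 10L) * 10L * seq_len(n_sites)  # on the 10-bp grid
  down <- as.vector(outer(sites, 100 + (0:(n_down - 1)) * spacing, `+`))
  up <- as.vector(outer(sites, -(100 + (0:(n_up - 1)) * spacing), `+`))
  sim <- simulate_reads(c(chr1 = chrom_len), n_reads, "single",
                        fragment_length = flen,
                        positioning_fraction = frac,
                        phased_centers = data.frame(
                          chrom = "chr1", center = c(down, up)),
                        jitter_sd = jitter, seed = seed)
  genome <- simulate_periodic_genome(chrom_len, period = 10, seed = seed + 7)
  list(sim = sim, genome = genome, sites = sites, chrom_len = chrom_len)
}

write_good_sample_files <- function(gs, dir = tempfile("goodsample")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sam <- file.path(dir, "reads.sam")
  write_sam(gs$sim, sam)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(gs$genome$seq, fa)
  tss <- file.path(dir, "tss.bed")
  utils::write.table(
    data.frame("chr1", gs$sites, gs$sites + 1L,
               paste0("tx", seq_along(gs$sites)), 0L, "+"),
    tss, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  dhs <- file.path(dir, "dhs.bed")
  utils::write.table(
    data.frame("chr1", gs$sites, gs$sites + 1600L),
    dhs, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  list(sam = sam, fa = fa, tss = tss, dhs = dhs, dir = dir)
}
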