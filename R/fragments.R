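#' Default preprocessing parameters
#'
#' Constants of the method: nucleosomal footprint length 147 bp, occupancy
#' core = the middle 73 bp of the footprint (center +/- 36 bp), MAPQ cutoff
#' 30, and a 10-million-read downsampling cap applied to the rotational
#' score and the single-end fragment-length estimator. All are overridable
#' here but the defaults are the published method.
#'
#' @param mapq_cutoff Minimum mapping quality retained (default 30).
#' @param footprint_length Nucleosome footprint length in bp (147).
#' @param core_half_width Half width of the occupancy core (36, giving the
#'   middle 73 bp).
#' @param downsample_n Read cap for the downsampled metrics (1e7).
#' @param rng_seed Pipeline seed; all stochastic steps derive from it.
#' @return A list of class `mn_params`.
#' @export
preprocess_params <- function(mapq_cutoff = 30L, footprint_length = 147L,
                              core_half_width = 36L, downsample_n = 1e7,
                              rng_seed = 1L) {
  stopifnot(footprint_length >= 1, core_half_width >= 0,
            2 * core_half_width < footprint_length, downsample_n > 0)
  structure(list(mapq_cutoff = as.integer(mapq_cutoff),
                 footprint_length = as.integer(footprint_length),
                 core_half_width = as.integer(core_half_width),
                 core_width = 2L * as.integer(core_half_width) + 1L,
                 downsample_n = downsample_n,
                 rng_seed = as.integer(rng_seed)),
            class = "mn_params")
}

#' Filter reads on mapping quality
#'
#' Removes reads with MAPQ below the cutoff (default 30, i.e. quality
#' "less than 30" is removed). Reads with unknown MAPQ (BED input) are kept.
#'
#' @param reads A reads `GRanges` from [load_alignments()].
#' @param mapq_cutoff Minimum MAPQ retained.
#' @return The filtered `GRanges`.
#' @export
filter_mapq <- function(reads, mapq_cutoff = 30L) {
  mq <- S4Vectors::mcols(reads)$mapq
  if (is.null(mq)) mq <- rep(NA_integer_, length(reads))
  keep <- is.na(mq) | mq >= mapq_cutoff
  out <- reads[keep]
  if (length(out) == 0 && length(reads) > 0) {
    warning("no reads remain after MAPQ filtering at cutoff ", mapq_cutoff)
  }
  md <- S4Vectors::metadata(reads)
  md$n_after_mapq <- length(out)
  S4Vectors::metadata(out) <- md
  out
}

#' Remove duplicate reads
#'
#' Single-end duplicates share (chromosome, 5' position, strand); paired
#' fragments are duplicates when the whole fragment interval matches.
#' Used inside the single-end fragment-length estimator; the pipeline
#' applies no global deduplication.
#'
#' @param reads A reads or fragments `GRanges`.
#' @return `GRanges` with at most one record per key.
#' @export
deduplicate <- function(reads) {
  if (length(reads) == 0) return(reads)
  paired <- isTRUE(S4Vectors::mcols(reads)$is_paired[1])
  key <- if (paired) {
    paste(GenomicRanges::seqnames(reads), GenomicRanges::start(reads),
          GenomicRanges::end(reads))
  } else {
    five <- ifelse(as.character(GenomicRanges::strand(reads)) == "-",
                   GenomicRanges::end(reads), GenomicRanges::start(reads))
    paste(GenomicRanges::seqnames(reads), five,
          GenomicRanges::strand(reads))
  }
  out <- reads[!duplicated(key)]
  S4Vectors::metadata(out) <- S4Vectors::metadata(reads)
  out
}

#' Downsample reads without replacement
#'
#' Uniform sampling to at most `n` reads, reproducible for a given seed.
#' Identity when the input is already at or below `n`.
#'
#' @param reads A `GRanges`.
#' @param n Maximum number of reads retained.
#' @param seed Integer seed.
#' @return The (possibly) downsampled `GRanges`, input order preserved.
#' @export
downsample <- function(reads, n, seed = 1L) {
  stopifnot(n > 0)
  if (length(reads) <= n) return(reads)
  idx <- with_seed(seed, sort(sample.int(length(reads), n)))
  out <- reads[idx]
  md <- S4Vectors::metadata(reads)
  md$n_after_downsample <- length(out)
  S4Vectors::metadata(out) <- md
  out
}

#' Transform reads into nucleosome footprints
#'
#' Single-end reads are extended to 147 bp in the 3' direction from their 5'
#' end (plus strand: rightward from the alignment start; minus strand:
#' leftward from the alignment end). Paired-end fragments are replaced by
#' the 147 bp window centered on the fragment center (73 bp on each side,
#' with the extra base downstream of the center so the middle 73 bp stays
#' symmetric). Footprints whose center falls outside the chromosome are
#' dropped and counted.
#'
#' @param reads A filtered reads/fragments `GRanges`.
#' @param read_mode `"single"` or `"paired"`; defaults to the mode recorded
#'   at load time.
#' @param params [preprocess_params()].
#' @return A `GRanges` of footprints (class tag in `metadata()$kind`), each
#'   of width `footprint_length`, with `metadata()` counts carried over.
#' @export
to_fragments <- function(reads, read_mode = NULL, params = preprocess_params()) {
  md <- S4Vectors::metadata(reads)
  if (is.null(read_mode)) read_mode <- md$read_mode
  read_mode <- match.arg(read_mode, c("single", "paired"))
  L <- params$footprint_length
  if (length(reads) == 0) {
    md$kind <- "fragments"
    S4Vectors::metadata(reads) <- md
    return(reads)
  }
  if (read_mode == "single") {
    minus <- as.character(GenomicRanges::strand(reads)) == "-"
    fp_start <- ifelse(minus, GenomicRanges::end(reads) - L + 1L,
                       GenomicRanges::start(reads))
    # footprints may overhang chromosome ends; clipping is handled later
    fp <- suppressWarnings(GenomicRanges::GRanges(
      GenomicRanges::seqnames(reads),
      IRanges::IRanges(start = fp_start, width = L),
      strand = GenomicRanges::strand(reads),
      seqinfo = GenomeInfoDb::seqinfo(reads)))
  } else {
    # fragment center in 0-based coordinates, then the [c-73, c+74) window
    c0 <- (GenomicRanges::start(reads) - 1L + GenomicRanges::end(reads)) %/% 2L
    fp <- suppressWarnings(GenomicRanges::GRanges(
      GenomicRanges::seqnames(reads),
      IRanges::IRanges(start = c0 - (L %/% 2L) + 1L, width = L),
      strand = "*",
      seqinfo = GenomeInfoDb::seqinfo(reads)))
  }
  # drop footprints whose center lies off the chromosome
  sl <- GenomeInfoDb::seqlengths(fp)[as.character(GenomicRanges::seqnames(fp))]
  ctr <- GenomicRanges::start(fp) + (L %/% 2L)
  bad <- ctr < 1L | (!is.na(sl) & ctr > sl)
  if (any(bad)) {
    message(sum(bad), " footprint(s) with center outside chromosome dropped")
    fp <- fp[!bad]
  }
  md$kind <- "fragments"
  md$read_mode <- read_mode
  md$n_fragments <- length(fp)
  md$n_center_dropped <- sum(bad)
  md$footprint_length <- L
  S4Vectors::metadata(fp) <- md
  fp
}

#' Footprint centers (1-based positions)
#'
#' @param fragments Footprint `GRanges` from [to_fragments()].
#' @return Integer vector of center positions.
#' @export
fragment_centers <- function(fragments) {
  L <- S4Vectors::metadata(fragments)$footprint_length
  if (is.null(L)) L <- 147L
  GenomicRanges::start(fragments) + (L %/% 2L)
}
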