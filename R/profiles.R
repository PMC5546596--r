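#' Build the nucleosome occupancy profile
#'
#' Each footprint contributes +1 over the middle 73 bp centered on its
#' footprint center (center +/- 36 bp); the per-base sums over all
#' footprints form the occupancy profile. Mass falling outside chromosome
#' bounds is clipped and accounted for.
#'
#' @param fragments Footprint `GRanges` from [to_fragments()].
#' @param params [preprocess_params()].
#' @return A list of class `mn_profile` with `signal` (an `RleList`, one
#'   run-length-encoded vector per chromosome), `kind = "occupancy"`,
#'   `n_fragments`, `total_mass` and `clipped_mass`.
#' @export
build_occupancy <- function(fragments, params = preprocess_params()) {
  core <- suppressWarnings(
    GenomicRanges::resize(fragments, params$core_width, fix = "center"))
  new_profile(core, kind = "occupancy",
              n_fragments = length(fragments),
              full_mass = as.numeric(params$core_width) * length(fragments))
}

#' Build the nucleosome center profile
#'
#' Per-base counts of footprint centers, the input to well-positioned
#' nucleosome-array detection.
#'
#' @inheritParams build_occupancy
#' @return An `mn_profile` with `kind = "center"`; the genome-wide sum
#'   equals the number of footprints (minus any clipped at chromosome
#'   edges).
#' @export
build_center_profile <- function(fragments, params = preprocess_params()) {
  if (length(fragments) == 0) warning("empty fragment set: all-zero profile")
  ctr <- suppressWarnings(GenomicRanges::resize(fragments, 1L, fix = "center"))
  new_profile(ctr, kind = "center",
              n_fragments = length(fragments),
              full_mass = as.numeric(length(fragments)))
}

new_profile <- function(gr, kind, n_fragments, full_mass) {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (anyNA(sl)) {
    # no declared chromosome lengths: use the observed extent
    obs <- vapply(split(GenomicRanges::end(gr),
                        as.character(GenomicRanges::seqnames(gr))),
                  max, numeric(1))
    sl[names(obs)][is.na(sl[names(obs)])] <- obs[is.na(sl[names(obs)])]
    sl[is.na(sl)] <- 0L
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  gr <- GenomicRanges::trim(gr)
  gr <- gr[GenomicRanges::width(gr) > 0]
  sig <- GenomicRanges::coverage(gr)
  total <- sum(vapply(sig, function(x) sum(as.numeric(S4Vectors::runValue(x)) *
                                             S4Vectors::runLength(x)),
                      numeric(1)))
  structure(list(signal = sig, kind = kind, n_fragments = n_fragments,
                 total_mass = total, clipped_mass = full_mass - total),
            class = "mn_profile")
}

#' @export
print.mn_profile <- function(x, ...) {
  cat("mn_profile (", x$kind, "): ", length(x$signal), " chromosome(s), ",
      x$n_fragments, " fragments, total mass ", format(x$total_mass),
      if (x$clipped_mass > 0) paste0(" (", format(x$clipped_mass),
                                     " clipped at edges)"), "\n", sep = "")
  invisible(x)
}

#' Extract a per-base window of a profile
#'
#' @param profile An `mn_profile`.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed interval. Positions outside the
#'   chromosome are returned as 0.
#' @return Numeric vector of length `end - start + 1`.
#' @export
profile_window <- function(profile, chrom, start, end) {
  stopifnot(inherits(profile, "mn_profile"), start <= end)
  out <- numeric(end - start + 1L)
  if (!chrom %in% names(profile$signal)) return(out)
  x <- profile$signal[[chrom]]
  lo <- max(start, 1L)
  hi <- min(end, length(x))
  if (lo <= hi) {
    out[(lo - start + 1L):(hi - start + 1L)] <-
      as.numeric(S4Vectors::window(x, lo, hi))
  }
  out
}

#' Export a profile as bedGraph
#'
#' Writes the per-base signal as a 0-based half-open bedGraph via
#' rtracklayer; zero runs are omitted.
#'
#' @param profile An `mn_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(profile, path) {
  gr <- methods::as(profile$signal, "GRanges")
  gr <- gr[S4Vectors::mcols(gr)$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
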