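# Base-graphics QC plots. Each returns the input invisibly so they can sit
# at the end of a pipeline call.

#' Plot the AA/TT/AT dinucleotide frequency curve
#'
#' Frequency versus footprint position with 10-bp gridlines, the visual
#' check of rotational positioning.
#'
#' @param curve An `mn_dinuc_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_dinuc_curve <- function(curve, ...) {
  graphics::plot(curve$position, curve$frequency, type = "l",
                 xlab = "position in extended read (bp)",
                 ylab = "AA/TT/AT frequency", ...)
  graphics::abline(v = seq(10, max(curve$position), by = 10),
                   col = "grey85", lty = 3)
  graphics::lines(curve$position, curve$frequency)
  invisible(curve)
}

#' Plot the nucleosomal DNA length distribution
#'
#' Histogram of the length distribution with a vertical line at 147 bp,
#' the canonical mono-nucleosome length.
#'
#' @param fraglen An `mn_fraglen`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_fragment_length <- function(fraglen, ...) {
  d <- fraglen$length_distribution
  graphics::plot(d$length, d$count, type = "h",
                 xlab = "fragment length (bp)", ylab = "count", ...)
  graphics::abline(v = 147, col = "red", lty = 2)
  invisible(fraglen)
}

#' Plot an aggregate nucleosome profile
#'
#' Raw and smoothed aggregate signal around the anchor (TSS or region
#' center).
#'
#' @param curve An `mn_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_aggregate_curve <- function(curve, ...) {
  graphics::plot(curve$position, curve$raw, type = "l", col = "grey60",
                 xlab = "position relative to anchor (bp)",
                 ylab = "mean occupancy", ...)
  graphics::lines(curve$position, curve$smoothed, col = "black", lwd = 2)
  graphics::abline(v = 0, col = "red", lty = 2)
  invisible(curve)
}

#' Heatmap of the region profile matrix
#'
#' Rows (regions, sorted by within-region signal) by binned position,
#' mirroring the promoter/custom-region heatmaps.
#'
#' @param rmat An `mn_region_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_region_heatmap <- function(rmat, ...) {
  m <- rmat$matrix
  graphics::image(x = rmat$positions, y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  xlab = "position relative to anchor (bp)",
                  ylab = "region (sorted by signal)", ...)
  invisible(rmat)
}
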