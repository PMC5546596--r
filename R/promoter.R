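#' Nucleosome profile matrix over anchored windows
#'
#' Bins the occupancy profile into 10-bp bins over a window anchored at each
#' TSS (default -1 kb..+2 kb) or region center (+/-1 kb for custom
#' regions). Rows for minus-strand anchors are column-reversed so that
#' increasing columns always run in the direction of transcription; rows
#' are ordered by the total signal within the window (descending), the
#' order used for the heatmap.
#'
#' @param occupancy An `mn_profile` of kind `"occupancy"`.
#' @param anchors A `GRanges` of TSS (width 1; see [load_tss()]) or custom
#'   regions (anchored at their centers).
#' @param window Integer pair: window relative to the anchor in bp,
#'   0-based-offset half-open (default `c(-1000, 2000)`).
#' @param bin Bin width in bp (default 10); must divide the window evenly.
#' @return A list of class `mn_region_matrix`: `matrix` (rows = anchors in
#'   sorted order, columns = bins), `positions` (bin midpoints relative to
#'   the anchor), `row_order`, `truncated` flags, `window`, `bin`.
#' @export
region_matrix <- function(occupancy, anchors, window = c(-1000L, 2000L),
                          bin = 10L) {
  stopifnot(inherits(occupancy, "mn_profile"))
  span <- window[2] - window[1]
  if (span <= 0 || span %% bin != 0) {
    stop("window must be positive and a multiple of the bin width")
  }
  n_bins <- span %/% bin
  if (length(anchors) == 0) stop("no anchor regions supplied")
  # anchor point: the start for width-1 TSS, else the region center (0-based)
  a0 <- ifelse(GenomicRanges::width(anchors) == 1L,
               GenomicRanges::start(anchors) - 1L,
               (GenomicRanges::start(anchors) - 1L +
                  GenomicRanges::end(anchors)) %/% 2L)
  minus <- as.character(GenomicRanges::strand(anchors)) == "-"
  chroms <- as.character(GenomicRanges::seqnames(anchors))
  mat <- matrix(0, nrow = length(anchors), ncol = n_bins)
  truncated <- logical(length(anchors))
  for (i in seq_along(anchors)) {
    if (minus[i]) {
      lo0 <- a0[i] - window[2] + 1L   # 0-based inclusive
      hi0 <- a0[i] - window[1]
    } else {
      lo0 <- a0[i] + window[1]
      hi0 <- a0[i] + window[2] - 1L
    }
    v <- profile_window(occupancy, chroms[i], lo0 + 1L, hi0 + 1L)
    chr_len <- length(occupancy$signal[[chroms[i]]])
    truncated[i] <- lo0 < 0L || hi0 + 1L > chr_len
    if (minus[i]) v <- rev(v)
    mat[i, ] <- colSums(matrix(v, nrow = bin))
  }
  nm <- S4Vectors::mcols(anchors)$transcript_id
  if (is.null(nm)) nm <- S4Vectors::mcols(anchors)$name
  if (is.null(nm)) nm <- paste0("region_", seq_along(anchors))
  rownames(mat) <- nm
  ord <- order(rowSums(mat), decreasing = TRUE)
  structure(list(matrix = mat[ord, , drop = FALSE],
                 positions = window[1] + (seq_len(n_bins) - 0.5) * bin,
                 row_order = ord, truncated = truncated[ord],
                 window = window, bin = bin),
            class = "mn_region_matrix")
}

#' Aggregate profile with kernel smoothing
#'
#' Column means of the region matrix, smoothed with a normalized Gaussian
#' kernel to remove bin-level noise before landmark detection. Kernel
#' weights are renormalized at the curve ends so a constant curve is left
#' unchanged.
#'
#' @param x An `mn_region_matrix`, or a numeric curve with a matching
#'   `positions` attribute/argument.
#' @param bandwidth Kernel standard deviation in bins (default 3, i.e.
#'   30 bp at 10-bp bins).
#' @param positions Bin midpoints, required when `x` is a bare numeric
#'   vector.
#' @return A data.frame of class `mn_curve`: `position`, `raw`, `smoothed`.
#' @export
aggregate_and_smooth <- function(x, bandwidth = 3, positions = NULL) {
  if (inherits(x, "mn_region_matrix")) {
    raw <- colMeans(x$matrix)
    positions <- x$positions
  } else {
    raw <- as.numeric(x)
    if (is.null(positions)) positions <- attr(x, "positions")
    if (is.null(positions)) stop("positions required for a bare curve")
  }
  kern <- gaussian_kernel(half_width = max(1L, ceiling(3 * bandwidth)),
                          sd = bandwidth)
  structure(data.frame(position = positions, raw = raw,
                       smoothed = smooth_renorm(raw, kern)),
            class = c("mn_curve", "data.frame"))
}

# Strict local extrema of a curve with plateaus collapsed to their leftmost
# bin. Returns indices into `y`.
local_extrema <- function(y) {
  r <- rle(y)
  m <- length(r$values)
  first_idx <- cumsum(c(1L, r$lengths[-m]))
  is_max <- is_min <- logical(m)
  if (m >= 3) {
    j <- 2:(m - 1)
    is_max[j] <- r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
    is_min[j] <- r$values[j] < r$values[j - 1] & r$values[j] < r$values[j + 1]
  }
  list(maxima = first_idx[is_max], minima = first_idx[is_min])
}

#' Locate promoter landmarks on the smoothed aggregate curve
#'
#' Scanning rightward from the TSS, the first strict local maximum is the
#' +1 nucleosome; scanning leftward, the first strict local minimum is the
#' nucleosome-free region (NFR) and the first strict local maximum beyond
#' it is the -1 nucleosome. The +2..+4 nucleosomes are the next three
#' local maxima after +1.
#'
#' @param curve An `mn_curve` spanning the promoter window.
#' @return A list of class `mn_landmarks`: `ok`, `reason`, `pos_plus1`,
#'   `pos_minus1`, `pos_nfr`, `downstream_peaks` (positions of +1..+4),
#'   signal values at the landmarks, and the curve range.
#' @export
find_landmarks <- function(curve) {
  stopifnot(inherits(curve, "mn_curve"))
  pos <- curve$position
  y <- curve$smoothed
  ex <- local_extrema(y)
  fail <- function(reason) {
    structure(list(ok = FALSE, reason = reason, pos_plus1 = NA_real_,
                   pos_minus1 = NA_real_, pos_nfr = NA_real_,
                   downstream_peaks = numeric(0), s_plus1 = NA_real_,
                   s_minus1 = NA_real_, s_nfr = NA_real_,
                   s_range = range(y)),
              class = "mn_landmarks")
  }
  down_max <- ex$maxima[pos[ex$maxima] >= 0]
  if (length(down_max) < 1) return(fail("no downstream local maximum (+1)"))
  plus1 <- down_max[1]
  up_min <- ex$minima[pos[ex$minima] < 0]
  if (length(up_min) < 1) return(fail("no upstream local minimum (NFR)"))
  nfr <- up_min[length(up_min)]                  # first one left of the TSS
  up_max <- ex$maxima[ex$maxima < nfr]
  if (length(up_max) < 1) return(fail("no upstream local maximum (-1)"))
  minus1 <- up_max[length(up_max)]
  peaks <- down_max[seq_len(min(4L, length(down_max)))]
  structure(list(ok = TRUE, reason = NULL,
                 pos_plus1 = pos[plus1], pos_minus1 = pos[minus1],
                 pos_nfr = pos[nfr], downstream_peaks = pos[peaks],
                 s_plus1 = y[plus1], s_minus1 = y[minus1], s_nfr = y[nfr],
                 s_range = range(y)),
            class = "mn_landmarks")
}

#' Promoter NFR score
#'
#' The smoothed aggregate signal at the +1 and -1 nucleosomes (their mean)
#' minus the NFR signal, normalized by the signal range over the 3-kb
#' promoter window; lies in [-1, 1], with higher values indicating a
#' sharper nucleosome-free region. Scores below 0.4 fail.
#'
#' @param landmarks An `mn_landmarks` from [find_landmarks()].
#' @param numerator `"mean"` (default) or `"sum"` of the +1/-1 signals
#'   before subtracting the NFR signal.
#' @param cutoff Pass threshold (default 0.4).
#' @return List of class `mn_nfr`: `nfr_score`, `judgment`, `cutoff`.
#' @export
nfr_score <- function(landmarks, numerator = c("mean", "sum"), cutoff = 0.4) {
  numerator <- match.arg(numerator)
  if (!landmarks$ok) {
    return(structure(list(nfr_score = NA_real_, judgment = "Fail",
                          reason = landmarks$reason, cutoff = cutoff),
                     class = "mn_nfr"))
  }
  rng <- diff(landmarks$s_range)
  if (rng == 0) {
    warning("flat aggregate curve: NFR score 0")
    score <- 0
  } else {
    peak <- if (numerator == "mean") {
      mean(c(landmarks$s_plus1, landmarks$s_minus1))
    } else {
      landmarks$s_plus1 + landmarks$s_minus1
    }
    score <- (peak - landmarks$s_nfr) / rng
  }
  structure(list(nfr_score = score,
                 judgment = if (!is.na(score) && score >= cutoff)
                   "Pass" else "Fail",
                 cutoff = cutoff),
            class = "mn_nfr")
}

#' Promoter positioning score
#'
#' The coefficient of variation (population standard deviation over mean)
#' of the three spacings between the +1, +2, +3 and +4 nucleosome peaks.
#' Perfectly phased arrays give 0; scores above 0.4 fail.
#'
#' @param landmarks An `mn_landmarks`.
#' @param cutoff Fail threshold (default 0.4).
#' @return List of class `mn_positioning`: `positioning_score`, `spacings`,
#'   `judgment`, `cutoff`.
#' @export
positioning_score <- function(landmarks, cutoff = 0.4) {
  if (!landmarks$ok || length(landmarks$downstream_peaks) < 4) {
    reason <- if (!landmarks$ok) landmarks$reason else
      "fewer than 4 downstream nucleosome peaks"
    return(structure(list(positioning_score = NA_real_, spacings = NULL,
                          judgment = "Fail", reason = reason,
                          cutoff = cutoff),
                     class = "mn_positioning"))
  }
  d <- diff(landmarks$downstream_peaks)
  cv <- sqrt(mean((d - mean(d))^2)) / mean(d)
  structure(list(positioning_score = cv, spacings = d,
                 judgment = if (cv <= cutoff) "Pass" else "Fail",
                 cutoff = cutoff),
            class = "mn_positioning")
}

#' Promoter QC scores from an occupancy profile
#'
#' Convenience wrapper: builds the TSS matrix, the smoothed aggregate
#' curve, locates the promoter landmarks and computes both promoter scores.
#'
#' @inheritParams region_matrix
#' @param tss TSS `GRanges`.
#' @param bandwidth Smoothing bandwidth in bins.
#' @return List of class `mn_promoter_scores` with the matrix, curve,
#'   landmarks, `nfr` and `positioning` results.
#' @export
promoter_scores <- function(occupancy, tss, window = c(-1000L, 2000L),
                            bin = 10L, bandwidth = 3) {
  mat <- region_matrix(occupancy, tss, window = window, bin = bin)
  curve <- aggregate_and_smooth(mat, bandwidth = bandwidth)
  lm <- find_landmarks(curve)
  structure(list(matrix = mat, curve = curve, landmarks = lm,
                 nfr = nfr_score(lm), positioning = positioning_score(lm)),
            class = "mn_promoter_scores")
}
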