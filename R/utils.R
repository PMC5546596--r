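# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# session RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Index of the maximal count; ties resolved toward the value closest to
# `target` (and to the smaller value on a residual tie, for determinism).
argmax_near <- function(counts, values, target = 147) {
  stopifnot(length(counts) == length(values), length(counts) > 0)
  m <- max(counts)
  cand <- values[counts == m]
  cand[order(abs(cand - target), cand)][1]
}

# Normalized Gaussian weights on -half_width..half_width.
gaussian_kernel <- function(half_width, sd) {
  stopifnot(half_width >= 1, sd > 0)
  d <- seq(-half_width, half_width)
  w <- exp(-d^2 / (2 * sd^2))
  w / sum(w)
}

# Kernel smoothing with zero-padding outside the vector (signal beyond the
# chromosome is taken as zero coverage).
smooth_zeropad <- function(x, kernel) {
  hw <- (length(kernel) - 1L) / 2L
  xp <- c(numeric(hw), as.numeric(x), numeric(hw))
  s <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(s[(hw + 1L):(hw + length(x))])
}

# Constant-preserving kernel smoothing: near the edges the kernel mass that
# falls outside the vector is renormalized away instead of zero-padded.
smooth_renorm <- function(x, kernel) {
  num <- smooth_zeropad(x, kernel)
  den <- smooth_zeropad(rep(1, length(x)), kernel)
  num / den
}
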