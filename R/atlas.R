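#' Shipped QC score cutoffs
#'
#' The published judgment cutoffs, all derived from the distribution of
#' scores over a historical reference atlas of human and mouse MNase-seq
#' samples: rotational score > 0.08 passes; estimated nucleosomal DNA
#' length in 140-155 bp passes; promoter NFR score >= 0.4 passes; promoter
#' positioning score <= 0.4 passes; DHS enrichment fold > 2 passes. MAPQ
#' filter cutoff 30.
#'
#' @return A named list of cutoffs.
#' @export
reference_cutoffs <- function() {
  list(mapq = 30L,
       rotational = 0.08,
       frag_len_pass = c(140L, 155L),
       nfr = 0.4,
       positioning = 0.4,
       dhs_fold = 2)
}

#' Load a historical score table
#'
#' A user-supplied tab-separated table of historical QC scores, one row
#' per sample, with (a subset of) the columns `sample_id`, `species`,
#' `coverage`, `rotational_score`, `estimated_length`, `nfr_score`,
#' `positioning_score`. Missing scores are tolerated. The table is used
#' only to place a sample within the historical distribution; judgments
#' always come from the shipped cutoffs.
#'
#' @param path Path to the TSV file (with a header line).
#' @return A data.frame of class `mn_atlas`.
#' @export
load_atlas <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("atlas table must have a 'sample_id' column")
  }
  structure(df, class = c("mn_atlas", "data.frame"))
}

#' Percentile of a score within the historical distribution
#'
#' Empirical percentile rank of `value` among the atlas values for
#' `metric`: 0 at (or below) the historical minimum, 100 at (or above)
#' the maximum, linear rank in between with ties taking their mid-rank.
#'
#' @param value The sample's score.
#' @param metric Atlas column name (e.g. `"rotational_score"`).
#' @param atlas An `mn_atlas` data.frame.
#' @return Percentile in 0..100, or `NA` when the atlas lacks the metric
#'   or has fewer than 2 non-missing values.
#' @export
percentile_in_atlas <- function(value, metric, atlas) {
  if (is.null(atlas) || !metric %in% names(atlas)) return(NA_real_)
  x <- atlas[[metric]]
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2 || is.na(value)) return(NA_real_)
  pr <- 100 * (sum(x < value) + (sum(x == value) + 1) / 2 - 1) / (n - 1)
  min(max(pr, 0), 100)
}
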