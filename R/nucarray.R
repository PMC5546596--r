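#' Nucleosome-array detection parameters
#'
#' Published defaults: Gaussian smoothing of the center profile with window
#' +/-73 bp and standard deviation 30 bp; local maxima of the modified
#' (absolute-difference) profile taken within +/-73 bp; well-positioned
#' arrays are runs longer than 600 bp with fold enrichment above 2.
#'
#' @param smooth_half_window Smoothing window half width in bp (73).
#' @param smooth_sd Smoothing standard deviation in bp (30).
#' @param local_max_half_window Local-maximum window half width in bp (73).
#' @param min_length Minimum array length in bp, exclusive (600).
#' @param min_fold Minimum fold enrichment, exclusive (2).
#' @param on_smoothed Take local maxima on the smoothed profile instead of
#'   on the absolute-difference profile (default `FALSE`: the
#'   absolute-difference profile, as the method defines).
#' @return A list of class `mn_array_params`.
#' @export
array_params <- function(smooth_half_window = 73L, smooth_sd = 30,
                         local_max_half_window = 73L, min_length = 600L,
                         min_fold = 2, on_smoothed = FALSE) {
  stopifnot(smooth_half_window >= 1, smooth_sd > 0,
            local_max_half_window >= 1, min_length > 0, min_fold > 0)
  structure(list(smooth_half_window = as.integer(smooth_half_window),
                 smooth_sd = smooth_sd,
                 local_max_half_window = as.integer(local_max_half_window),
                 min_length = as.integer(min_length), min_fold = min_fold,
                 on_smoothed = isTRUE(on_smoothed)),
            class = "mn_array_params")
}

# One chromosome of the nuc-array computation, on a plain numeric vector of
# per-bp center counts. Returns the unnormalized connected-local-maxima
# curve (one value per bp).
nuc_array_chrom <- function(x, params) {
  L <- length(x)
  if (L < 2 || all(x == 0)) return(numeric(L))
  kern <- gaussian_kernel(params$smooth_half_window, params$smooth_sd)
  s <- smooth_zeropad(x, kern)
  d <- abs(diff(s))                      # modified profile, length L-1
  base <- if (params$on_smoothed) s[-L] else d
  hw <- params$local_max_half_window
  padded <- c(rep(-Inf, hw), base, rep(-Inf, hw))
  wmax <- zoo::rollmax(padded, k = 2L * hw + 1L, align = "center")
  cand <- which(base == wmax & base > 0)
  if (length(cand) == 0) return(numeric(L))
  # ties within one window mark only the leftmost position
  keep <- rep(TRUE, length(cand))
  last <- cand[1]
  if (length(cand) > 1) {
    for (j in 2:length(cand)) {
      if (cand[j] - last <= hw && base[cand[j]] == base[last]) {
        keep[j] <- FALSE
      } else {
        last <- cand[j]
      }
    }
  }
  marked <- cand[keep]
  v <- if (length(marked) == 1) {
    rep(base[marked], L - 1L)
  } else {
    stats::approx(x = marked, y = base[marked], xout = seq_len(L - 1L),
                  rule = 2)$y
  }
  c(v, v[L - 1L])                        # extend the last bp
}

#' Build the nuc-array curve
#'
#' The detection signal for well-positioned nucleosome arrays: the center
#' profile is Gaussian-smoothed (+/-73 bp, sd 30), the absolute difference
#' between adjacent bp forms the modified profile, local maxima of that
#' profile within +/-73 bp are marked, and adjacent marked maxima are
#' connected by linear interpolation (held flat beyond the outermost
#' maxima) to give a dense per-bp "nuc-array" value. The curve is then
#' divided by its genome-wide mean (over all assayable bp) so values are
#' fold enrichments over background with mean 1.
#'
#' @param centers An `mn_profile` of kind `"center"`, a named list of
#'   numeric per-bp count vectors, or a single numeric vector (taken as one
#'   chromosome `"chr1"`).
#' @param params [array_params()].
#' @param normalize Divide by the genome-wide mean (default `TRUE`).
#' @return A list of class `mn_nucarray`: `curve` (named list of per-bp
#'   numeric vectors; fold scale when normalized), `genome_mean` (the raw
#'   background level), `normalized`, `params`.
#' @export
nuc_array_curve <- function(centers, params = array_params(),
                            normalize = TRUE) {
  vecs <- if (inherits(centers, "mn_profile")) {
    stopifnot(centers$kind == "center")
    lapply(as.list(centers$signal), as.numeric)
  } else if (is.numeric(centers)) {
    list(chr1 = as.numeric(centers))
  } else {
    stopifnot(is.list(centers), !is.null(names(centers)))
    lapply(centers, as.numeric)
  }
  curve <- lapply(vecs, nuc_array_chrom, params = params)
  n_bp <- sum(vapply(curve, length, numeric(1)))
  total <- sum(vapply(curve, sum, numeric(1)))
  gmean <- if (n_bp > 0) total / n_bp else 0
  if (normalize) {
    if (gmean > 0) {
      curve <- lapply(curve, function(v) v / gmean)
    } else {
      warning("all-zero nuc-array curve: no background to normalize against")
    }
  }
  structure(list(curve = curve, genome_mean = gmean,
                 normalized = normalize && gmean > 0, params = params),
            class = "mn_nucarray")
}

#' Detect well-positioned nucleosome arrays
#'
#' Maximal runs of consecutive bp whose fold value strictly exceeds
#' `min_fold`; runs strictly longer than `min_length` are reported,
#' position-sorted, each scored with its mean fold value.
#'
#' @param nucarray An `mn_nucarray` (normalized).
#' @param params [array_params()].
#' @return A `GRanges` of arrays with columns `name` and
#'   `nuc_array_value`; empty (with a warning) when no run qualifies.
#' @export
detect_arrays <- function(nucarray, params = nucarray$params) {
  stopifnot(inherits(nucarray, "mn_nucarray"))
  if (!nucarray$normalized) {
    warning("nuc-array curve not normalized; no arrays reported")
    return(empty_segments())
  }
  segs <- list()
  for (chr in names(nucarray$curve)) {
    v <- nucarray$curve[[chr]]
    r <- rle(v > params$min_fold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths > params$min_length
    if (!any(ok)) next
    means <- mapply(function(s, e) mean(v[s:e]), starts[ok], ends[ok])
    segs[[chr]] <- GenomicRanges::GRanges(
      chr, IRanges::IRanges(starts[ok], ends[ok]),
      nuc_array_value = as.numeric(means))
  }
  if (length(segs) == 0) {
    warning("no well-positioned nucleosome arrays detected")
    return(empty_segments())
  }
  out <- sort(do.call(c, unname(segs)))
  S4Vectors::mcols(out)$name <- paste0("array_", seq_along(out))
  S4Vectors::mcols(out) <- S4Vectors::mcols(out)[, c("name",
                                                     "nuc_array_value")]
  out
}

empty_segments <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(0), nuc_array_value = numeric(0))
  gr
}

#' Positioning score of a region
#'
#' The mean nuc-array value over a region, used to compare the simulated
#' perfect-positioning and no-positioning regions across coverage levels.
#'
#' @param nucarray An `mn_nucarray`.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed interval within the curve.
#' @param scale `"raw"` (default; curve values before background
#'   normalization, the scale used for the simulation comparison) or
#'   `"fold"`.
#' @return Mean value over the region.
#' @export
positioning_score_region <- function(nucarray, chrom, start, end,
                                     scale = c("raw", "fold")) {
  scale <- match.arg(scale)
  v <- nucarray$curve[[chrom]]
  if (is.null(v) || start < 1 || end > length(v) || start > end) {
    stop("region outside the nuc-array curve bounds")
  }
  m <- mean(v[start:end])
  if (scale == "raw" && nucarray$normalized) m <- m * nucarray$genome_mean
  if (scale == "fold" && !nucarray$normalized) {
    stop("fold scale requested but the curve is unnormalized")
  }
  m
}

#' Enrichment of arrays over a region set
#'
#' Fold change of the observed proportion of arrays overlapping the region
#' set (by at least 1 bp) over the proportion expected by chance, the
#' latter being the merged region length divided by the effective genome
#' size. Applied to 3-kb downstream promoters and to union-DHS sites; for
#' the DHS set, folds above 2 pass.
#'
#' @param segments Array `GRanges` from [detect_arrays()].
#' @param regions Region `GRanges`; overlaps are merged before the length
#'   computation.
#' @param effective_genome_size Effective genome size in bp.
#' @param region_set_name Label; the Pass/Fail judgment against `cutoff`
#'   is attached when this is `"union_DHS"`.
#' @param cutoff Pass threshold on the fold (default 2, exclusive).
#' @return A list of class `mn_enrichment`: `region_set_name`,
#'   `observed_proportion`, `expected_proportion`, `fold`, `judgment`.
#' @export
enrichment_fold <- function(segments, regions, effective_genome_size,
                            region_set_name = "regions", cutoff = 2) {
  merged <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  reg_len <- sum(as.numeric(GenomicRanges::width(merged)))
  if (reg_len == 0) stop("region set has zero length")
  expected <- reg_len / effective_genome_size
  judged <- identical(region_set_name, "union_DHS")
  if (length(segments) == 0) {
    return(structure(list(region_set_name = region_set_name,
                          observed_proportion = NA_real_,
                          expected_proportion = expected, fold = NA_real_,
                          judgment = if (judged) "Fail" else NA_character_,
                          reason = "no arrays detected", cutoff = cutoff),
                     class = "mn_enrichment"))
  }
  observed <- mean(IRanges::overlapsAny(segments, merged,
                                        ignore.strand = TRUE))
  fold <- observed / expected
  structure(list(region_set_name = region_set_name,
                 observed_proportion = observed,
                 expected_proportion = expected, fold = fold,
                 judgment = if (judged) {
                   if (fold > cutoff) "Pass" else "Fail"
                 } else NA_character_,
                 cutoff = cutoff),
            class = "mn_enrichment")
}

#' Strand-aware downstream promoters
#'
#' The 3-kb regions downstream of each TSS used for the promoter
#' enrichment of nucleosome arrays.
#'
#' @param tss TSS `GRanges`.
#' @param length Downstream extent in bp (default 3000).
#' @return A `GRanges` of promoters, clipped to chromosome bounds where
#'   lengths are known.
#' @export
downstream_promoters <- function(tss, length = 3000L) {
  minus <- as.character(GenomicRanges::strand(tss)) == "-"
  start <- ifelse(minus, GenomicRanges::start(tss) - length + 1L,
                  GenomicRanges::start(tss))
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(start = pmax(start, 1L), width = length),
    strand = GenomicRanges::strand(tss),
    seqinfo = GenomeInfoDb::seqinfo(tss))
  suppressWarnings(GenomicRanges::trim(gr))
}

#' Annotate nucleosome arrays to genes
#'
#' For each transcript the promoter is TSS +/- 3 kb; the promoter
#' nuc-array length is the total overlap (bp) between that promoter and
#' any detected array, with -1 marking promoters no array touches.
#'
#' @param segments Array `GRanges`.
#' @param tss TSS `GRanges` with `transcript_id`.
#' @param flank Promoter half width in bp (default 3000).
#' @return A `GRanges` (one row per transcript, promoter coordinates) with
#'   columns `name` (transcript) and `score` (promoter nuc-array length,
#'   -1 for none), ready for BED6 export.
#' @export
annotate_genes <- function(segments, tss, flank = 3000L) {
  prom <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(start = pmax(GenomicRanges::start(tss) - flank, 1L),
                     end = GenomicRanges::start(tss) + flank - 1L),
    strand = GenomicRanges::strand(tss),
    seqinfo = GenomeInfoDb::seqinfo(tss))
  prom <- suppressWarnings(GenomicRanges::trim(prom))
  ov_len <- rep(0, length(prom))
  if (length(segments) > 0) {
    hits <- GenomicRanges::findOverlaps(prom, segments, ignore.strand = TRUE)
    if (length(hits) > 0) {
      w <- GenomicRanges::width(IRanges::pintersect(
        prom[S4Vectors::queryHits(hits)],
        segments[S4Vectors::subjectHits(hits)], ignore.strand = TRUE))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      ov_len[as.integer(names(agg))] <- agg
    }
  }
  S4Vectors::mcols(prom) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(tss)$transcript_id,
    score = ifelse(ov_len > 0, ov_len, -1))
  prom
}
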