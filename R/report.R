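#' Run the full MNase-seq QC pipeline
#'
#' Orchestrates: load + MAPQ-filter reads, build footprints and the
#' occupancy/center profiles, compute sequencing coverage, rotational
#' score (when a genome sequence is supplied), nucleosomal DNA length,
#' promoter profiles and scores, custom-region profiles, nucleosome-array
#' detection with promoter/DHS enrichment and gene-level annotation, and
#' assemble a QC report. Stages fail independently: an error in one metric
#' is recorded and the remaining metrics still run.
#'
#' @param alignments Path to SAM or BED aligned reads.
#' @param format,paired Passed to [load_alignments()].
#' @param genome Path to a genome FASTA or an `mn_genome`; `NULL` runs in
#'   sequence-free mode (rotational score not computed).
#' @param build Genome build id for [effective_genome_size()]; custom
#'   builds instead supply `genome_size`.
#' @param genome_size Effective genome size override in bp.
#' @param tss Path to a TSS BED file or a TSS `GRanges`.
#' @param custom_regions,dhs Optional paths/`GRanges` of custom regions and
#'   union-DHS sites.
#' @param atlas Optional path to a historical score table or an
#'   `mn_atlas`; adds percentiles to the report.
#' @param out_prefix Optional output prefix; when set, BED/TSV/report
#'   files are written as `<out_prefix>_*`.
#' @param seed Pipeline seed; every stochastic step derives from it.
#' @param params [preprocess_params()].
#' @param arr_params [array_params()].
#' @param cutoffs [reference_cutoffs()].
#' @return A list of class `mn_qc_report`.
#' @export
run_pipeline <- function(alignments, format = "auto", paired = FALSE,
                         genome = NULL, build = NULL, genome_size = NULL,
                         tss, custom_regions = NULL, dhs = NULL,
                         atlas = NULL, out_prefix = NULL, seed = 1L,
                         params = preprocess_params(rng_seed = seed),
                         arr_params = array_params(),
                         cutoffs = reference_cutoffs()) {
  if (missing(alignments) || missing(tss)) {
    stop("configuration error: 'alignments' and 'tss' are mandatory")
  }
  if (is.null(build) && is.null(genome_size)) {
    stop("configuration error: supply 'build' or 'genome_size'")
  }
  egs <- effective_genome_size(if (is.null(build)) "custom" else build,
                               override = genome_size)
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  if (is.character(genome)) genome <- load_genome(genome)
  if (!is.null(genome) && !inherits(genome, "mn_genome")) {
    stop("'genome' must be a FASTA path or an mn_genome object")
  }
  cl <- if (!is.null(genome)) genome$chrom_lengths else NULL

  reads <- load_alignments(alignments, format = format, paired = paired,
                           chrom_lengths = cl)
  n_input <- S4Vectors::metadata(reads)$n_input_records
  reads_f <- filter_mapq(reads, params$mapq_cutoff)
  n_mapq <- length(reads_f)
  frags <- to_fragments(reads_f, params = params)
  occupancy <- build_occupancy(frags, params)
  centers <- build_center_profile(frags, params)

  tss_gr <- if (is.character(tss)) load_tss(tss, chrom_lengths = cl) else tss
  coverage <- stage("coverage", sequencing_coverage(n_mapq, egs))
  rotational <- if (is.null(genome)) NULL else stage("rotational", {
    ds <- downsample(reads_f, params$downsample_n, seed = params$rng_seed)
    rotational_score(dinuc_frequency(to_fragments(ds, params = params),
                                     genome),
                     cutoff = cutoffs$rotational)
  })
  fraglen <- stage("fragment_length",
                   estimate_fragment_length(
                     reads_f, max_distance = 250L,
                     pass_range = cutoffs$frag_len_pass, params = params))
  promoter <- stage("promoter", promoter_scores(occupancy, tss_gr))
  custom <- if (is.null(custom_regions)) NULL else stage("custom_regions", {
    cr <- if (is.character(custom_regions)) {
      load_regions(custom_regions, chrom_lengths = cl)
    } else custom_regions
    mat <- region_matrix(occupancy, cr, window = c(-1000L, 1000L))
    list(matrix = mat, curve = aggregate_and_smooth(mat))
  })
  nucarray <- stage("nuc_array", nuc_array_curve(centers, arr_params))
  segments <- if (is.null(nucarray)) NULL else
    stage("arrays", suppressWarnings(detect_arrays(nucarray, arr_params)))
  prom_enrich <- if (is.null(segments)) NULL else
    stage("promoter_enrichment",
          enrichment_fold(segments, downstream_promoters(tss_gr), egs,
                          region_set_name = "downstream_promoters",
                          cutoff = cutoffs$dhs_fold))
  dhs_enrich <- if (is.null(segments) || is.null(dhs)) NULL else
    stage("dhs_enrichment", {
      dr <- if (is.character(dhs)) load_regions(dhs, chrom_lengths = cl)
        else dhs
      enrichment_fold(segments, dr, egs, region_set_name = "union_DHS",
                      cutoff = cutoffs$dhs_fold)
    })
  genes <- if (is.null(segments)) NULL else
    stage("gene_annotation", annotate_genes(segments, tss_gr))

  if (is.character(atlas)) atlas <- stage("atlas", load_atlas(atlas))
  pct <- function(value, metric) {
    if (is.null(atlas)) NA_real_ else percentile_in_atlas(value, metric, atlas)
  }
  report <- structure(list(
    metrics = list(
      coverage = if (!is.null(coverage)) list(
        value = coverage$coverage, judgment = NA_character_, cutoff = NA,
        percentile = pct(coverage$coverage, "coverage")),
      rotational_score = if (is.null(genome)) list(
        value = NA_real_, judgment = "not computed",
        cutoff = cutoffs$rotational, percentile = NA_real_)
      else if (!is.null(rotational)) list(
        value = rotational$rotational_score, judgment = rotational$judgment,
        cutoff = cutoffs$rotational,
        percentile = pct(rotational$rotational_score, "rotational_score")),
      estimated_length = if (!is.null(fraglen)) list(
        value = fraglen$estimated_length, judgment = fraglen$judgment,
        cutoff = cutoffs$frag_len_pass,
        percentile = pct(fraglen$estimated_length, "estimated_length")),
      nfr_score = if (!is.null(promoter)) list(
        value = promoter$nfr$nfr_score, judgment = promoter$nfr$judgment,
        cutoff = cutoffs$nfr,
        percentile = pct(promoter$nfr$nfr_score, "nfr_score")),
      positioning_score = if (!is.null(promoter)) list(
        value = promoter$positioning$positioning_score,
        judgment = promoter$positioning$judgment,
        cutoff = cutoffs$positioning,
        percentile = pct(promoter$positioning$positioning_score,
                         "positioning_score")),
      dhs_enrichment = if (!is.null(dhs_enrich)) list(
        value = dhs_enrich$fold, judgment = dhs_enrich$judgment,
        cutoff = cutoffs$dhs_fold, percentile = NA_real_)),
    counts = list(n_input_reads = n_input, n_after_mapq = n_mapq,
                  n_removed_mapq = n_input -
                    S4Vectors::metadata(reads)$n_skipped - n_mapq *
                    (if (paired) 2L else 1L),
                  n_skipped = S4Vectors::metadata(reads)$n_skipped,
                  n_fragments = length(frags),
                  n_arrays = if (is.null(segments)) NA_integer_
                             else length(segments)),
    details = list(coverage = coverage, rotational = rotational,
                   fraglen = fraglen, promoter = promoter, custom = custom,
                   nucarray_genome_mean = if (!is.null(nucarray))
                     nucarray$genome_mean,
                   promoter_enrichment = prom_enrich,
                   dhs_enrichment = dhs_enrich),
    segments = segments, gene_annotation = genes,
    stage_errors = errors,
    run = list(alignments = alignments, paired = paired, seed = seed,
               effective_genome_size = egs,
               version = as.character(utils::packageVersion("mnaseqc")))),
    class = "mn_qc_report")
  if (!is.null(out_prefix)) write_report_outputs(report, out_prefix)
  report
}

write_report_outputs <- function(report, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$segments) && length(report$segments) > 0) {
    seg <- report$segments
    utils::write.table(
      data.frame(as.character(GenomicRanges::seqnames(seg)),
                 GenomicRanges::start(seg) - 1L, GenomicRanges::end(seg),
                 S4Vectors::mcols(seg)$name,
                 S4Vectors::mcols(seg)$nuc_array_value),
      paste0(prefix, "_Nucleosome_Array.bed"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(report$gene_annotation)) {
    ga <- report$gene_annotation
    utils::write.table(
      data.frame(as.character(GenomicRanges::seqnames(ga)),
                 GenomicRanges::start(ga) - 1L, GenomicRanges::end(ga),
                 S4Vectors::mcols(ga)$name, S4Vectors::mcols(ga)$score,
                 as.character(GenomicRanges::strand(ga))),
      paste0(prefix, "_geneLevel_nucarrayAnnotation.bed"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  d <- report$details
  if (!is.null(d$rotational) && !is.null(d$rotational$spectrum)) {
    utils::write.table(d$rotational$spectrum,
                       paste0(prefix, "_rotational_spectrum.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(d$fraglen)) {
    utils::write.table(d$fraglen$length_distribution,
                       paste0(prefix, "_fragment_length.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(d$promoter)) {
    utils::write.table(d$promoter$curve,
                       paste0(prefix, "_promoter_aggregate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mat <- d$promoter$matrix$matrix
    utils::write.table(
      cbind(region = rownames(mat), as.data.frame(mat)),
      paste0(prefix, "_promoter_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report_to_list(report),
                       paste0(prefix, "_qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  writeLines(utils::capture.output(print(report)),
             paste0(prefix, "_qc_report.txt"))
  invisible(prefix)
}

report_to_list <- function(report) {
  list(metrics = report$metrics, counts = report$counts,
       stage_errors = report$stage_errors, run = report$run)
}

#' @export
print.mn_qc_report <- function(x, ...) {
  cat("MNase-seq QC report\n")
  cat("  input:", x$run$alignments,
      if (x$run$paired) "(paired-end)" else "(single-end)", "\n")
  cat("  reads:", x$counts$n_input_reads, "input,",
      x$counts$n_after_mapq, "after MAPQ filter,",
      x$counts$n_fragments, "footprints\n")
  fmt <- function(v) if (is.na(v)) "NA" else format(v, digits = 4)
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    if (is.null(m)) next
    cat(sprintf("  %-18s %s", nm, fmt(m$value)))
    if (!is.na(m$judgment)) cat("  [", m$judgment, "]", sep = "")
    if (!is.na(m$percentile)) {
      cat(sprintf("  (atlas percentile %.1f)", m$percentile))
    }
    cat("\n")
  }
  if (!is.na(x$counts$n_arrays)) {
    cat("  nucleosome arrays:", x$counts$n_arrays, "\n")
  }
  if (length(x$stage_errors)) {
    cat("  stage errors:\n")
    for (nm in names(x$stage_errors)) {
      cat("    ", nm, ": ", x$stage_errors[[nm]], "\n", sep = "")
    }
  }
  invisible(x)
}
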