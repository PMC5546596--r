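#' Load aligned MNase-seq reads from SAM or BED
#'
#' Ingests aligned reads into a [GenomicRanges::GRanges] carrying the fields
#' the downstream filters need (`mapq`, `read_id`, `is_paired`,
#' `template_length`). SAM input is parsed with Rsamtools/GenomicAlignments;
#' unmapped, secondary and supplementary records are skipped (and counted).
#' For paired-end SAM only proper pairs are kept and each pair yields one
#' fragment record keyed on the leftmost mate, so pairs are never double
#' counted. BED input carries no mapping quality: records are loaded with
#' `mapq = NA` and later treated as passing the MAPQ filter (a message notes
#' the bypass), matching the convention that MAPQ applies at the alignment
#' stage.
#'
#' @param path Path to a SAM or BED file.
#' @param format `"sam"` or `"bed"`; `"auto"` guesses from the file
#'   extension.
#' @param paired Logical; is the data paired-end? Only meaningful for SAM.
#' @param chrom_lengths Optional named vector of chromosome lengths to attach
#'   to BED input (SAM input takes them from the header).
#' @return A `GRanges` of reads (single-end) or fragments (paired-end) with
#'   metadata columns `mapq`, `read_id`, `is_paired`, `template_length`, and
#'   attributes `n_input_records` and `n_skipped` in `metadata()`.
#' @export
load_alignments <- function(path, format = c("auto", "sam", "bed"),
                            paired = FALSE, chrom_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  }
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "sam") {
    load_sam_reads(path, paired = paired)
  } else {
    load_bed_reads(path, chrom_lengths = chrom_lengths)
  }
}

load_sam_reads <- function(path, paired = FALSE) {
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE))
  bf <- Rsamtools::BamFile(bam)
  n_total <- Rsamtools::countBam(bf)$records
  n_paired_flag <- Rsamtools::countBam(
    bf, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isPaired = TRUE)))$records
  if (paired && n_paired_flag == 0 && n_total > 0) {
    stop("paired = TRUE but no record carries the paired flag")
  }
  if (!paired && n_paired_flag > 0) {
    stop("paired = FALSE but ", n_paired_flag,
         " records carry the paired flag")
  }
  flag0 <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  if (paired) {
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isProperPair = TRUE),
      what = "mapq")
    gp <- GenomicAlignments::readGAlignmentPairs(bf, param = param,
                                                 use.names = TRUE)
    gr <- GenomicRanges::granges(gp, on.discordant.seqnames = "drop")
    keep <- names(gp) %in% names(gr)
    mq1 <- S4Vectors::mcols(GenomicAlignments::first(gp))$mapq[keep]
    mq2 <- S4Vectors::mcols(GenomicAlignments::second(gp))$mapq[keep]
    S4Vectors::mcols(gr)$mapq <- pmin(mq1, mq2)
    S4Vectors::mcols(gr)$read_id <- names(gr)
    S4Vectors::mcols(gr)$is_paired <- TRUE
    S4Vectors::mcols(gr)$template_length <- GenomicRanges::width(gr)
    names(gr) <- NULL
    GenomicRanges::strand(gr) <- "*"
    n_kept <- 2L * length(gr)
  } else {
    param <- Rsamtools::ScanBamParam(flag = flag0, what = c("mapq", "qname"))
    ga <- GenomicAlignments::readGAlignments(bf, param = param)
    gr <- GenomicRanges::granges(ga)
    S4Vectors::mcols(gr)$mapq <- S4Vectors::mcols(ga)$mapq
    S4Vectors::mcols(gr)$read_id <- S4Vectors::mcols(ga)$qname
    S4Vectors::mcols(gr)$is_paired <- FALSE
    S4Vectors::mcols(gr)$template_length <- NA_integer_
    n_kept <- length(gr)
  }
  n_skipped <- n_total - n_kept
  if (n_skipped > 0) {
    message(n_skipped, " SAM record(s) skipped ",
            "(unmapped/secondary/supplementary/improper)")
  }
  S4Vectors::metadata(gr) <- list(n_input_records = n_total,
                                  n_skipped = n_skipped,
                                  read_mode = if (paired) "paired" else "single")
  gr
}

load_bed_reads <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(chrom_lengths)) {
    gr <- attach_chrom_lengths(gr, chrom_lengths)
  }
  S4Vectors::mcols(gr)$mapq <- NA_integer_
  nm <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr)$read_id <-
    if (is.null(nm)) paste0("bed_", seq_along(gr)) else nm
  S4Vectors::mcols(gr)$is_paired <- FALSE
  S4Vectors::mcols(gr)$template_length <- NA_integer_
  S4Vectors::mcols(gr)$name <- NULL
  S4Vectors::mcols(gr)$score <- NULL
  message("BED input carries no MAPQ; all ", length(gr),
          " records will pass the MAPQ filter")
  S4Vectors::metadata(gr) <- list(n_input_records = length(gr),
                                  n_skipped = 0L, read_mode = "single")
  gr
}

attach_chrom_lengths <- function(gr, chrom_lengths) {
  sl <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr), names(sl))
  GenomeInfoDb::seqlengths(gr)[names(sl)] <- sl
  gr
}

#' Load TSS annotation from a BED-like file
#'
#' Expects BED6 rows of the form `chrom  tss  tss+1  transcript_id  score
#' strand` (0-based half-open, so the interval has width 1).
#'
#' @param path Path to the BED file.
#' @param chrom_lengths Optional named chromosome lengths; records on unknown
#'   chromosomes are dropped with a message.
#' @return A width-1 `GRanges` with metadata column `transcript_id`.
#' @export
load_tss <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) != 1)) {
    stop("TSS records must have width 1 (chrom, tss, tss+1)")
  }
  if (!all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-"))) {
    stop("TSS records must carry strand + or -")
  }
  gr <- drop_unknown_chroms(gr, chrom_lengths, what = "TSS")
  nm <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$transcript_id <-
    if (is.null(nm)) paste0("tx_", seq_along(gr)) else nm
  gr
}

#' Load a BED region file (custom regions, union-DHS sites)
#'
#' @param path Path to a BED3+ file.
#' @param chrom_lengths Optional named chromosome lengths; regions on unknown
#'   chromosomes are rejected at load with the count logged.
#' @return A `GRanges` with an optional `name` column.
#' @export
load_regions <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1)) stop("region with start >= end")
  drop_unknown_chroms(gr, chrom_lengths, what = "region")
}

drop_unknown_chroms <- function(gr, chrom_lengths, what = "record") {
  if (is.null(chrom_lengths)) return(gr)
  known <- as.character(GenomicRanges::seqnames(gr)) %in% names(chrom_lengths)
  if (any(!known)) {
    message(sum(!known), " ", what, "(s) on unknown chromosomes dropped")
    gr <- gr[known]
  }
  attach_chrom_lengths(gr, chrom_lengths)
}

#' Write a GRanges as BED
#'
#' Thin wrapper around [rtracklayer::export.bed()]; coordinates are printed
#' 0-based half-open.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
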