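#' Load a genome from a FASTA file
#'
#' Reads a (multi-)FASTA genome into memory and returns a genome object used
#' by all sequence-dependent steps (rotational score, read simulation).
#'
#' @param fasta_path Path to a FASTA file.
#' @return An object of class `mn_genome`: a list with `seq` (a
#'   [Biostrings::DNAStringSet], uppercased) and `chrom_lengths` (named
#'   integer vector).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGTAC"), fa)
#' g <- load_genome(fa)
#' g$chrom_lengths
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("genome FASTA not found: ", fasta_path)
  }
  seq <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seq) == 0) stop("no FASTA records in ", fasta_path)
  # FASTA headers may carry descriptions; the record name is the first word
  names(seq) <- sub("\\s.*$", "", names(seq))
  if (anyNA(names(seq)) || any(names(seq) == "")) {
    stop("FASTA record without a name in ", fasta_path)
  }
  if (anyDuplicated(names(seq))) {
    stop("duplicate FASTA record name: ",
         names(seq)[duplicated(names(seq))][1])
  }
  seq <- Biostrings::DNAStringSet(toupper(seq))
  structure(
    list(seq = seq,
         chrom_lengths = stats::setNames(Biostrings::width(seq), names(seq))),
    class = "mn_genome")
}

#' @export
print.mn_genome <- function(x, ...) {
  cat("mn_genome with", length(x$seq), "sequence(s),",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Extract genome sequence by BED-style coordinates
#'
#' @param genome An `mn_genome` from [load_genome()] or
#'   [simulate_periodic_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval, as printed in BED files.
#' @return An uppercase character string of length `end - start`.
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "mn_genome"))
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  len <- genome$chrom_lengths[[chrom]]
  if (!(start >= 0 && start < end && end <= len)) {
    stop("coordinates [", start, ", ", end, ") out of range for ", chrom,
         " (length ", len, ")")
  }
  as.character(Biostrings::subseq(genome$seq[[chrom]], start + 1L, end))
}

#' Effective genome size for a genome build
#'
#' The mappable genome length used as the denominator of sequencing coverage
#' and of expected overlap proportions. Shipped values: 2.7e9 bp for the
#' human builds (hg19, hg38) and 1.87e9 bp for the mouse builds (mm9, mm10);
#' both are smaller than the assembly sizes because repetitive sequence is
#' excluded. Any other build requires an explicit `override`.
#'
#' @param build_id Genome build identifier.
#' @param override Effective size in bp for builds outside the registry
#'   (custom genomes); ignored when `build_id` is registered.
#' @return Effective genome size in bp.
#' @examples
#' effective_genome_size("hg19")
#' effective_genome_size("toy1", override = 1.2e6)
#' @export
effective_genome_size <- function(build_id, override = NULL) {
  registry <- c(hg19 = 2.7e9, hg38 = 2.7e9, mm9 = 1.87e9, mm10 = 1.87e9)
  if (build_id %in% names(registry)) {
    return(unname(registry[[build_id]]))
  }
  if (is.null(override)) {
    stop("unknown genome build '", build_id,
         "'; supply an explicit effective genome size")
  }
  override <- as.numeric(override)
  if (!is.finite(override) || override <= 0) {
    stop("effective genome size must be a positive number")
  }
  override
}
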