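agg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "aggnuc")
  if (path == "") {
    # during in-source development the file sits under inst/
    path <- file.path("inst", "extdata", file)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}

#' Reference DNA-fragment peak table (hippocampal aggregates)
#'
#' Thirty-eight genomic loci with significant ChIP-seq DNA-fragment peaks
#' in sarkosyl-insoluble aggregates from Alzheimer's-disease (AD) and
#' age-matched-control (AMC) hippocampus. Coordinates are 1-based closed;
#' `length` is `end - start + 1`. `peaks_ad`/`peaks_amc` are read counts in
#' the peak, `p_ad`/`p_amc` the per-group p-values against a uniform
#' genomic ("flat") null; the AD entry of the chromosome-7 locus carried no
#' peak and its p-value is missing, never 1. `dist_5p`/`dist_3p` are gap
#' distances in bp to the nearest flanking genes (0 = peak-coincident).
#'
#' @return A 38-row tibble.
#' @export
#' @examples
#' peaks <- agg_dna_peaks()
#' count_significant_peaks(peaks, "AD", 1e-5)  # 25
agg_dna_peaks <- function() {
  agg_extdata("dna_peaks_hippocampus.tsv")
}

#' Reference RNA-fragment count table (hippocampal aggregates)
#'
#' Forty-nine gene-coincident RNA-fragment peaks from AD and AMC
#' hippocampal aggregates with per-group read counts (`reads_ad`,
#' `reads_amc`), printed abundance ratios, and the printed significance
#' ceiling `p_printed` (chi-square / Fisher). `ns` marks rows reported as
#' not significant, which never count as differential at any threshold.
#' One peak spans two genes and is stored as a single record with the
#' secondary gene noted in `description`.
#'
#' @return A 49-row tibble.
#' @export
#' @examples
#' glance(classify_differentials(agg_rna_fragments(), alpha = 0.001))
agg_rna_fragments <- function() {
  agg_extdata("rna_fragments_hippocampus.tsv")
}

#' Reference viral read-count table (hippocampal aggregates)
#'
#' Ten human viruses detected among aggregate-derived reads that failed to
#' map to the human genome, with RNA- and DNA-fragment read counts per
#' group and per-cell logical flags (`pass_*`) recording whether the count
#' passed all three screening thresholds (coverage depth >= 5x, contiguous
#' covered run >= 100 nt, >= 400 reads) in that assay. `rna_diff_p` is the
#' printed ceiling for the AD-vs-AMC RNA count comparison where
#' significant.
#'
#' @return A 10-row tibble.
#' @export
agg_viral_reads <- function() {
  agg_extdata("viral_reads_hippocampus.tsv")
}

#' Sequencing library totals for viral fractions
#'
#' Viral read counts and total library sizes per group and molecule, the
#' numerator/denominator pairs behind the viral fractions (0.09% of AMC
#' RNA, 0.15% of AD RNA, 0.33% of DNA reads).
#'
#' @return A 4-row tibble with `group`, `molecule`, `viral_reads`,
#'   `total_reads`.
#' @export
#' @examples
#' lib <- agg_library_totals()
#' viral_fraction(lib$viral_reads, lib$total_reads)
agg_library_totals <- function() {
  agg_extdata("sequencing_library_totals.tsv")
}
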