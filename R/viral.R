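#' Coverage summary of reads on a viral genome
#'
#' Mean depth is averaged over covered positions only; the longest run is
#' the maximal stretch of consecutive positions with depth >= 1.
#'
#' @param reads Tibble of read intervals (`start`, `end`, 1-based closed)
#'   on the viral genome; may be empty.
#' @param genome_length Viral genome length, bp.
#' @return One-row tibble: `reads`, `mean_depth`, `longest_run`.
#' @export
#' @examples
#' summarize_coverage(tibble::tibble(start = c(1, 102), end = c(100, 200)), 300)
summarize_coverage <- function(reads, genome_length) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) {
    return(tibble(reads = 0L, mean_depth = 0, longest_run = 0))
  }
  if (any(reads$start < 1) || any(reads$end > genome_length)) {
    abort("read intervals fall outside [1, genome_length]")
  }
  ir <- IRanges::IRanges(start = reads$start, end = reads$end)
  covered <- IRanges::reduce(ir)
  n_cov <- sum(IRanges::width(covered))
  total_bases <- sum(reads$end - reads$start + 1)
  tibble(
    reads = nrow(reads),
    mean_depth = total_bases / n_cov,
    longest_run = max(IRanges::width(covered))
  )
}

#' Apply viral screening thresholds
#'
#' Two stages are configured: a loose `retrieval` stage (depth >= 5x, run
#' >= 75 nt, >= 50 reads) used when forming group read ratios, and the
#' strict `positive_id` stage (depth >= 5x, run >= 100 nt, >= 400 reads)
#' required to call a virus positively identified. All comparisons are
#' inclusive (>=), and a virus is positive only when all three pass.
#'
#' @param summaries Tibble with `reads`, `mean_depth`, `longest_run`
#'   columns (one row per virus/assay).
#' @param stage `"positive_id"` or `"retrieval"`.
#' @param config An [aggnuc_config()].
#' @return `summaries` with logical `pass_depth`, `pass_run`,
#'   `pass_reads`, `positive` and the `stage` label appended.
#' @export
#' @examples
#' apply_thresholds(tibble::tibble(reads = 400, mean_depth = 5, longest_run = 100))$positive
apply_thresholds <- function(summaries, stage = c("positive_id", "retrieval"),
                             config = aggnuc_config()) {
  stage <- match.arg(stage)
  th <- config$viral[[stage]]
  out <- as_tibble(summaries)
  out$pass_depth <- out$mean_depth >= th$min_depth
  out$pass_run <- out$longest_run >= th$min_run
  out$pass_reads <- out$reads >= th$min_reads
  out$positive <- out$pass_depth & out$pass_run & out$pass_reads
  out$stage <- stage
  out
}

#' Viral read fraction of a library
#'
#' @param viral_reads Viral read count(s).
#' @param total_reads Total library read count(s).
#' @return Percentage, full precision (report rounds to 2 decimals).
#' @export
#' @examples
#' round(viral_fraction(124803, 132252624), 2)  # 0.09
viral_fraction <- function(viral_reads, total_reads) {
  if (any(total_reads <= 0)) abort("total_reads must be positive")
  if (any(viral_reads > total_reads)) abort("viral_reads exceed total_reads")
  100 * viral_reads / total_reads
}

#' Per-virus ratio report
#'
#' From a wide per-virus count table (columns `reads_amc_rna`,
#' `reads_ad_rna`, `reads_amc_dna`, `reads_ad_dna`) computes the RNA/DNA
#' ratio within each group and the AD/AMC ratio within each molecule.
#' Ratios with a zero denominator are flagged `NA`.
#'
#' @param table Per-virus count tibble, e.g. [agg_viral_reads()].
#' @return The input with `rna_dna_amc`, `rna_dna_ad`, `ad_amc_rna`,
#'   `ad_amc_dna` appended (full precision).
#' @export
#' @examples
#' rr <- ratio_report(agg_viral_reads())
#' round(rr$rna_dna_ad[rr$virus_id == "Human_adenovirus_54"], 1)  # 44.0
ratio_report <- function(table) {
  tbl <- as_tibble(table)
  need <- c("reads_amc_rna", "reads_ad_rna", "reads_amc_dna", "reads_ad_dna")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("ratio_report needs columns: %s", paste(need, collapse = ", ")))
  }
  mutate(tbl,
         rna_dna_amc = abundance_ratio(.data$reads_amc_rna, .data$reads_amc_dna),
         rna_dna_ad = abundance_ratio(.data$reads_ad_rna, .data$reads_ad_dna),
         ad_amc_rna = abundance_ratio(.data$reads_ad_rna, .data$reads_amc_rna),
         ad_amc_dna = abundance_ratio(.data$reads_ad_dna, .data$reads_amc_dna))
}

#' Virus-level positivity census of a screened table
#'
#' Given per-cell pass flags (`pass_amc_rna`, `pass_ad_rna`,
#' `pass_amc_dna`, `pass_ad_dna`, as in [agg_viral_reads()]), counts
#' viruses carrying at least one passing assay among the selected
#' columns. With the AD columns selected this reproduces the
#' seven positively identified viruses of the bundled table.
#'
#' @param table Tibble with per-cell `pass_*` logical columns.
#' @param columns Which pass columns to consider (default: all four).
#' @return Integer: number of viruses with >= 1 passing selected cell.
#' @export
#' @examples
#' tally_viral_positives(agg_viral_reads(), c("pass_ad_rna", "pass_ad_dna"))  # 7
tally_viral_positives <- function(table,
                                  columns = c("pass_amc_rna", "pass_ad_rna",
                                              "pass_amc_dna", "pass_ad_dna")) {
  tbl <- as_tibble(table)
  miss <- setdiff(columns, names(tbl))
  if (length(miss)) abort(sprintf("missing pass columns: %s", paste(miss, collapse = ", ")))
  flags <- as.matrix(tbl[columns])
  sum(apply(flags, 1, function(r) any(r, na.rm = TRUE)))
}

#' Plot per-virus group ratios
#'
#' @param table Output of [ratio_report()].
#' @return A ggplot: RNA/DNA ratios per group, per virus (log scale).
#' @export
plot_viral_ratios <- function(table) {
  long <- tidyr::pivot_longer(
    select(table, "virus_id", "rna_dna_amc", "rna_dna_ad"),
    cols = c("rna_dna_amc", "rna_dna_ad"),
    names_to = "group", values_to = "ratio")
  long$group <- ifelse(long$group == "rna_dna_ad", "AD", "AMC")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$virus_id, y = .data$ratio,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "RNA / DNA read ratio",
                  title = "Viral RNA/DNA read ratios by group")
}
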