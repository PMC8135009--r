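#' Peak p-value against a uniform genomic null
#'
#' Probability of observing at least `k` reads in a window of `w` bp when
#' `N` library reads fall uniformly ("flat") over a genome of `G` bp, i.e.
#' the upper tail of Binomial(N, w/G). The exact binomial tail is used for
#' any library up to 1e6 reads; beyond that, windows small relative to the
#' genome (w/G < 1e-2) switch to the Poisson(N w / G) tail, whose error is
#' negligible in that regime.
#'
#' @param k Reads observed in the window.
#' @param N Total library reads.
#' @param w Window width, bp.
#' @param G Genome length, bp.
#' @return P(X >= k); 1 when `k` is 0. Vectorized, monotone non-increasing
#'   in `k`.
#' @export
#' @examples
#' peak_pvalue(8, 100, 10, 1000)
peak_pvalue <- function(k, N, w, G) {
  if (any(w > G)) abort("window width w exceeds genome length G")
  if (any(w <= 0) || any(G <= 0)) abort("w and G must be positive")
  if (any(k < 0) || any(k > N)) abort("require 0 <= k <= N")
  args <- tibble(k = k, N = N, w = w, G = G)
  p <- args$w / args$G
  out <- ifelse(
    args$N > 1e6 & p < 1e-2,
    ppois(args$k - 1, lambda = args$N * p, lower.tail = FALSE),
    pbinom(args$k - 1, size = args$N, prob = p, lower.tail = FALSE)
  )
  ifelse(args$k == 0, 1, pmin(out, 1))
}

as_read_tibble <- function(reads) {
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads)) {
    list(tbl = as_tibble(reads$reads),
         library_size = reads$library_size %||% nrow(reads$reads))
  } else {
    list(tbl = as_tibble(reads), library_size = nrow(reads))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call fragment pile-up peaks against the uniform null
#'
#' Candidate windows have read-defined, variable widths. In sparse data
#' (expected background coverage <= 0.5x) they are simply the merged
#' overlapping reads (gap tolerance 0). In dense data, where merging would
#' fuse the whole genome into one window, candidates are the maximal runs
#' of coverage at least twice the expected background coverage; this
#' reduces to plain merging as coverage falls. Each window is scored with
#' [peak_pvalue()] on the count of overlapping reads, using the
#' overlap-effective width (window width plus mean read width minus 1) and
#' the library size as `N`; an E-value (p-value times the number of
#' candidate windows genome-wide) is attached. Windows significant at
#' `alpha` are retained.
#'
#' @param reads A tibble of read intervals (`chrom`, `start`, `end`) or a
#'   read set from [simulate_fragments()] (which carries `library_size`).
#' @param genome_length Genome length in bp.
#' @param alpha Retention threshold (strict `p < alpha`), default 1e-5.
#' @param library_size Total raw reads; defaults to the read count (or the
#'   read set's recorded value).
#' @param min_coverage Coverage cut defining candidate windows; default
#'   `NULL` picks `1` when expected background coverage is <= 0.5x, else
#'   twice the expected coverage.
#' @param retain Score the threshold against the p-value (default) or the
#'   E-value.
#' @return An `agg_peaks` tibble: `chrom`, `start`, `end`, `length`,
#'   `reads`, `p`, `evalue`, sorted by (chrom, start); attribute
#'   `n_candidates` holds the number of candidate windows tested.
#' @export
call_peaks <- function(reads, genome_length, alpha = aggnuc_config()$alpha_peak,
                       library_size = NULL, min_coverage = NULL,
                       retain = c("p", "evalue")) {
  retain <- match.arg(retain)
  if (genome_length <= 0) abort("empty genome")
  rs <- as_read_tibble(reads)
  tbl <- rs$tbl
  library_size <- library_size %||% rs$library_size
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  length = numeric(), reads = integer(),
                  p = numeric(), evalue = numeric())
  if (nrow(tbl) == 0) {
    return(structure(empty, n_candidates = 0L, genome_length = genome_length,
                     class = c("agg_peaks", class(empty))))
  }
  mean_width <- mean(tbl$end - tbl$start + 1)
  if (is.null(min_coverage)) {
    cov_exp <- library_size * mean_width / genome_length
    min_coverage <- if (cov_exp <= 0.5) 1 else ceiling(2 * cov_exp)
  }
  per_chrom <- lapply(split(tbl, tbl$chrom), function(d) {
    ir <- IRanges::IRanges(start = d$start, end = d$end)
    cov <- IRanges::coverage(ir)
    win <- IRanges::reduce(IRanges::ranges(IRanges::slice(cov, lower = min_coverage)))
    k <- IRanges::countOverlaps(win, ir)
    tibble(chrom = d$chrom[1],
           start = as.numeric(IRanges::start(win)),
           end = as.numeric(IRanges::end(win)),
           length = as.numeric(IRanges::width(win)),
           reads = as.integer(k))
  })
  cand <- bind_rows(per_chrom)
  n_cand <- nrow(cand)
  w_eff <- pmin(cand$length + mean_width - 1, genome_length)
  cand$p <- peak_pvalue(cand$reads, library_size, w_eff, genome_length)
  cand$evalue <- cand$p * n_cand
  score <- if (retain == "p") cand$p else cand$evalue
  out <- arrange(cand[score < alpha, , drop = FALSE], .data$chrom, .data$start)
  structure(out, n_candidates = n_cand, genome_length = genome_length,
            class = c("agg_peaks", class(empty)))
}

#' Candidate windows (all merged pile-ups, unthresholded)
#'
#' Same as [call_peaks()] with `alpha = 1` plus retention of every
#' candidate window; used for null-calibration checks.
#'
#' @inheritParams call_peaks
#' @return An `agg_peaks` tibble of all candidate windows.
#' @export
candidate_windows <- function(reads, genome_length, library_size = NULL) {
  call_peaks(reads, genome_length, alpha = Inf, library_size = library_size)
}

#' Count peaks significant for one group
#'
#' Counts rows whose group p-value is strictly below `alpha`. Rows with a
#' missing p-value (explicit "no peak" entries) never count.
#'
#' @param peaks A tibble carrying per-group p-value columns named
#'   `p_<group>` (e.g. `p_ad`, `p_amc` in [agg_dna_peaks()]) or a single
#'   `p` column when `group` is `NULL`.
#' @param group Group label, matched case-insensitively.
#' @param alpha Significance threshold (strict inequality).
#' @return Integer count.
#' @export
#' @examples
#' count_significant_peaks(agg_dna_peaks(), "AMC", 1e-5)  # 28
count_significant_peaks <- function(peaks, group = NULL, alpha = aggnuc_config()$alpha_peak) {
  col <- if (is.null(group)) "p" else paste0("p_", tolower(group))
  if (!col %in% names(peaks)) {
    abort(sprintf("unknown group %s: no column %s", group %||% "<none>", col))
  }
  p <- peaks[[col]]
  sum(!is.na(p) & p < alpha)
}

#' Annotate peaks with nearest flanking genes
#'
#' For each peak, `gene_5p` is the nearest gene lying at or before the
#' peak start and `gene_3p` the nearest at or after the peak end, with gap
#' distances in bp (0 when gene and peak overlap or abut). A gene
#' overlapping the peak is reported on the side of its midpoint, at
#' distance 0. Chromosomes without genes on one side leave that side
#' missing.
#'
#' @param peaks Tibble of peak intervals (`chrom`, `start`, `end`).
#' @param genes Gene tibble as from [read_gff_genes()] (needs `gene_id`,
#'   `chrom`, `start`, `end`), sorted or not.
#' @return `peaks` with `gene_5p`, `dist_5p`, `gene_3p`, `dist_3p`,
#'   `gene_mapped` columns appended.
#' @export
annotate_nearest_genes <- function(peaks, genes) {
  genes <- arrange(as_tibble(genes), .data$chrom, .data$start)
  peaks <- as_tibble(peaks)
  ann <- purrr::pmap(list(peaks$chrom, peaks$start, peaks$end), function(ch, ps, pe) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    res <- list(gene_5p = NA_character_, dist_5p = NA_real_,
                gene_3p = NA_character_, dist_3p = NA_real_)
    if (nrow(g) == 0) return(res)
    overlaps <- g$end >= ps & g$start <= pe
    mid_g <- (g$start + g$end) / 2
    mid_p <- (ps + pe) / 2
    # overlapping genes sit at distance 0 on the side of their midpoint
    five <- (overlaps & mid_g <= mid_p) | (!overlaps & g$end < ps)
    three <- (overlaps & mid_g > mid_p) | (!overlaps & g$start > pe)
    if (any(five)) {
      d5 <- ifelse(overlaps[five], 0, ps - g$end[five] - 1)
      i <- which.min(d5)
      res$gene_5p <- g$gene_id[five][i]
      res$dist_5p <- max(0, d5[i])
    }
    if (any(three)) {
      d3 <- ifelse(overlaps[three], 0, g$start[three] - pe - 1)
      i <- which.min(d3)
      res$gene_3p <- g$gene_id[three][i]
      res$dist_3p <- max(0, d3[i])
    }
    res
  })
  ann <- bind_rows(ann)
  out <- dplyr::bind_cols(peaks, ann)
  out$gene_mapped <- (!is.na(out$dist_5p) & out$dist_5p == 0) |
    (!is.na(out$dist_3p) & out$dist_3p == 0)
  out
}

#' Count peaks coincident with a gene
#'
#' A peak is gene-mapped when its nearest gene on either side is at zero
#' distance (overlap or direct abutment).
#'
#' @param annotations Tibble with a `gene_mapped` column, or `dist_5p` /
#'   `dist_3p` columns from which it is derived.
#' @return Integer count.
#' @export
#' @examples
#' count_gene_mapped(agg_dna_peaks())  # 5
count_gene_mapped <- function(annotations) {
  if (!"gene_mapped" %in% names(annotations)) {
    if (!all(c("dist_5p", "dist_3p") %in% names(annotations))) {
      abort("need a gene_mapped column or dist_5p/dist_3p columns")
    }
    gm <- (!is.na(annotations$dist_5p) & annotations$dist_5p == 0) |
      (!is.na(annotations$dist_3p) & annotations$dist_3p == 0)
  } else {
    gm <- annotations$gene_mapped
  }
  sum(gm, na.rm = TRUE)
}

#' Summarize peak lengths
#'
#' @param peaks Tibble with a `length` column (bp).
#' @return One-row tibble with `n`, `mean_bp`, `sd_bp` (sample SD, n - 1
#'   denominator).
#' @export
#' @examples
#' summarize_peak_lengths(agg_dna_peaks())  # mean rounds to 579 bp
summarize_peak_lengths <- function(peaks) {
  len <- peaks$length
  if (length(len) < 2) abort("need at least 2 peaks to summarize lengths")
  tibble(n = length(len), mean_bp = mean(len), sd_bp = sd(len))
}

#' @exportS3Method generics::glance
glance.agg_peaks <- function(x, ...) {
  tibble(n_peaks = nrow(x),
         n_candidates = attr(x, "n_candidates"),
         genome_length = attr(x, "genome_length"),
         mean_length = if (nrow(x)) mean(x$length) else NA_real_,
         min_p = if (nrow(x)) min(x$p) else NA_real_)
}

#' @exportS3Method generics::tidy
tidy.agg_peaks <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.agg_peaks <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = -log10(.data$p))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = -log10(.data$p))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "genomic position (bp)", y = "-log10 p (uniform null)",
                  title = "Fragment pile-up peaks vs uniform background")
}
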