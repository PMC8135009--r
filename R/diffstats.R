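#' Two-group abundance ratio
#'
#' Simple count ratio A/B, full precision; table output rounds to 2
#' decimals via [write_table()]. A zero denominator yields `NA` (an
#' undefined-ratio marker), never infinity.
#'
#' @param count_a,count_b Read counts (vectorized).
#' @return Numeric ratios.
#' @export
#' @examples
#' round(abundance_ratio(22800, 4958), 2)  # 4.60
abundance_ratio <- function(count_a, count_b) {
  ifelse(count_b > 0, count_a / count_b, NA_real_)
}

#' Yates continuity-corrected chi-square test on a 2x2 table
#'
#' Nondirectional chi-square with 1 df and Yates' correction:
#' chi2 = N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2), clamped to 0 when the
#' correction exceeds |ad - bc|.
#'
#' @param a,b,c,d Cell counts, row-wise: (a, b) / (c, d).
#' @return One-row tibble with `statistic` and `p`.
#' @export
#' @examples
#' yates_chi2_2x2(5, 59, 95, 41)$p < 0.005
yates_chi2_2x2 <- function(a, b, c, d) {
  v <- yates_chi2_core(a, b, c, d)
  tibble(statistic = v[[1]], p = v[[2]])
}

yates_chi2_core <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be nonnegative")
  # doubles throughout: the denominator overflows 32-bit integers easily
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    abort("a margin of the 2x2 table is zero; use fisher_exact_2tail() instead")
  }
  num <- abs(a * d - b * c) - n / 2
  stat <- if (num <= 0) 0 else n * num^2 / (r1 * r2 * c1 * c2)
  c(stat, pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities of tables no more probable than the observed one.
#'
#' @param a,b,c,d Cell counts, row-wise: (a, b) / (c, d).
#' @return The two-tailed p-value.
#' @export
#' @examples
#' fisher_exact_2tail(0, 5, 5, 0)  # 2 / choose(10, 5)
fisher_exact_2tail <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be nonnegative")
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  # small relative tolerance guards against ties lost to rounding
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Welch (Behrens-Fisher) heteroscedastic t test
#'
#' Two-tailed t test with the Welch-Satterthwaite degrees of freedom; the
#' appropriate conservative test when intra-group variances are not well
#' estimated from small samples.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return One-row tibble with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each sample needs n >= 2")
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  se2 <- vx + vy
  if (se2 == 0) {
    if (mean(x) == mean(y)) return(tibble(t = 0, df = NA_real_, p = 1))
    abort("zero variance in both samples with unequal means: t undefined")
  }
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  tibble(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

expected_cells_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  outer(c(a + b, c + d), c(a + c, b + d)) / n
}

#' Classify two-group differential abundance
#'
#' For each locus, decides significance at `alpha` and an enrichment
#' direction by the count ratio. In `printed_p` mode the table's printed
#' p-value ceilings are compared with `p <= alpha` (so a printed 0.001
#' qualifies at threshold 0.001), and rows flagged `ns` never count. In
#' `computed_p` mode each locus is tested as the 2x2 table of in-locus vs
#' remaining library reads per group, with the Yates chi-square replaced
#' by the two-tailed Fisher exact test whenever any expected cell is
#' below 5.
#'
#' @param records Tibble with `locus_id`, count columns (`reads_ad` /
#'   `reads_amc`, or `count_a` / `count_b`), and, depending on mode,
#'   `p_printed` (+ optional logical `ns`) or `library_a` / `library_b`.
#' @param alpha Significance threshold (inclusive).
#' @param mode `"printed_p"` or `"computed_p"`.
#' @return An `agg_diff` object; see [tidy.agg_diff()] and
#'   [glance.agg_diff()].
#' @export
#' @examples
#' fit <- classify_differentials(agg_rna_fragments(), alpha = 0.001)
#' glance(fit)  # 39 significant: 30 A(AD)-enriched, 9 B(AMC)-enriched
classify_differentials <- function(records, alpha = aggnuc_config()$alpha_diff,
                                   mode = c("printed_p", "computed_p")) {
  mode <- match.arg(mode)
  rec <- as_tibble(records)
  if (!"count_a" %in% names(rec) && "reads_ad" %in% names(rec)) {
    rec$count_a <- rec$reads_ad
    rec$count_b <- rec$reads_amc
  }
  stopifnot(all(c("locus_id", "count_a", "count_b") %in% names(rec)))
  ns <- if ("ns" %in% names(rec)) isTRUE_v(rec$ns) else rep(FALSE, nrow(rec))
  if (mode == "printed_p") {
    if (!"p_printed" %in% names(rec)) abort("printed_p mode needs a p_printed column")
    missing_p <- is.na(rec$p_printed) & !ns
    if (any(missing_p)) {
      abort(sprintf("missing printed p-value for locus %s",
                    rec$locus_id[which(missing_p)[1]]))
    }
    p <- rec$p_printed
    test_used <- rep("printed", nrow(rec))
    statistic <- rep(NA_real_, nrow(rec))
  } else {
    stopifnot(all(c("library_a", "library_b") %in% names(rec)))
    n_rec <- nrow(rec)
    p <- statistic <- rep(NA_real_, n_rec)
    test_used <- character(n_rec)
    for (i in seq_len(n_rec)) {
      a <- rec$count_a[i]; b <- rec$library_a[i] - a
      c_ <- rec$count_b[i]; d <- rec$library_b[i] - c_
      if (any(c(a, b, c_, d) < 0)) abort("counts exceed library sizes")
      if (any(expected_cells_2x2(a, b, c_, d) < 5)) {
        p[i] <- fisher_exact_2tail(a, b, c_, d)
        test_used[i] <- "fisher_exact"
      } else {
        y <- yates_chi2_core(a, b, c_, d)
        statistic[i] <- y[[1]]
        p[i] <- y[[2]]
        test_used[i] <- "yates_chi2"
      }
    }
  }
  ratio <- abundance_ratio(rec$count_a, rec$count_b)
  significant <- !ns & !is.na(p) & p <= alpha
  direction <- dplyr::case_when(
    significant & ratio > 1 ~ "A-enriched",
    significant & ratio < 1 ~ "B-enriched",
    TRUE ~ "none"
  )
  out <- tibble(
    locus_id = rec$locus_id, count_a = rec$count_a, count_b = rec$count_b,
    ratio = ratio, statistic = statistic, p = p, test_used = test_used,
    direction = direction, significant = significant
  )
  structure(list(results = out, alpha = alpha, mode = mode),
            class = "agg_diff")
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
print.agg_diff <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Differential fragment abundance (%s mode, alpha = %g)\n%d loci: %d significant (%d A-enriched, %d B-enriched)\n",
    x$mode, x$alpha, g$n_loci, g$n_significant, g$n_a_enriched, g$n_b_enriched))
  invisible(x)
}

#' Per-locus differential results
#' @param x An `agg_diff` object.
#' @param ... Unused.
#' @return Tibble with ratio, statistic, p, test, direction per locus.
#' @export
#' @method tidy agg_diff
tidy.agg_diff <- function(x, ...) {
  x$results
}

#' One-row summary of a differential classification
#' @param x An `agg_diff` object.
#' @param ... Unused.
#' @return Tibble with `n_loci`, `n_significant`, `n_a_enriched`,
#'   `n_b_enriched`, `alpha`, `mode`.
#' @export
#' @method glance agg_diff
glance.agg_diff <- function(x, ...) {
  r <- x$results
  tibble(
    n_loci = nrow(r),
    n_significant = sum(r$significant),
    n_a_enriched = sum(r$direction == "A-enriched"),
    n_b_enriched = sum(r$direction == "B-enriched"),
    alpha = x$alpha, mode = x$mode
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.agg_diff <- function(object, ...) {
  df <- object$results
  df$p_plot <- pmax(df$p, 1e-6)  # printed ceilings bottom out at 1e-4
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$ratio),
                                   y = -log10(.data$p_plot),
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::labs(x = "log2 count ratio (A / B)", y = "-log10 p",
                  colour = "direction",
                  title = "Two-group differential fragment abundance")
}
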