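test_that("abundance ratios reproduce printed table values", {
  expect_equal(round(abundance_ratio(22800, 4958), 2), 4.60)
  expect_equal(round(abundance_ratio(536, 232), 2), 2.31)
  expect_equal(abundance_ratio(c(7, 123), c(7, 123)), c(1, 1))
  expect_true(is.na(abundance_ratio(5, 0)))
})

test_that("Yates chi-square matches the reference implementation", {
  z <- yates_chi2_2x2(10, 10, 10, 10)
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)
  # the Y-chromosome 5-vs-59 comparison framed against equal expectation
  expect_lt(yates_chi2_2x2(5, 59, 95, 41)$p, 0.005)
  set.seed(21)
  for (i in 1:25) {
    tab <- matrix(sample(1:80, 4, replace = TRUE), 2)
    got <- yates_chi2_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(yates_chi2_2x2(0, 0, 3, 4), "margin")
})

test_that("Yates p approximates the Fisher two-tail p at read-count scale", {
  # null-distributed tables with margins in the read-count range of the
  # fragment tables (thousands), where the continuity-corrected chi-square
  # tracks the exact test within 10%
  set.seed(31)
  checked <- 0
  while (checked < 25) {
    r1 <- sample(1000:3000, 1); r2 <- sample(1000:3000, 1)
    c1 <- sample(round(0.3 * (r1 + r2)):round(0.7 * (r1 + r2)), 1)
    a <- stats::rhyper(1, r1, r2, c1)
    b <- r1 - a; c_ <- c1 - a; d <- r2 - c_
    if (min(c(a, b, c_, d)) < 0) next
    pf <- fisher_exact_2tail(a, b, c_, d)
    if (pf < 0.05 || pf > 0.95) next
    py <- yates_chi2_2x2(a, b, c_, d)$p
    expect_lt(abs(py - pf) / pf, 0.10)
    checked <- checked + 1
  }
})

test_that("Fisher two-tail p equals full enumeration", {
  expect_equal(fisher_exact_2tail(0, 5, 5, 0), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_2tail(1, 1, 1, 1), 1)
  # exhaustive small grid
  for (a in 0:4) for (b in 0:4) for (c_ in 0:4) for (d in 0:4) {
    expect_equal(fisher_exact_2tail(a, b, c_, d),
                 oracle_fisher_2tail(a, b, c_, d), tolerance = 1e-12)
  }
  # random tables with margins up to 30, cross-checked against fisher.test
  set.seed(41)
  for (i in 1:100) {
    cells <- sample(0:15, 4, replace = TRUE)
    got <- fisher_exact_2tail(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, oracle_fisher_2tail(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    if (sum(cells) > 0) {
      ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
      expect_equal(got, ref, tolerance = 1e-7)
    }
  }
})

test_that("Welch t matches t.test and is calibrated under the null", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(welch_t(x, x)$p, 1)
  expect_lt(welch_t(c(1, 2, 3), c(101, 102, 103))$p, 0.01)
  set.seed(51)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), sd = 2)
    got <- welch_t(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # type-I rate over equal-distribution samples
  set.seed(52)
  rej <- vapply(1:2000, function(i) {
    welch_t(rnorm(10), rnorm(10))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("printed-mode classification reproduces the published census", {
  fit <- classify_differentials(agg_rna_fragments(), alpha = 0.001,
                                mode = "printed_p")
  g <- glance(fit)
  expect_equal(g$n_significant, 39)
  expect_equal(g$n_a_enriched, 30)
  expect_equal(g$n_b_enriched, 9)
  # counts are conserved
  expect_equal(g$n_significant, g$n_a_enriched + g$n_b_enriched)
  td <- tidy(fit)
  expect_equal(sum(td$significant) + sum(!td$significant), g$n_loci)
  # N.S. rows never count, even at alpha = 1 they stay direction "none"
  ns <- td[td$locus_id %in% c("NCL", "CRYAB", "APOE"), ]
  expect_true(all(!ns$significant))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("printed mode demands a p-value or an explicit NS marker", {
  bad <- tibble::tibble(locus_id = "L1", count_a = 5, count_b = 2,
                        p_printed = NA_real_, ns = FALSE)
  expect_error(classify_differentials(bad), "L1")
  flat <- tibble::tibble(locus_id = c("L1", "L2"), count_a = c(10, 20),
                         count_b = c(10, 20), p_printed = c(1e-4, 1e-4))
  g <- glance(classify_differentials(flat, alpha = 0.001))
  expect_equal(g$n_a_enriched + g$n_b_enriched, 0)
})

test_that("computed mode switches to Fisher when expected cells are small", {
  rec <- tibble::tibble(
    locus_id = c("big", "tiny"),
    count_a = c(600, 3), count_b = c(300, 0),
    library_a = 1e5, library_b = 1e5
  )
  td <- tidy(classify_differentials(rec, mode = "computed_p"))
  expect_equal(td$test_used, c("yates_chi2", "fisher_exact"))
  expect_lt(td$p[1], 1e-10)
})

test_that("null count simulations flag ~alpha of loci; planted ratios recover direction", {
  counts <- simulate_counts(n_genes = 10000, ratio = 1, mean_a = 500, seed = 61)
  fit <- classify_differentials(counts, alpha = 0.001, mode = "computed_p")
  frac <- glance(fit)$n_significant / nrow(counts)
  expect_lt(abs(frac - 0.001), 3 * sqrt(0.001 * 0.999 / nrow(counts)))

  planted <- simulate_counts(n_genes = 5000, ratio = 2, mean_a = 100, seed = 62)
  expect_gte(mean(planted$count_a > planted$count_b), 0.99)

  # strong printed-table-scale signal is always recovered as A-enriched
  strong <- simulate_counts(n_genes = 100, ratio = 4.6, mean_a = 22800, seed = 63)
  td <- tidy(classify_differentials(strong, alpha = 0.001, mode = "computed_p"))
  expect_gte(mean(td$direction == "A-enriched" & td$p <= 0.001), 0.99)
})
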