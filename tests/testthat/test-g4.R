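test_that("QGRS scan handles canonical and degenerate inputs", {
  expect_equal(nrow(qgrs_scan("AAAAAAAAAA")), 0)
  telo <- qgrs_scan("GGGTTAGGGTTAGGGTTAGGG")
  expect_equal(nrow(telo), 1)
  expect_equal(telo$g_group_size, 3)
  expect_equal(c(telo$loop1, telo$loop2, telo$loop3), c(3, 3, 3))
  expect_equal(telo$start, 1)
  expect_equal(telo$end, 21)
  expect_error(qgrs_scan("ACGTX"), "characters")
})

test_that("QGRS candidates equal exhaustive enumeration on short sequences", {
  set.seed(81)
  for (i in 1:10) {
    n <- sample(25:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(0.2, 0.15, 0.45, 0.2)), collapse = "")
    got <- qgrs_scan(s, select = "all")
    want <- oracle_qgrs_candidates(s)
    got <- dplyr::arrange(got[, c("start", "end", "g_group_size",
                                  "loop1", "loop2", "loop3")],
                          start, end, g_group_size, loop1, loop2)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("greedy selection keeps the top-scoring non-overlapping motifs", {
  # two telomeric motifs separated by A-run: both kept
  s <- paste0("GGGTTAGGGTTAGGGTTAGGG", "AAAA", "GGGTTAGGGTTAGGGTTAGGG")
  expect_equal(nrow(qgrs_scan(s)), 2)
  # selected motifs never overlap and are sorted
  set.seed(82)
  for (i in 1:5) {
    s <- paste(sample(c("A", "G"), 80, replace = TRUE, prob = c(0.4, 0.6)),
               collapse = "")
    sel <- qgrs_scan(s)
    if (nrow(sel) > 1) {
      expect_true(all(diff(sel$start) > 0))
      expect_true(all(sel$start[-1] > sel$end[-nrow(sel)]))
    }
    # every candidate overlaps a selected motif of score >= its own
    cand <- qgrs_scan(s, select = "all")
    for (j in seq_len(nrow(cand))) {
      ov <- sel$start <= cand$end[j] & sel$end >= cand$start[j]
      expect_true(any(ov & sel$gscore >= cand$gscore[j] - 1e-9))
    }
  }
})

test_that("strand handling is reverse-complement symmetric", {
  set.seed(83)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    both <- qgrs_scan(s, both_strands = TRUE, select = "all")
    flipped <- qgrs_scan(reverse_complement(s), both_strands = TRUE,
                         select = "all")
    n <- nchar(s)
    # map the flipped scan back into the original coordinates
    remapped <- tibble::tibble(
      start = n - flipped$end + 1L, end = n - flipped$start + 1L,
      g_group_size = flipped$g_group_size
    )
    a <- dplyr::arrange(both[, c("start", "end", "g_group_size")],
                        start, end, g_group_size)
    b <- dplyr::arrange(remapped, start, end, g_group_size)
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})

test_that("G4Hunter base scoring follows capped run values", {
  expect_equal(g4hunter_score("AAAA", window = 4)$score, 0)
  expect_equal(g4hunter_score("GGGG", window = 4)$score, 4)
  expect_equal(g4hunter_score("GGGGCCCC", window = 8)$score, 0)
  # window longer than sequence collapses to one window
  one <- g4hunter_score("GGTT", window = 100)
  expect_equal(nrow(one), 1)
  expect_equal(one$score, (2 + 2 + 0 + 0) / 4)
  # run cap at 4: six G's all score 4
  expect_equal(g4hunter_score("GGGGGG", window = 6)$score, 4)
  # sliding-window agreement with a naive per-base rescan
  set.seed(84)
  s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  win <- 25
  got <- g4hunter_score(s, window = win)
  chars <- strsplit(s, "")[[1]]
  r <- rle(chars)
  base <- rep(ifelse(r$values == "G", pmin(r$lengths, 4),
                     ifelse(r$values == "C", -pmin(r$lengths, 4), 0)),
              r$lengths)
  for (i in c(1, 17, 60, nrow(got))) {
    expect_equal(got$score[i], mean(base[got$start[i]:got$end[i]]))
  }
  expect_true(all(got$qualifies == (abs(got$score) >= 1.3)))
})

test_that("shuffle expectation is seeded and composition-aware", {
  s <- "GGGTTAGGGTTAGGGTTAGGGTTAAACCC"
  e1 <- shuffle_expectation(s, n_shuffles = 30, seed = 9)
  e2 <- shuffle_expectation(s, n_shuffles = 30, seed = 9)
  expect_identical(e1, e2)
  expect_gte(e1, 0)
  # no G anywhere: expectation exactly zero
  expect_equal(shuffle_expectation("ACTACTACTACTACT", n_shuffles = 10, seed = 1), 0)
})

test_that("fold-enrichment classes use strict cutpoints and a pseudocount", {
  expect_equal(classify_g4(5, 5)$class, "G4-poor")
  expect_lt(abs(classify_g4(5, 5)$fold - 1), 1e-12)
  expect_equal(classify_g4(60, 0)$class, "G4-rich")
  # folds landing exactly on a cutpoint stay intermediate
  expect_equal(classify_g4(49.5, 0)$fold, 100)
  expect_equal(classify_g4(49.5, 0)$class, "intermediate")
  expect_equal(classify_g4(9.5, 0)$fold, 20)
  expect_equal(classify_g4(9.5, 0)$class, "intermediate")
  expect_error(classify_g4(1, -1), ">= 0")
})

test_that("planted quadruplex motifs are all recovered", {
  sim <- simulate_genome(genome_length = 10000, g4_density = 1, seed = 91)
  expect_equal(nrow(sim$g4_truth), 10)
  found <- qgrs_scan(sim$sequence)
  expect_gte(nrow(found), 10)
  for (i in seq_len(nrow(sim$g4_truth))) {
    ov <- found$start <= sim$g4_truth$end[i] & found$end >= sim$g4_truth$start[i]
    expect_true(any(ov))
  }
})

test_that("locus report separates G4-dense from background loci", {
  set.seed(92)
  # G4-dense locus: 60 G3-quadruplex motifs in an otherwise G-poor sequence
  filler <- function(n) paste(sample(c("A", "C", "T"), n, TRUE), collapse = "")
  motif <- "GGGTTAGGGTTAGGGTTAGGG"
  dense <- paste(vapply(1:60, function(i) paste0(motif, filler(80)), ""),
                 collapse = "")
  background <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  cfg <- aggnuc_config()
  cfg$g4$min_g_group <- 3
  rep <- g4_report(c(dense = dense, background = background),
                   n_shuffles = 15, seed = 93, config = cfg)
  expect_equal(rep$class[rep$locus_id == "dense"], "G4-rich")
  expect_equal(rep$class[rep$locus_id == "background"], "G4-poor")
})
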