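check_nucleotides <- function(sequence) {
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) abort("sequence contains characters other than A/C/G/T/N")
  s
}

#' Reverse complement
#' @param sequence Nucleotide string over A/C/G/T/N.
#' @return The reverse complement.
#' @export
reverse_complement <- function(sequence) {
  s <- check_nucleotides(sequence)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# length of the G-run starting at each position (0 where base is not G)
g_run_from <- function(chars) {
  n <- length(chars)
  run <- integer(n)
  nxt <- 0L
  for (i in n:1) {
    nxt <- if (chars[i] == "G") nxt + 1L else 0L
    run[i] <- nxt
  }
  run
}

qgrs_gscore <- function(g, l1, l2, l3, loop_max) {
  loops <- cbind(l1, l2, l3)
  20 * g +
    (loop_max - rowMeans(loops)) +
    (loop_max - (apply(loops, 1, max) - apply(loops, 1, min)))
}

qgrs_candidates_one <- function(s, max_length, min_g_group, loop_min, loop_max) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  run <- g_run_from(chars)
  acc <- vector("list", 64L); n_acc <- 0L
  g_cap <- max_length %/% 4L
  for (i in seq_len(n)) {
    if (run[i] < min_g_group) next
    for (g in min_g_group:min(run[i], g_cap)) {
      budget <- max_length - 4L * g
      if (budget < 3L * loop_min) break
      l1_max <- min(loop_max, budget - 2L * loop_min)
      for (l1 in loop_min:l1_max) {
        p2 <- i + g + l1
        if (p2 + 3L * g - 1L > n) break
        if (run[p2] < g) next
        l2_max <- min(loop_max, budget - l1 - loop_min)
        for (l2 in loop_min:l2_max) {
          p3 <- p2 + g + l2
          if (p3 + 2L * g - 1L > n) break
          if (run[p3] < g) next
          l3_max <- min(loop_max, budget - l1 - l2)
          for (l3 in loop_min:l3_max) {
            p4 <- p3 + g + l3
            if (p4 + g - 1L > n) break
            if (run[p4] < g) next
            n_acc <- n_acc + 1L
            if (n_acc > length(acc)) acc <- c(acc, vector("list", length(acc)))
            acc[[n_acc]] <- c(i, p4 + g - 1L, g, l1, l2, l3)
          }
        }
      }
    }
  }
  if (n_acc == 0L) {
    return(tibble(start = integer(), end = integer(), g_group_size = integer(),
                  loop1 = integer(), loop2 = integer(), loop3 = integer(),
                  gscore = numeric()))
  }
  m <- do.call(rbind, acc[seq_len(n_acc)])
  tibble(start = m[, 1], end = m[, 2], g_group_size = m[, 3],
         loop1 = m[, 4], loop2 = m[, 5], loop3 = m[, 6],
         gscore = qgrs_gscore(m[, 3], m[, 4], m[, 5], m[, 6], loop_max))
}

greedy_nonoverlap <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(-cand$gscore, cand$start, cand$end), , drop = FALSE]
  taken_start <- numeric(0); taken_end <- numeric(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= taken_end & cand$end[i] >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, cand$start[i])
      taken_end <- c(taken_end, cand$end[i])
    }
  }
  arrange(cand[keep, , drop = FALSE], .data$start)
}

#' Scan for quadruplex-forming G-rich sequences (QGRS)
#'
#' Finds windows of at most `max_length` nt of the form
#' Gx-loop-Gx-loop-Gx-loop-Gx with four equal G-runs of length
#' x >= `min_g_group` and loop lengths within `[loop_min, loop_max]`
#' (loops may contain any base, including G). Each candidate receives a
#' G-score rewarding longer G-groups (dominant term), shorter loops and
#' more-equal loops:
#' `20 g + (loop_max - mean(loops)) + (loop_max - (max(loop) - min(loop)))`.
#' Overlapping candidates are resolved by greedily keeping the
#' highest-scoring non-overlapping set (ties to the leftmost motif).
#'
#' @param sequence Nucleotide string over A/C/G/T/N.
#' @param max_length Maximum motif span, nt (default 30).
#' @param min_g_group Minimum G-run length (default 2).
#' @param loop_min,loop_max Loop-length bounds, nt (defaults 0 and 36).
#' @param both_strands Also scan the reverse complement; minus-strand
#'   motifs are reported in plus-strand coordinates with `strand = "-"`.
#' @param select `"greedy"` (default) returns the non-overlapping set per
#'   strand; `"all"` returns every candidate.
#' @return Tibble: `start`, `end`, `g_group_size`, `loop1..3`, `gscore`,
#'   `strand` (1-based closed coordinates on the input).
#' @export
#' @examples
#' qgrs_scan("GGGTTAGGGTTAGGGTTAGGG")  # human telomeric repeat: 1 motif
qgrs_scan <- function(sequence, max_length = 30, min_g_group = 2,
                      loop_min = 0, loop_max = 36,
                      both_strands = FALSE, select = c("greedy", "all")) {
  select <- match.arg(select)
  stopifnot(max_length >= 4 * min_g_group, min_g_group >= 1,
            loop_min >= 0, loop_max >= loop_min)
  s <- check_nucleotides(sequence)
  pick <- function(cand) if (select == "greedy") greedy_nonoverlap(cand) else cand
  fwd <- qgrs_candidates_one(s, max_length, min_g_group, loop_min, loop_max)
  fwd <- pick(fwd)
  fwd$strand <- rep("+", nrow(fwd))
  if (!both_strands) return(fwd)
  n <- nchar(s)
  rev <- qgrs_candidates_one(reverse_complement(s), max_length, min_g_group,
                             loop_min, loop_max)
  rev <- pick(rev)
  if (nrow(rev)) {
    new_start <- n - rev$end + 1L
    rev$end <- n - rev$start + 1L
    rev$start <- new_start
    rev$strand <- "-"
  } else {
    rev$strand <- character(0)
  }
  arrange(bind_rows(fwd, rev), .data$start, .data$strand)
}

#' G4Hunter window scores
#'
#' Per-base scores are +min(run, 4) for bases inside a G-run of that
#' length and -min(run, 4) inside a C-run, 0 elsewhere; each window's
#' score is the mean of its base scores. A region is considered
#' quadruplex-prone when |score| meets the threshold (default 1.3).
#'
#' @param sequence Nucleotide string.
#' @param window Window width, nt; windows longer than the sequence
#'   collapse to a single whole-sequence window.
#' @param threshold Qualification threshold on |score|.
#' @return Tibble: `start`, `end`, `score`, `qualifies` for each sliding
#'   window (step 1).
#' @export
#' @examples
#' g4hunter_score("GGGG", window = 4)$score  # 4
g4hunter_score <- function(sequence, window = 25, threshold = 1.3) {
  stopifnot(window >= 1)
  s <- check_nucleotides(sequence)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  r <- rle(chars)
  val <- ifelse(r$values == "G", pmin(r$lengths, 4),
                ifelse(r$values == "C", -pmin(r$lengths, 4), 0))
  base <- rep(val, r$lengths)
  if (window >= n) {
    sc <- mean(base)
    return(tibble(start = 1L, end = n, score = sc,
                  qualifies = abs(sc) >= threshold))
  }
  cs <- c(0, cumsum(base))
  starts <- seq_len(n - window + 1L)
  sc <- (cs[starts + window] - cs[starts]) / window
  tibble(start = starts, end = starts + window - 1L, score = sc,
         qualifies = abs(sc) >= threshold)
}

#' Expected motif count under a mononucleotide shuffle null
#'
#' The random expectation for a locus is the mean QGRS motif count over
#' `n_shuffles` composition-preserving shuffles of its sequence,
#' deterministic for a given seed.
#'
#' @param sequence Nucleotide string.
#' @param n_shuffles Number of shuffles (default 100).
#' @param seed Integer seed.
#' @param ... Passed to [qgrs_scan()].
#' @return The mean motif count (numeric scalar).
#' @export
shuffle_expectation <- function(sequence, n_shuffles = 100, seed = 1L, ...) {
  stopifnot(n_shuffles >= 1)
  s <- check_nucleotides(sequence)
  chars <- strsplit(s, "")[[1]]
  counts <- local_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      nrow(qgrs_scan(paste(sample(chars), collapse = ""), ...))
    }, numeric(1))
  })
  mean(counts)
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Classify loci by G-quadruplex fold enrichment
#'
#' Fold enrichment over the shuffle null is
#' `(observed + pseudo) / (expected + pseudo)` with a pseudocount
#' (default 0.5) guarding zero expectations. Classes use strict
#' inequalities: fold > 100 is G4-rich, fold < 20 is G4-poor, anything
#' else (including folds of exactly 100 or 20) is intermediate.
#'
#' @param observed Observed motif counts (vectorized).
#' @param expected Expected counts under the shuffle null.
#' @param pseudo Pseudocount.
#' @param fold_rich,fold_poor Class cutpoints.
#' @return Tibble with `observed`, `expected`, `fold`, `class`.
#' @export
#' @examples
#' classify_g4(60, 0)$class  # "G4-rich"
classify_g4 <- function(observed, expected, pseudo = 0.5,
                        fold_rich = 100, fold_poor = 20) {
  if (any(expected < 0)) abort("expected counts must be >= 0")
  fold <- (observed + pseudo) / (expected + pseudo)
  tibble(
    observed = observed, expected = expected, fold = fold,
    class = dplyr::case_when(
      fold > fold_rich ~ "G4-rich",
      fold < fold_poor ~ "G4-poor",
      TRUE ~ "intermediate"
    )
  )
}

#' G-quadruplex enrichment report over loci
#'
#' Runs [qgrs_scan()] on each locus sequence, computes the shuffle-null
#' expectation and classifies fold enrichment.
#'
#' @param sequences Named character vector of locus sequences.
#' @param n_shuffles Shuffles per locus.
#' @param seed Integer seed (each locus uses `seed + its index`).
#' @param config An [aggnuc_config()]; supplies the QGRS parameters and
#'   cutpoints.
#' @return Tibble: `locus_id`, `observed`, `expected`, `fold`, `class`,
#'   `n_shuffles`, `seed`.
#' @export
g4_report <- function(sequences, n_shuffles = NULL, seed = 1L,
                      config = aggnuc_config()) {
  g4 <- config$g4
  n_shuffles <- n_shuffles %||% g4$n_shuffles
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  rows <- purrr::imap(setNames(as.character(sequences), ids), function(s, id) {
    i <- match(id, ids)
    obs <- nrow(qgrs_scan(s, max_length = g4$max_length,
                          min_g_group = g4$min_g_group,
                          loop_min = g4$loop_min, loop_max = g4$loop_max))
    exp <- shuffle_expectation(s, n_shuffles = n_shuffles, seed = seed + i,
                               max_length = g4$max_length,
                               min_g_group = g4$min_g_group,
                               loop_min = g4$loop_min, loop_max = g4$loop_max)
    cls <- classify_g4(obs, exp, pseudo = g4$pseudo,
                       fold_rich = g4$fold_rich, fold_poor = g4$fold_poor)
    mutate(cls, locus_id = id, n_shuffles = n_shuffles, seed = seed + i,
           .before = 1)
  })
  bind_rows(rows)
}

#' Plot a G4Hunter score profile
#'
#' @param sequence Nucleotide string.
#' @param window,threshold As in [g4hunter_score()].
#' @return A ggplot of window scores with the qualification band.
#' @export
plot_g4_profile <- function(sequence, window = 25, threshold = 1.3) {
  df <- g4hunter_score(sequence, window = window, threshold = threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold), linetype = 2) +
    ggplot2::labs(x = "position (nt)", y = "G4Hunter window score",
                  title = "G4Hunter profile")
}
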