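#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one list, with the
#' defaults used throughout: peak significance at p < 1e-5 against the
#' uniform null, differential-abundance significance at p <= 0.001, the
#' two-stage viral screening thresholds (a loose retrieval stage of depth
#' >= 5x / contiguous run >= 75 nt / >= 50 reads used to form group read
#' ratios, and a strict positive-identification stage of depth >= 5x /
#' run >= 100 nt / >= 400 reads), and the G-quadruplex scan settings
#' (QGRS motif length <= 30 nt, G-groups >= 2, loops 0-36 nt; G4Hunter
#' window threshold 1.3; shuffle null of 100 mononucleotide shuffles with
#' pseudocount 0.5 and fold cutpoints >100 for G4-rich, <20 for G4-poor).
#'
#' @param alpha_peak Peak significance threshold (strict inequality).
#' @param alpha_diff Differential-abundance threshold (inclusive).
#' @param viral Named list with `retrieval` and `positive_id` stages, each
#'   a list of `min_depth`, `min_run`, `min_reads`.
#' @param g4 Named list of QGRS/G4Hunter parameters (see Details).
#' @param float_digits Decimal places used when writing numeric table
#'   columns to disk.
#' @param seed Nonnegative integer seed for seeded operations.
#'
#' @return A list of class `aggnuc_config`.
#' @export
#' @examples
#' cfg <- aggnuc_config()
#' cfg$viral$positive_id$min_reads
aggnuc_config <- function(alpha_peak = 1e-5,
                          alpha_diff = 0.001,
                          viral = list(
                            retrieval   = list(min_depth = 5, min_run = 75,  min_reads = 50),
                            positive_id = list(min_depth = 5, min_run = 100, min_reads = 400)
                          ),
                          g4 = list(
                            max_length = 30, min_g_group = 2,
                            loop_min = 0, loop_max = 36,
                            hunter_threshold = 1.3, hunter_window = 25,
                            n_shuffles = 100, pseudo = 0.5,
                            fold_rich = 100, fold_poor = 20
                          ),
                          float_digits = 2,
                          seed = 1L) {
  stopifnot(
    alpha_peak > 0, alpha_peak < 1,
    alpha_diff > 0, alpha_diff < 1,
    seed >= 0, seed == as.integer(seed)
  )
  structure(
    list(alpha_peak = alpha_peak, alpha_diff = alpha_diff,
         viral = viral, g4 = g4, float_digits = float_digits,
         seed = as.integer(seed)),
    class = "aggnuc_config"
  )
}
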