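#' Build a validated genomic-interval tibble
#'
#' Coordinates are 1-based and closed on both ends, the convention of the
#' bundled peak tables (length = end - start + 1). BED input is converted
#' at the boundary by [read_intervals()].
#'
#' @param chrom Chromosome names (treated as opaque strings).
#' @param start,end 1-based inclusive coordinates.
#' @return A tibble with columns `chrom`, `start`, `end`, `length`.
#' @export
#' @examples
#' genomic_intervals("chr1", 633735, 634300)$length  # 566
genomic_intervals <- function(chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 1)) abort("interval start must be >= 1 (1-based closed coordinates)")
  if (any(end < start)) {
    bad <- which(end < start)[1]
    abort(sprintf("interval %d has end < start (%s:%s-%s)", bad,
                  chrom[bad], format(start[bad]), format(end[bad])))
  }
  tibble(chrom = as.character(chrom), start = start, end = end,
         length = end - start + 1)
}

#' Read genomic intervals from BED or internal TSV
#'
#' BED uses 0-based half-open coordinates; they are converted to the
#' internal 1-based closed convention on input. The internal TSV dialect
#' carries 1-based closed `chrom`/`start`/`end` columns as-is. Input
#' ordering is preserved.
#'
#' @param path File path.
#' @param dialect `"bed"` (3+ whitespace-separated columns, no header) or
#'   `"tsv"` (header with chrom/start/end).
#' @return A tibble as from [genomic_intervals()].
#' @export
read_intervals <- function(path, dialect = c("bed", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (dialect == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "[ \t]+")
    bad <- which(vapply(fields, length, 1L) < 3)
    if (length(bad)) {
      abort(sprintf("malformed BED line %d in %s: fewer than 3 fields", bad[1], path))
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad)) {
      abort(sprintf("malformed BED line %d in %s: non-numeric coordinates", bad[1], path))
    }
    genomic_intervals(chrom, start0 + 1, end0)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(df))) {
      abort(sprintf("TSV %s lacks columns: %s", path,
                    paste(setdiff(need, names(df)), collapse = ", ")))
    }
    genomic_intervals(df$chrom, df$start, df$end)
  }
}

#' Write intervals as BED
#'
#' Converts the internal 1-based closed convention back to BED 0-based
#' half-open coordinates; a round trip through [read_intervals()] is the
#' identity.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  lines <- sprintf("%s\t%s\t%s", intervals$chrom,
                   format(intervals$start - 1, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Keeps gene-level features with their native 1-based closed GFF
#' coordinates, sorted by (chrom, start). Features without an `ID`
#' attribute are skipped with a warning.
#'
#' @param path GFF3 file path.
#' @param feature_type Feature types treated as genes.
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`.
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    df <- df[df$type %in% feature_type, , drop = FALSE]
    ids <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA_character_, nrow(df))
    biotype <- if ("biotype" %in% names(df)) as.character(df$biotype) else rep(NA_character_, nrow(df))
    out <- tibble(
      gene_id = ids,
      chrom = as.character(df$seqnames),
      start = as.numeric(df$start), end = as.numeric(df$end),
      strand = as.character(df$strand), biotype = biotype
    )
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 1L) == 9L]
    keep <- vapply(f, function(x) x[3] %in% feature_type, TRUE)
    f <- f[keep]
    attr9 <- vapply(f, `[[`, "", 9L)
    ids <- stringr::str_match(attr9, "(?:^|;)ID=([^;]+)")[, 2]
    out <- tibble(
      gene_id = ids,
      chrom = vapply(f, `[[`, "", 1L),
      start = as.numeric(vapply(f, `[[`, "", 4L)),
      end = as.numeric(vapply(f, `[[`, "", 5L)),
      strand = vapply(f, `[[`, "", 7L),
      biotype = NA_character_
    )
  }
  if (any(is.na(out$gene_id) | out$gene_id == "")) {
    n_bad <- sum(is.na(out$gene_id) | out$gene_id == "")
    warn(sprintf("skipping %d gene feature(s) without an ID attribute", n_bad))
    out <- out[!(is.na(out$gene_id) | out$gene_id == ""), , drop = FALSE]
  }
  if (any(out$end < out$start)) abort("gene feature with end < start")
  out$strand[!out$strand %in% c("+", "-")] <- "unknown"
  arrange(out, .data$chrom, .data$start)
}

#' Write a tabular result to TSV
#'
#' Numeric (double) columns are rendered at a fixed number of decimal
#' places so that a round-trip read returns values equal at that
#' precision; abundance ratios printed at 2 decimals (e.g. 4.60) follow
#' this rule.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param digits Decimal places for double columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, digits = aggnuc_config()$float_digits) {
  out <- as_tibble(records)
  is_dbl <- vapply(out, is.double, TRUE)
  out[is_dbl] <- lapply(out[is_dbl], function(x) {
    ifelse(is.na(x), NA_character_,
           ifelse(x == floor(x) & abs(x) < 1e15,
                  format(x, scientific = FALSE, trim = TRUE),
                  sprintf(paste0("%.", digits, "f"), x)))
  })
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Gap distance between two closed intervals
#'
#' Returns the number of bases strictly between the intervals: 0 when they
#' overlap or abut with no gap, matching the "at zero distance from peaks"
#' convention of the bundled tables.
#'
#' @param start1,end1,start2,end2 1-based inclusive coordinates
#'   (vectorized).
#' @return Nonnegative gap sizes in bp.
#' @export
#' @examples
#' interval_gap(100, 200, 300, 400)  # gap covers 201..299 -> 99
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start2 - end1 - 1, start1 - end2 - 1))
}
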