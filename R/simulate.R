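#' Default read-width distributions
#'
#' Fragment contig widths are drawn per molecule from the observed contig
#' size distributions: Normal(579, 34) bp for DNA and Normal(291, 31) bp
#' for RNA, truncated below at 50 bp to avoid degenerate intervals.
#' @keywords internal
width_params <- function(molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  if (molecule == "DNA") list(mean = 579, sd = 34, min = 50)
  else list(mean = 291, sd = 31, min = 50)
}

draw_widths <- function(n, molecule) {
  wp <- width_params(molecule)
  pmax(wp$min, round(rnorm(n, wp$mean, wp$sd)))
}

#' Simulate a genome with optional planted G-quadruplex motifs and genes
#'
#' The background sequence has uniform base composition. When
#' `g4_density > 0`, canonical quadruplex motifs (four G-runs of 3,
#' separated by loops of 1-7 nt drawn from A/C/T) are embedded at the
#' stated density, at recorded non-overlapping positions. Gene intervals
#' are non-overlapping and evenly spread.
#'
#' @param genome_length Genome length, bp.
#' @param n_genes Number of genes to place.
#' @param gene_length Mean gene length, bp.
#' @param g4_density Planted quadruplex motifs per kb.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of class `sim_genome`: `sequence` (character string,
#'   chromosome `sim1`), `genes` (tibble as [read_gff_genes()]), and
#'   `g4_truth` (tibble of planted motif intervals).
#' @export
simulate_genome <- function(genome_length = 10000, n_genes = 0,
                            gene_length = 500, g4_density = 0, seed = 1L) {
  if (n_genes > 0 && genome_length < 10 * n_genes * gene_length) {
    abort(sprintf(
      "infeasible packing: genome_length %d < 10 * n_genes (%d) * gene_length (%d)",
      genome_length, n_genes, gene_length))
  }
  local_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
    n_motifs <- round(g4_density * genome_length / 1000)
    g4_truth <- tibble(chrom = character(), start = integer(),
                       end = integer(), motif = character())
    if (n_motifs > 0) {
      # one motif per equal slot, jittered, so planted motifs never overlap
      slot <- genome_length / n_motifs
      max_len <- 12 + 3 * 7
      if (slot < max_len + 2) {
        abort("infeasible packing: g4_density too high for genome_length")
      }
      for (i in seq_len(n_motifs)) {
        loops <- sample(1:7, 3, replace = TRUE)
        motif <- paste0("GGG",
                        paste(sample(c("A", "C", "T"), loops[1], TRUE), collapse = ""),
                        "GGG",
                        paste(sample(c("A", "C", "T"), loops[2], TRUE), collapse = ""),
                        "GGG",
                        paste(sample(c("A", "C", "T"), loops[3], TRUE), collapse = ""),
                        "GGG")
        len <- nchar(motif)
        lo <- floor((i - 1) * slot) + 1
        start <- lo + sample.int(max(1, floor(slot) - len - 1), 1)
        chars[start:(start + len - 1)] <- strsplit(motif, "")[[1]]
        g4_truth <- bind_rows(g4_truth,
                              tibble(chrom = "sim1", start = start,
                                     end = start + len - 1L, motif = motif))
      }
    }
    genes <- tibble(gene_id = character(), chrom = character(),
                    start = numeric(), end = numeric(),
                    strand = character(), biotype = character())
    if (n_genes > 0) {
      slot <- genome_length / n_genes
      lens <- pmax(50, round(rnorm(n_genes, gene_length, gene_length / 10)))
      lens <- pmin(lens, floor(slot) - 2)
      starts <- vapply(seq_len(n_genes), function(i) {
        floor((i - 1) * slot) + 1 + sample.int(max(1, floor(slot) - lens[i] - 1), 1)
      }, numeric(1))
      genes <- tibble(
        gene_id = sprintf("gene%03d", seq_len(n_genes)),
        chrom = "sim1", start = starts, end = starts + lens - 1,
        strand = sample(c("+", "-"), n_genes, TRUE),
        biotype = "protein_coding"
      )
    }
    structure(list(sequence = paste(chars, collapse = ""),
                   genes = genes, g4_truth = g4_truth),
              class = "sim_genome")
  })
}

#' Simulate a fragment read set over a genome
#'
#' Background read starts are uniform over the genome (the "flat"
#' null); each planted peak receives additional reads so that its read
#' density is `fold` times background over the peak width. Read widths
#' follow the molecule's contig-width distribution (DNA 579 +/- 34 bp,
#' RNA 291 +/- 31 bp, truncated at 50 bp).
#'
#' @param genome_length Genome length, bp.
#' @param group Group label (e.g. "AD", "AMC").
#' @param molecule "DNA" or "RNA".
#' @param background_rate Background reads per bp.
#' @param peaks Tibble of planted peaks (`start`, `end`, `fold`), folds
#'   >= 1; `fold = 1` plants nothing (pure uniform).
#' @param seed Integer seed.
#' @return A list of class `read_set`: `reads` (tibble `chrom`, `start`,
#'   `end`), `library_size`, `group`, `molecule`, and the planted `peaks`
#'   as ground truth.
#' @export
simulate_fragments <- function(genome_length = 1e5, group = "A",
                               molecule = c("DNA", "RNA"),
                               background_rate = 0.01,
                               peaks = NULL, seed = 1L) {
  molecule <- match.arg(molecule)
  stopifnot(background_rate > 0)
  if (!is.null(peaks) && nrow(peaks) && any(peaks$fold < 1)) {
    abort("planted peak enrichment folds must be >= 1")
  }
  local_seed(seed, {
    n_bg <- rpois(1, background_rate * genome_length)
    w_bg <- draw_widths(n_bg, molecule)
    start_bg <- pmax(1, floor(runif(n_bg, 1, genome_length - w_bg + 1)))
    starts <- start_bg
    widths <- w_bg
    if (!is.null(peaks) && nrow(peaks)) {
      for (i in seq_len(nrow(peaks))) {
        pw <- peaks$end[i] - peaks$start[i] + 1
        n_extra <- rpois(1, background_rate * pw * (peaks$fold[i] - 1))
        if (n_extra > 0) {
          w <- draw_widths(n_extra, molecule)
          mid <- floor(runif(n_extra, peaks$start[i], peaks$end[i] + 1))
          s <- pmax(1, mid - floor(w / 2))
          starts <- c(starts, s)
          widths <- c(widths, w)
        }
      }
    }
    ends <- pmin(genome_length, starts + widths - 1)
    reads <- tibble(chrom = "sim1", start = starts, end = ends)
    structure(list(reads = reads, library_size = nrow(reads),
                   group = group, molecule = molecule,
                   peaks = peaks %||%
                     tibble(start = numeric(), end = numeric(), fold = numeric())),
              class = "read_set")
  })
}

#' Simulate two-group count records
#'
#' Per-gene counts are Poisson with means (m, m / ratio): the minimal
#' count-sampling model under which chi-square / Fisher comparisons of
#' read counts are exact. Genes drawing zero in both groups are excluded
#' with a warning. The true ratio is carried for recovery tests.
#'
#' @param n_genes Number of genes.
#' @param ratio True group-A : group-B abundance ratio(s); scalar or
#'   per-gene vector, > 0.
#' @param mean_a Group-A Poisson mean m.
#' @param library_a,library_b Library sizes recorded on each record.
#' @param seed Integer seed.
#' @return Tibble: `locus_id`, `true_ratio`, `count_a`, `count_b`,
#'   `library_a`, `library_b`.
#' @export
simulate_counts <- function(n_genes = 100, ratio = 1, mean_a = 500,
                            library_a = 1e6, library_b = 1e6, seed = 1L) {
  if (any(ratio <= 0)) abort("ratio must be positive")
  ratio <- rep_len(ratio, n_genes)
  local_seed(seed, {
    out <- tibble(
      locus_id = sprintf("gene%05d", seq_len(n_genes)),
      true_ratio = ratio,
      count_a = rpois(n_genes, mean_a),
      count_b = rpois(n_genes, mean_a / ratio),
      library_a = library_a, library_b = library_b
    )
    zero <- out$count_a == 0 & out$count_b == 0
    if (any(zero)) {
      warn(sprintf("excluding %d record(s) with zero counts in both groups", sum(zero)))
      out <- out[!zero, , drop = FALSE]
    }
    out
  })
}

#' Simulate viral screening summaries and genomes
#'
#' Each requested insert yields a coverage summary carrying exactly the
#' requested read count, mean depth and longest contiguous covered run,
#' alongside a random viral genome sequence.
#'
#' @param inserts Tibble with `virus_id` (unique), `depth`, `run`,
#'   `reads`; optional `group` and `molecule` columns pass through.
#' @param genome_length Viral genome length, bp (scalar or per-virus).
#' @param seed Integer seed.
#' @return List of class `sim_viral`: `summaries` (tibble with `reads`,
#'   `mean_depth`, `longest_run`) and `sequences` (named character).
#' @export
simulate_viral <- function(inserts, genome_length = 5000, seed = 1L) {
  inserts <- as_tibble(inserts)
  if (anyDuplicated(inserts$virus_id)) abort("virus ids must be unique")
  genome_length <- rep_len(genome_length, nrow(inserts))
  if (any(inserts$run > genome_length)) {
    abort("requested contiguous run exceeds the viral genome length")
  }
  local_seed(seed, {
    seqs <- vapply(genome_length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    names(seqs) <- inserts$virus_id
    summaries <- mutate(inserts,
                        mean_depth = .data$depth,
                        longest_run = .data$run,
                        genome_length = genome_length) %>%
      select(-"depth", -"run")
    structure(list(summaries = summaries, sequences = seqs),
              class = "sim_viral")
  })
}

#' Simulate a crosslink contactome with planted structure
#'
#' Builds `n_clusters` connected components containing `n_central_hubs`
#' hub proteins in total. Hubs within a cluster are joined in a chain;
#' the first `n_connectors` chain links are replaced by degree-2
#' connector proteins, so each planted connector is the only path between
#' the hubs it joins. Every hub receives leaf satellites until its degree
#' is at least 5; `n_peripheral` additional satellites are spread
#' round-robin. Planted keeper proteins draw spectral hits that satisfy
#' the >= `min_hits` in >= `min_replicates` filter; `n_dropouts` decoy
#' proteins (attached to hubs) draw hits that fail it and must vanish on
#' filtering. Protein lengths are log-uniform on 100-30000 aa.
#'
#' @param n_clusters Number of connected components.
#' @param n_central_hubs Total hub proteins (>= `n_clusters`).
#' @param n_connectors Number of hub connectors
#'   (<= `n_central_hubs - n_clusters`).
#' @param n_peripheral Extra satellite proteins beyond the degree-5
#'   minimum.
#' @param n_dropouts Decoy proteins failing the spectral filter.
#' @param reps Number of replicate crosslinking experiments.
#' @param min_hits,min_replicates Filter the keepers are built to pass.
#' @param seed Integer seed.
#' @return List of class `sim_contactome`: `proteins`, `edges`, `truth`
#'   (tibble `protein_id`, `role`, `cluster_id`, `kept`).
#' @export
simulate_contactome <- function(n_clusters = 11, n_central_hubs = 24,
                                n_connectors = 4, n_peripheral = 0,
                                n_dropouts = 3, reps = 3,
                                min_hits = 10, min_replicates = 2,
                                seed = 1L) {
  stopifnot(n_clusters >= 1, n_central_hubs >= n_clusters,
            n_connectors >= 0, n_peripheral >= 0, n_dropouts >= 0,
            reps >= min_replicates)
  if (n_connectors > n_central_hubs - n_clusters) {
    abort("n_connectors exceeds the number of joinable hub pairs (n_central_hubs - n_clusters)")
  }
  local_seed(seed, {
    sizes <- rep(n_central_hubs %/% n_clusters, n_clusters)
    extra <- n_central_hubs %% n_clusters
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    hub_ids <- sprintf("hub%03d", seq_len(n_central_hubs))
    cluster_of <- rep(seq_len(n_clusters), sizes)
    edges <- tibble(protein_a = character(), protein_b = character())
    conn_ids <- character(0)
    conn_cluster <- integer(0)
    conn_left <- n_connectors
    for (cl in seq_len(n_clusters)) {
      members <- hub_ids[cluster_of == cl]
      if (length(members) < 2) next
      for (j in seq_len(length(members) - 1)) {
        if (conn_left > 0) {
          cid <- sprintf("conn%02d", n_connectors - conn_left + 1)
          conn_ids <- c(conn_ids, cid)
          conn_cluster <- c(conn_cluster, cl)
          edges <- bind_rows(edges,
                             tibble(protein_a = cid, protein_b = members[j]),
                             tibble(protein_a = cid, protein_b = members[j + 1]))
          conn_left <- conn_left - 1
        } else {
          edges <- bind_rows(edges,
                             tibble(protein_a = members[j], protein_b = members[j + 1]))
        }
      }
    }
    # top up every hub to degree >= 5 with leaf satellites
    deg <- table(c(edges$protein_a, edges$protein_b))
    per_ids <- character(0)
    per_cluster <- integer(0)
    n_per <- 0L
    for (h in seq_along(hub_ids)) {
      d <- if (hub_ids[h] %in% names(deg)) deg[[hub_ids[h]]] else 0L
      need <- max(0L, 5L - d)
      for (s in seq_len(need)) {
        n_per <- n_per + 1L
        pid <- sprintf("per%04d", n_per)
        per_ids <- c(per_ids, pid)
        per_cluster <- c(per_cluster, cluster_of[h])
        edges <- bind_rows(edges, tibble(protein_a = hub_ids[h], protein_b = pid))
      }
    }
    for (s in seq_len(n_peripheral)) {
      h <- ((s - 1) %% n_central_hubs) + 1
      n_per <- n_per + 1L
      pid <- sprintf("per%04d", n_per)
      per_ids <- c(per_ids, pid)
      per_cluster <- c(per_cluster, cluster_of[h])
      edges <- bind_rows(edges, tibble(protein_a = hub_ids[h], protein_b = pid))
    }
    drop_ids <- if (n_dropouts > 0) sprintf("drop%02d", seq_len(n_dropouts)) else character(0)
    for (s in seq_len(n_dropouts)) {
      h <- ((s - 1) %% n_central_hubs) + 1
      edges <- bind_rows(edges, tibble(protein_a = hub_ids[h],
                                       protein_b = drop_ids[s]))
    }
    keep_ids <- c(hub_ids, conn_ids, per_ids)
    keeper_hits <- function(n) {
      m <- matrix(rpois(n * reps, 30), nrow = n, ncol = reps)
      m[, seq_len(min_replicates)] <- pmax(m[, seq_len(min_replicates), drop = FALSE], min_hits)
      m
    }
    dropout_hits <- function(n) {
      # at most min_replicates - 1 qualifying replicates each
      m <- matrix(rpois(n * reps, 2), nrow = n, ncol = reps)
      m <- pmin(m, min_hits - 1)
      if (n > 0 && min_replicates > 1) m[, 1] <- min_hits + 2
      m
    }
    hits <- rbind(keeper_hits(length(keep_ids)), dropout_hits(length(drop_ids)))
    colnames(hits) <- sprintf("hits_rep%d", seq_len(reps))
    all_ids <- c(keep_ids, drop_ids)
    proteins <- dplyr::bind_cols(
      tibble(protein_id = all_ids,
             length_aa = round(exp(runif(length(all_ids), log(100), log(30000))))),
      as_tibble(hits)
    )
    edges$crosslink_count <- rpois(nrow(edges), 5) + 1
    truth <- tibble(
      protein_id = all_ids,
      role = c(rep("central_hub", length(hub_ids)),
               rep("hub_connector", length(conn_ids)),
               rep("other", length(per_ids)),
               rep("dropout", length(drop_ids))),
      cluster_id = c(cluster_of, conn_cluster, per_cluster,
                     rep(NA_integer_, length(drop_ids))),
      kept = c(rep(TRUE, length(keep_ids)), rep(FALSE, length(drop_ids)))
    )
    structure(list(proteins = proteins, edges = edges, truth = truth),
              class = "sim_contactome")
  })
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i] %||% paste0("seq", i)), con)
    s <- sequences[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a simulated scenario to disk with its truth tables
#'
#' Emits the genome FASTA, gene table, read BED files, and `truth_*.tsv`
#' files so recovery tests can read planted structure from disk only.
#'
#' @param sim A `sim_genome`, `read_set`, `sim_viral` or `sim_contactome`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(sim, "sim_genome")) {
    write_fasta(c(sim1 = sim$sequence), file.path(dir, "genome.fasta"))
    write_table(sim$genes, file.path(dir, "genes.tsv"))
    write_table(sim$g4_truth, file.path(dir, "truth_g4.tsv"))
  } else if (inherits(sim, "read_set")) {
    write_bed(sim$reads, file.path(dir, sprintf("reads_%s_%s.bed", sim$group, sim$molecule)))
    write_table(sim$peaks, file.path(dir, "truth_peaks.tsv"))
  } else if (inherits(sim, "sim_viral")) {
    write_fasta(sim$sequences, file.path(dir, "viral.fasta"))
    write_table(sim$summaries, file.path(dir, "truth_viral.tsv"))
  } else if (inherits(sim, "sim_contactome")) {
    write_table(sim$proteins, file.path(dir, "proteins.tsv"))
    write_table(sim$edges, file.path(dir, "edges.tsv"))
    write_table(sim$truth, file.path(dir, "truth_contactome.tsv"))
  } else {
    abort("unknown scenario object")
  }
  invisible(dir)
}
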