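---
title: "Methods: nucleic-acid fragments and contact networks in protein aggregates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleic-acid fragments and contact networks in protein aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggnuc)
```

## What this package models

Sarkosyl-insoluble "protein aggregates" purified from brain tissue and
neuronal cell models carry more than protein: they entrap RNA and DNA
fragments, and the proteins themselves form a reproducible contact
network when crosslinked. This package implements the downstream desk
analysis of such preparations:

1. **Peak calling** of fragment pile-ups against a uniform genomic null
   ("are the recovered fragments random samples of the genome?").
2. **Nearest-gene annotation** of peaks with gap distances, and the
   census of peak-coincident genes.
3. **Two-group differential abundance** of per-gene fragment counts
   (disease vs. age-matched control), with the field's count statistics:
   Yates-corrected chi-square, two-tailed Fisher exact, Welch t.
4. **Viral screening** of non-host reads by coverage depth, contiguous
   covered span, and read count.
5. **G-quadruplex detection** (QGRS-style motif scan and G4Hunter run
   scoring) and classification of loci by fold enrichment over a
   composition-preserving shuffle null.
6. **Contactome hub taxonomy**: filtering crosslink spectral evidence,
   then labelling central hubs, hub connectors, and clusters.

Reference tables of DNA peaks, RNA fragment counts, viral read counts,
and library totals from AD / age-matched control hippocampal aggregates
ship with the package (`agg_dna_peaks()`, `agg_rna_fragments()`,
`agg_viral_reads()`, `agg_library_totals()`); every census the package
reports is recomputed from those tables at run time.

## Coordinate conventions

Internal coordinates are 1-based and closed on both ends, because the
reference tables use that convention (`length = end - start + 1` holds
for every row). BED input/output converts at the boundary
(`read_intervals()`, `write_bed()`), and the round trip is the identity.
Distances between non-overlapping intervals are *gap sizes* in bp — 0
when intervals overlap or abut — matching the tables' "zero distance"
notion of a peak-coincident gene. Chromosome names are opaque strings.

## The uniform-null peak model

If `N` library reads fall independently and uniformly on a genome of `G`
bp, the count in a window of `w` bp is Binomial(`N`, `w/G`).
`peak_pvalue(k, N, w, G)` is the upper tail `P(X >= k)`. Numerical
choice: the exact binomial tail is used for all libraries up to 1e6
reads; only beyond that, and only for windows with `w/G < 1e-2`, does
the implementation switch to the Poisson(`N w/G`) tail, where the
approximation error is far below any reported precision. This keeps the
p-value identical (relative error < 1e-6) to brute-force summation in
every regime a test or a desk-scale analysis will touch.

**Candidate windows.** Peak widths in this assay are read-defined, not
tiled: overlapping reads merge (gap tolerance 0) into variable-width
candidate windows. Pure merging, however, degenerates once expected
background coverage exceeds ~1x — every read chains into one
genome-wide window. `call_peaks()` therefore forms candidates as maximal
runs of coverage at least twice the expected background coverage
(`library_size * mean_read_width / G`), a rule that reduces *exactly* to
read merging when expected coverage is below 0.5x. Windows are scored on
the count of overlapping reads with the overlap-effective width
(`window width + mean read width - 1`), and an E-value (p times the
number of candidate windows) is reported alongside p. Retention defaults
to `p < 1e-5`, the threshold used for the bundled DNA peak census.
Strand is ignored throughout; "no peak" table entries are missing
values, never `p = 1`.

**Calibration.** The null calibration of the p-value kernel is tested on
uniform read placement over fixed tiling windows (1e4 windows of 1e4 bp,
1e7 reads, i.e. 1000 expected reads per window, where the discrete tail
is near-continuous): the empirical rate at alpha in {0.05, 0.01, 1e-3}
must sit within 3 binomial Monte-Carlo SDs of alpha. Calibration is
deliberately *not* asserted on merged pile-up candidates: a window
defined by the data as "contains at least one read" does not carry a
uniform null p-value, so the well-posed caller-level control is instead
that fold-1 (pure background) simulations yield zero significant
windows at `p < 1e-5`.

## Differential abundance

Each locus is a 2x2 comparison of in-locus reads versus the remaining
library reads in the two groups. `classify_differentials()` has two
modes:

* `printed_p`: trusts the p-value ceilings carried in a table
  (`p_printed`), as in the bundled RNA census. Significance is
  `p <= alpha` so that a printed "0.001" qualifies at threshold 0.001 —
  required for the bundled table's 39-significant census to reconcile
  with its 30/9 direction split. Rows flagged `ns` never count.
* `computed_p`: computes the statistic from counts and library sizes,
  using the Yates-corrected chi-square and substituting the two-tailed
  Fisher exact test whenever any expected cell falls below 5 (the
  conventional reading of "numerical constraints"). The Fisher two-tail
  p sums hypergeometric probabilities of all margin-fixed tables no more
  probable than the observed one.

No library-size normalization is applied by default: the reference
counts are already per-microgram normalized, and the printed ratios are
raw count ratios. No multiple-testing correction is applied, matching
the source analysis. Ratios with a zero denominator are undefined
markers, never infinities. The one peak housing two genes is a single
record, so gene-level tallies count it once.

## Viral screening

`summarize_coverage()` reduces read placements on a viral genome to
three metrics: read count, mean depth *over covered positions only*
(the natural reading of "coverage depth >= 5x" for partially covered
genomes), and the longest contiguous covered run. `apply_thresholds()`
is two-staged because the pipeline's own settings differ by purpose: a
loose **retrieval** stage (depth >= 5x, run >= 75 nt, reads >= 50) used
when tabulating group read ratios, and a strict **positive_id** stage
(depth >= 5x, run >= 100 nt, reads >= 400) for calling a virus present.
All comparisons are inclusive, and verdicts are monotone in every
metric. Host-read subtraction is an upstream input, not reimplemented.

## G-quadruplex detection

`qgrs_scan()` finds windows up to 30 nt of the form
G^x N_a G^x N_b G^x N_c G^x with four *equal* G-runs (x >= 2 by
default) and loops of 0-36 nt. The G-score rewards, in order of weight,
larger G-groups, then shorter and more-equal loops:

    gscore = 20 x + (loop_max - mean(loops)) + (loop_max - (max(loop) - min(loop)))

The formula is the package's own (the scoring of the original mapper is
unpublished); it is pinned by an exhaustive-enumeration oracle rather
than by external software output. Overlapping candidates are resolved
greedily by score, ties to the leftmost motif. Heterogeneous-run
quadruplexes are the province of `g4hunter_score()`, which scores each
base +min(run, 4) in a G-run and -min(run, 4) in a C-run and averages
over sliding windows; |score| >= 1.3 marks quadruplex propensity.

The "random expectation" for a locus is the mean motif count over
composition-preserving mononucleotide shuffles (default 100, seeded).
Fold enrichment is `(obs + 0.5) / (exp + 0.5)`; the pseudocount guards
zero expectations, at the documented price that fold > 100 requires
both a near-zero expectation and >= 50 observed motifs. Classes use the
strict cutpoints fold > 100 (G4-rich) and fold < 20 (G4-poor);
boundary folds are intermediate. The published per-locus G4 ratios for
the peak tables require the underlying human genome sequence and are
out of scope; the classifier is validated on synthetic loci instead.

## Contactome

Proteins enter the graph only with >= 10 spectral hits in >= 2 of 3
replicate crosslinking experiments (`filter_proteins()`, idempotent);
edges touching removed proteins drop. Roles on the filtered graph:

* **central hub** — degree > 4;
* **hub connector** — degree <= 4 whose removal separates at least two
  central hubs previously connected through it (an articulation-style
  test restricted to hub pairs, the minimal formalization of "joining
  hubs not otherwise connected");
* **cluster** — connected component, indexed deterministically by each
  component's lexicographically smallest protein id.

Degree is also reported per residue (`degree / length_aa`), the
length normalization that keeps titin-scale proteins from dominating
rankings by size alone. Both raw and normalized degree are emitted so a
census can be formed on either. Edge weights (crosslink counts) are
carried for reporting but do not affect topology-based roles.
Annotation enrichment of a protein set uses the upper-tail
hypergeometric test; its p-values depend on the annotation universe
supplied by the user and are not part of any bundled census.

## The synthetic-data generators

Each generator is seeded and byte-deterministic, and emits its planted
structure as machine-readable truth alongside the data
(`write_scenario()` writes `truth_*.tsv` files).

* `simulate_genome()` — uniform base composition; optional canonical
  quadruplex motifs (four G3 runs, loops 1-7 nt over A/C/T) planted at a
  stated density in non-overlapping slots; non-overlapping genes.
* `simulate_fragments()` — background read starts uniform over the
  genome; planted peaks receive extra reads to reach a stated fold;
  widths drawn from the observed contig-size distributions, Normal(579,
  34) bp for DNA and Normal(291, 31) bp for RNA, truncated at 50 bp to
  avoid degenerate intervals.
* `simulate_counts()` — per-gene Poisson counts with means (m, m/ratio),
  the minimal count-sampling model under which chi-square/Fisher
  comparisons of read counts are exact; zero-zero records are excluded
  with a warning.
* `simulate_viral()` — summaries carrying exactly the requested depth,
  run and read count, plus random viral genomes.
* `simulate_contactome()` — takes an explicit cluster count: hubs are
  distributed over clusters and chained within a cluster, with the first
  `n_connectors` chain links replaced by degree-2 connector proteins, so
  each planted connector is provably the only path between its two hubs.
  (A design where hub stars connect *only* through connectors cannot
  realize a census like 11 clusters / 24 hubs / 4 connectors, since k
  connectors over h single-hub stars always leave h - k components;
  chaining inside clusters is the minimal construction that can.) Every
  hub is topped up to degree >= 5 with leaf satellites; keeper proteins
  draw spectral hits guaranteed to pass the replicate filter and planted
  dropouts draw hits guaranteed to fail it.

Defaults chosen where the study conditions are silent, fixed once:
background density 0.01 reads/bp, planted folds 20, Poisson count mean
500, keeper spectral-hit mean 30 per replicate, protein lengths
log-uniform on 100-30000 aa. What the generators do **not** emulate:
sequencing error, quality scores, paired ends, mappability structure,
overdispersion between biological replicates, and correlated fragment
boundaries. Passing recovery tests therefore demonstrate correctness of
the inference rules under their stated models, not robustness to every
artefact of real libraries.

## Problem sizes and test design

The shipped suite runs in about 90 seconds on one CPU with these sizes,
chosen as the smallest that make each property sharp: binomial-tail
oracle up to N = 1000; null calibration on 1e4 windows at 1000 expected
reads each; Fisher enumeration over the full 0-4 cell grid plus random
margins to 30; QGRS enumeration oracle on sequences up to 60 nt;
connector oracle on random graphs up to 200 nodes; peak recovery over
100 seeded replicates of fold-10 peaks on 50 kb genomes at 20x
background; contactome recovery over 40 randomized scenarios plus the
11/24/4 census. The Yates-vs-Fisher agreement cross-check samples
null tables at read-count scale (margins 1000-3000), the regime of the
bundled tables, where the continuity-corrected approximation tracks the
exact test within 10%; at margins of only tens to hundreds the
two can differ by 15-30% and the check would be testing a false claim.

## Known limitations

* The reference p-values in the bundled DNA table come from the
  upstream workbench whose exact null computation is unpublished; they
  are treated as given data for counting, not as values to reproduce.
* The G4-rich / G4-poor proportions reported for the reference loci
  depend on genome sequence and an undefined binning; they are treated
  as qualitative.
* Which individual thresholds each reference virus failed is not
  recorded; the bundled table carries only per-cell pass flags.
* The hypergeometric enrichment p of the contactome depends entirely on
  the annotation universe and should not be compared across universes.
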