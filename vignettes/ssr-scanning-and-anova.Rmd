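---
title: "Scanning genomes for SSR motifs and comparing their abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for SSR motifs and comparing their abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscan)
```

## The problem

Simple sequence repeats (microsatellites) are tandem tracts of a short
motif whose copy number mutates rapidly; their density and tract lengths
differ between genomes and are used to quantify genomic similarity.
`ssrscan` answers two questions for a fixed panel of motifs (by default
ten tetranucleotides: `r paste(DEFAULT_MOTIFS, collapse = ", ")`):
*where* does each motif occur in each genome, and *do the genomes (or the
motifs) differ* in SSR abundance once occurrence counts are reduced to
comparable observation units?

## The exact-match engine

The scanner is a Boyer–Moore matcher built from three precomputed tables.

**First-occurrence heuristic.** Scanning starts at the smallest alignment
offset whose final characters agree: the first text position at which the
motif's rightmost character could match. When the motif's final character
never occurs at an align-able position the motif cannot occur at all, and
the scan returns an empty result without examining any alignment. Any
earlier alignment would be rejected on its last-character comparison, so
starting here discards nothing.

**Bad-character table.** `bad_character_table()` maps each base to its
last (0-based) index in the motif, −1 when absent. On a mismatch at motif
index `j` against text character `c`, the alignment can jump forward by
`j − β[c]`. Characters outside the motif alphabet — notably `N`, which
marks assembly gaps — behave as −1, so `N` never matches and every
alignment covering it is skipped efficiently.

**Good-suffix table.** `good_suffix_table()` is built from border arrays
(`prefix_function()`) of the motif and its reversal. Its entry for a full
match equals the motif period `m − τ[m]`: after reporting an occurrence of
`ATAT` (period 2) the scan advances by 2, which is precisely why
overlapping occurrences are found, not skipped. Every entry lies in
`[1, m]`, so the scan always advances and terminates.

Two policies are deliberate and exposed rather than hidden:

- **Overlap policy.** *All* occurrences are reported and counted,
  including overlapping ones. Reports additionally carry `run_count`
  (each maximal tandem tract counted once) so either counting convention
  can be compared downstream.
- **Strand and masking.** Motifs are matched on the forward strand
  exactly as given (the default panel already contains reverse-complement
  pairs); soft-masked lowercase bases are uppercased at read time and
  searched, since repeat-masked regions are exactly where SSRs live.

`naive_find_occurrences()` — a character-by-character check of every
alignment — defines the reference semantics; the test suite asserts
set-identity of starts between the two engines on randomized sequences
(including `N`-containing ones), on the default panel plus the
adversarially periodic `AAAA` and `ATAT`, and against
`Biostrings::matchPattern` as a third, independent implementation.

**Tandem runs.** Occurrences whose consecutive starts differ by exactly
`m` chain into runs; a run's span in bases (`copies × m`) is the tract
length, and both the longest span and the copy count are reported, since
"largest repeat" can reasonably mean either.

## From occurrences to observations

A single genome yields a single count per motif, which supports no
variance estimate. The package therefore partitions each genome into
non-overlapping windows of `window_size` bases (default 100 kb; the
half-open convention assigns an occurrence to the window containing its
start, and the trailing partial window is dropped so all windows are
comparable). Per-window counts are the replicate observations. Windows
are an analysis choice, not a biological claim: SSR density along real
chromosomes is autocorrelated, so windows are not strictly independent,
and the ANOVA below should be read accordingly.

## The inference layer

`one_way_anova()` implements the classical decomposition: between-group
sum of squares `Σ nᵢ(x̄ᵢ − x̄_G)²` on `k − 1` degrees of freedom, within-group
`Σ(x_ij − x̄ᵢ)²` on `N − k`, F as the ratio of mean squares, and the
upper-tail F probability. The identity
`SS_between + SS_within = SS_total` is asserted to 1e-9 relative
tolerance on randomized inputs, and (F, p) agree with `stats::aov` to
1e-8 on 100 random datasets — `aov` is the cross-check, never the
implementation.

**Decision rules.** The default rejects the null when `p < alpha`
(equivalently `F > F_critical`). An `"inverted"` compatibility rule —
reject when `F < F_critical` — is available for reproducing analyses that
used that inverted convention; it is never the default, and reports
record which rule produced each decision column.

**Two-way layout.** `two_way_anova()` handles the balanced genome × motif
design with windows as replicates (`cmd_anova` truncates every genome to
the minimum common window count to keep the design balanced, where the
closed-form decomposition is exact). With one replicate per cell the
additive model is fitted and the interaction is absorbed into the
residual on `(a−1)(b−1)` df. Unbalanced designs are refused loudly rather
than approximated.

**Tukey HSD.** `tukey_hsd()` uses the studentized range quantile
`qtukey(1 − α, k, df_within)`; the Tukey–Kramer `(1/n_a + 1/n_b)` form is
exact for equal group sizes and a standard mild-imbalance adjustment
otherwise. The reject flag is *defined* as the interval excluding zero,
so family-wise error control follows from the interval construction.

**Degenerate inputs.** Zero within-group (or residual) variance — e.g.
windowed counts from a motif that never occurs — raises an explicit
degenerate-input error naming the constant groups; `cmd_anova` converts
such errors into error rows in the report and continues with the
remaining tests. Explicit failure was preferred to returning an infinite
F.

## The synthetic-data generator

`generate_panel()` emulates a multi-genome SSR study at desk scale:

- **Background**: i.i.d. residues at a target GC fraction (default 0.40,
  typical of primate genomes), from which every panel motif is scrubbed
  by local re-rolling — so the background contributes *zero* occurrences
  and truth tables are exact equalities, not probabilistic statements.
- **Planting**: per genome and motif, a Poisson number of tandem runs
  with mean `multiplier × base_rate_per_mb × genome_length/1e6` (default
  25 runs/motif/Mb), geometric copy numbers with mean 2.5 capped at 30
  (SSR tract-length distributions are heavy-tailed and short-biased), at
  uniform non-overlapping positions.
- **Junction scrubbing**: planted tract boundaries can create accidental
  occurrences that straddle tract and background; background bases in any
  such occurrence are re-rolled (planted bases are never touched) until
  the only occurrences present are those inside planted intervals.
- **Truth**: a naive scan restricted to the union of planted intervals.
  This includes the overlaps implied by motif periodicity (planting
  `ATAT` twice yields starts 0, 2, 4) *and* occurrences of one motif
  inside a tract of a rotated motif — a `TAGA` run contains `GATA` and
  `AGAT`, which is also why those motifs' counts covary in real genomes
  scanned with this panel.

What the generator does **not** emulate: sequence composition structure
(isochores, CpG islands), SSR clustering, interruptions and point
mutations within tracts, indels, or assembly artifacts beyond `N`-free
backgrounds. Passing the planted-recovery tests therefore demonstrates
exactness of the search and bookkeeping, not robustness to mutated or
approximate repeats — approximate matching is out of scope by design.

Determinism: a panel is fully determined by its seed; the simulate
subcommand records the merged configuration in a manifest so any panel
can be regenerated byte-identically.

## Numerical and scale choices

- Coordinates are 0-based half-open internally and in BED output; the
  summary TSV prints counts and spans, and the pseudocode-style 1-based
  view appears nowhere in machine-readable output.
- The scan inner loop is C++ (via Rcpp) for chromosome-scale throughput;
  all shift tables are computed, exposed and tested in R.
- Window size must be at least 10× the motif length (below that, most
  windows are empty and the count model degenerates) and at most the
  genome length.
- Fixture scales were chosen to exercise the full pipeline in seconds to
  a couple of minutes on one core: randomized oracle equivalence uses
  1,000 sequences of 10 kb; the planted-recovery panel uses 5 genomes of
  400 kb (2 Mb of sequence) with 20-kb windows; calibration uses 10,000
  replicates of an 11-group, 10-observations-per-group null. These sizes
  give the calibration check a standard error of ≈0.002 on a 0.05 rate.
- Type-I calibration at α = 0.05 is asserted within [0.04, 0.06]; power
  is checked for monotonicity in the planted shift rather than against
  any closed-form value.

## Known limitations

- Exact matching only: a single substitution inside a tract splits or
  hides occurrences; motifs with ambiguity codes are rejected.
- Forward strand only by default; add reverse complements to the motif
  list explicitly if needed.
- Windows as replicates is the package's reproducible reading of
  "observations per genome"; other unit choices (per-chromosome counts,
  densities, log counts) change the F statistics and are left to the
  caller via the exposed windowing and grouping functions.
- The two-way path requires balance; heavily unequal window counts are
  truncated, discarding data from longer genomes.
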