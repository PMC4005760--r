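---
title: "Methods: consensus summits, overlap rules and DR3 motif screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus summits, overlap rules and DR3 motif screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdrmeta)
```

# The problem

ChIP-seq experiments for the vitamin D receptor (VDR) exist for several
human cellular models, each in a ligand-stimulated and an unstimulated
state. Each sample yields its own set of called peaks with its own summit
positions, fold enrichments (FE) and q-values. Comparing binding across
samples requires a single, non-redundant catalogue of binding locations:
nearby per-sample summits that represent the same site must be merged into
one *consensus summit*, while genuinely distinct neighbouring sites must
stay separate. On top of that catalogue one can then ask which sites are
cell-type specific, how stimulated and unstimulated profiles relate, and
how often the classical VDR-RXR recognition element — a direct repeat of
two RGGTCA-like hexamers spaced by three nucleotides (DR3,
`RGGTCANNGRGTTCA`) — underlies the peak summits.

`vdrmeta` implements this meta-analysis as a reusable, fully tested
pipeline operating on standard formats (narrowPeak, bedGraph, FASTA), and
ships a seeded simulator that generates complete synthetic studies with
known ground truth so every stage can be validated end to end.

# Coordinate model

All coordinates are 0-based half-open (`[start, end)`), the
BED/narrowPeak convention; summits are stored as absolute positions rather
than offsets. Peak tables converted between genome builds do not always
document their base; fixing one convention internally and converting at
the file boundary eliminates the off-by-one error class. An interval never
covers its `end` position, and extracted sequence windows
`[center - flank, center + flank)` always have exactly `2 * flank` bases,
with `N`-padding beyond chromosome ends.

# Consensus summit detection

All summit positions from all samples on a chromosome are pooled and
smoothed with a triangular kernel of half-width `bandwidth` (default
20 bp):

$$d(x) = \sum_i \max\!\left(0,\; 1 - \frac{|x - s_i|}{b}\right).$$

Positions whose density is positive and not exceeded anywhere within
±`span`/2 (default span 100 bp) are candidate maxima. Plateaus of equal
density collapse to their integer midpoint (rounding down). Candidates are
then accepted greedily in order of density descending, position ascending;
a candidate within `span` of an accepted summit is rejected. Accepted
summits are elongated by `elongation` (default 100 bp) per side and
adjacent overlapping intervals are both cut at the midpoint of their
overlap (odd widths round down, so the left peak keeps the boundary base),
yielding pairwise disjoint consensus peaks of width at most
`2 * elongation` = 200 bp.

## Numerical choices

* **Exact kernel sums, not a density estimator.** Each summit contributes
  the integer weight $(b - |x - s_i|)^+$ on the 1-bp grid; the density is
  that integer sum divided by $b$. Integer sums are exact in doubles, so
  plateau and tie detection can use exact equality and the result is
  bit-reproducible. Generic kernel density estimators normalise globally
  and evaluate on an interpolated grid, which introduces numerical noise;
  the `density_floor` parameter (default 1e-15) exists to zero such noise
  and is retained as a configurable no-op here — with exact sums every
  positive density is at least $1/b$, which the test suite asserts.
  Convolution is done by direct multiply-add (`stats::filter`), not FFT,
  again for exactness.
* **Ties.** Equal-density maxima are taken leftmost-first in the greedy
  step; the "within span" rejection is inclusive (distance ≤ span). Both
  choices are arbitrary but deterministic; two summits 70 bp apart in
  different samples merge at span 100 and stay separate at span 60, which
  fixes the inclusive reading.
* **Accuracy.** With bandwidth 20 the mode of the summed kernels sits
  within about ±10 bp of the true site when per-sample summits jitter by a
  few bp; the recovery tests assert exactly this bound under uniform
  ±5 bp jitter across six samples.

## Per-sample metrics

A sample is *present* at a consensus peak iff one of its original peak
summits lies inside the consensus interval — the literal "original peak
within the area of the consensus peak" reading, rather than the pairwise
50% rule, which belongs to set-vs-set comparison. When present, FE and
q-value come from the highest-FE contained peak; when absent they can be
read from the sample's FE/q bedGraph score tracks at the consensus summit
(tracks are built with a pseudocount of 1:
`FE = (treat + 1) / (control + 1)`), else default to 0. `n_cell_types`
counts cell types with at least one present sample, so duplicate samples
of one cell type count once.

## Distance sensitivity sweep

The sweep reruns the consensus stage with span = `d` and elongation =
`d/2` for a grid of maximal summit distances `d` (60–500 bp), reporting
the total number of consensus peaks and the number present in all cell
types. Larger `d` merges more summits, so the total count is
monotonically non-increasing — a property the suite asserts. Note that
with elongation `d/2` the consensus interval is only `d` wide, so at small
`d` a merged-away summit can fall outside the interval and presence
counting is conservative; the default analysis (span 100, elongation 100)
does not have this edge because intervals are twice the span's half-width.

# Overlap rules

Two peaks overlap when **more than** half of the narrower peak is covered
by the wider one; the inequality is strict, so an exactly-50% overlap does
not qualify. Equal widths treat the first argument as narrower (the
result is unaffected). Pairwise set comparisons report the proportion of
the *smaller* set with at least one qualifying partner (and the symmetric
figure for the larger set). For the stimulated/unstimulated partition a
qualifying pair defines one common locus; peaks are matched 1:1 greedily
in genomic order, so each peak is counted at most once — how one-to-many
overlaps were deduplicated originally is not documented, so the 1:1 rule
is our documented choice, not a claim about the original behaviour.
Percentages are rounded half-up to two decimals; one-decimal figures
reproduce by re-rounding.

# DR3 motif screening

The representative DR3 motif is built from the IUPAC consensus
`RGGTCANNGRGTTCA`: an unambiguous base receives probability
`match_prob` (default 0.997) with the remainder split over the other
bases, `R` splits `match_prob` over A/G, `N` is uniform; probabilities are
floored at 0.001 and columns renormalised. Scores are natural-log odds
against a uniform background, summed over positions; `N` in the sequence
scores `ln(0.001/0.25)`; minus-strand scores use the reverse complement.
Scanning considers every start where the whole motif fits inside the
`[summit - flank, summit + flank)` window (default flank 100 bp), both
strands, and reports the best hit strictly above the threshold (ties:
smaller offset, then `+` strand).

The motif's native threshold 9.184643 and the sweep floor of 4 are carried
as defaults because they are the operating points of interest for this
motif; they are ordinary parameters, and no claim is made that this score
scale coincides with scanners that use GC-adjusted backgrounds — the
comparative structure (threshold sweeps, FE-ranked percentage curves,
density profiles), not any absolute percentage, is the contract.
Accordingly the analysis exposes:

* `dr3_threshold_sweep()` — percentage of peaks with a hit per threshold
  (non-increasing by construction, computed from one pass of best scores);
* `motif_density_profile()` — all hits (not just best) binned by offset in
  ±500 bp, normalised to hits per peak per bp;
* `fe_window_curve()` — peaks ranked by FE (ties broken by genomic
  position for determinism), cut into consecutive windows of 100, per
  window the mean FE and the percentage with a hit above the native
  threshold; an incomplete trailing window is dropped;
* `motif_snp_distance()` — signed distance from the motif's central
  nucleotide (`start + 7` for the 15-mer) to the nearest SNP, negative
  when the SNP is upstream; equidistant neighbours resolve to the
  upstream SNP (a documented tie-break; the convention's source is silent
  on ties), and chromosomes without SNPs yield `NA`.

# The synthetic-data generator

`simulate_dataset()` draws, from one seed and in a fixed order (genome →
truth → samples):

1. an i.i.d. random genome at a configurable base composition;
2. true binding sites spaced at least `min_spacing` apart, each active in
   `k` cell types with `k` drawn from a sharing distribution whose default
   follows the observed six-cell-type specificity proportions (75.61% in
   one cell type, 21.12% in two, 2.00%, 0.76%, 0.31%, 0.18%); per active
   (site, cell type) a state drawn as stimulated-only / unstimulated-only
   / both with default probabilities 0.599 / 0.276 / 0.125, matching the
   observed unique-stimulated / unique-unstimulated / common partition;
   one log-normal FE per site (meanlog `log 4`, sdlog 0.5, a realistic
   MACS2-scale FE range of roughly 1.5–11) and a DR3 motif planted with
   probability `plogis(-3 + 0.8 · FE)`, giving the sigmoidal
   motif-vs-occupancy relationship the FE-window curve is designed to
   expose;
3. per-(cell type, state) samples: one peak per active site with summit =
   true position + integer jitter uniform on ±5 bp (the regime in which
   consensus accuracy of ±10 bp is claimed), interval = summit ± 150 bp,
   stimulated FE multiplied by 1.5 to mirror the stronger stimulated
   signal, and a constant q-column above the FDR < 1% cutoff (the
   q-value model of the peak caller is out of scope). Planted motifs are
   written into the genome with bases drawn from the PWM at fidelity
   0.99, centred on the site, on a random strand.

The configuration requires only `min_spacing > motif length + 2 · jitter`
— enough to keep motif edits and site neighbourhoods from colliding — so
that deliberately tight fixtures (e.g. 120 bp spacing) can exercise
midpoint truncation, which spacings above `2 · elongation` never would.

**What the generator does not emulate:** read-level noise and mappability,
irregular peak widths, correlated jitter between samples, background
(false-positive) peaks, GC-biased genome composition, and q-values that
vary with signal. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical structure, not robustness to every
artefact of real ChIP-seq data.

# Validation strategy and problem sizes

Every core operation is tested against an independently written
brute-force oracle (all-pairs overlap enumeration, exhaustive grid
evaluation for consensus maxima, exhaustive offset × strand motif
enumeration, linear-scan nearest-SNP), with exact equality required.
Statistical recovery uses fixtures of 200 sites × 6 samples on 1 Mb for
consensus accuracy, 3 000 sites on 2 × 1 Mb for the specificity-category
histogram (compared exactly against the realised truth and within 3σ of
the configured multinomial), and 2 000 peaks for motif-fraction recovery
(3σ binomial plus a 2-point allowance for fidelity-0.99 emission losses)
and the FE-window monotonicity check (Spearman > 0.8 over 20 windows).
These sizes give the statistical assertions comfortable power while
keeping the full suite around a minute of runtime.

# Known limitations

* Exact numeric equality with pipelines built on normalised
  kernel-density estimators is not guaranteed (their grids and
  normalisation differ); positions agree within the stated ±10 bp
  accuracy.
* Score-scale parity with HOMER is not claimed (see above), so published
  absolute DR3 percentages are not reproduction targets.
* The 1:1 greedy common-locus matching and the leftmost tie-breaks are
  documented choices where the original method is silent.
* Chromosome-scale memory: the density grid is materialised per
  chromosome (8 bytes/bp plus the sliding-max workspace), which is fine
  for human-genome chromosomes but not for multi-Gb contigs.
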