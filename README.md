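# vdrmeta

Meta-analysis of vitamin D receptor (VDR) ChIP-seq peak sets across
multiple cellular models and stimulation states.

Genome-wide VDR binding has been profiled in several human cell types,
each with and without stimulation by the receptor's ligand
1α,25-dihydroxyvitamin D₃. Every sample brings its own peak calls, summit
positions, fold enrichments (FE) and q-values; comparing them requires a
single non-redundant catalogue of binding locations and a consistent set
of overlap and motif statistics. `vdrmeta` provides that pipeline for
anyone working with MACS2-style peak calls from multiple samples:

* **Consensus summits.** All per-sample summits are pooled per chromosome
  and smoothed with a triangular kernel, d(x) = Σᵢ max(0, 1 − |x − sᵢ|/b)
  with bandwidth b = 20 bp. Local density maxima selected with a 100 bp
  span are the consensus summits (accurate to about ±10 bp); elongating
  each by 100 bp per side and truncating overlaps at their midpoint gives
  pairwise disjoint consensus peaks of ≤ 200 bp. Kernel sums are computed
  exactly on the integer grid, so results are bit-reproducible.
* **Overlap statistics.** Two peaks overlap when more than 50% of the
  narrower peak is covered by the wider one (strict inequality). On top of
  this rule: pairwise set comparisons referenced to the smaller set,
  stimulated/unstimulated partitions into unique/common loci, and
  cell-type-specificity category counts (peaks present in exactly k of K
  cell types).
* **DR3 motif screening.** Log-odds scanning for the classical VDR-RXR
  response element `RGGTCANNGRGTTCA` (direct repeat of two hexamer
  half-sites spaced by 3 nt) in ±100 bp summit windows on both strands:
  score(seq) = Σⱼ ln(pⱼ(baseⱼ)/q(baseⱼ)), with threshold sweeps,
  summit-centred motif density profiles, FE-ranked DR3-percentage curves
  and signed motif-to-SNP distances.
* **Synthetic studies.** A seeded generator produces a genome FASTA with
  planted motifs, per-sample narrowPeak files with jittered summits and
  truth tables, so the whole pipeline can be validated against known
  ground truth.

## Worked example

```r
library(vdrmeta)

# a synthetic 3-cell-type study with known ground truth
cfg <- simulation_config(seed = 7, n_true_sites = 80, chrom_length = 3e5,
                         min_spacing = 500, K_cell_types = 3)
sim <- simulate_dataset(cfg)
sim$samples[[1]]
#> <sample_set> cellA_stim (cellA, stimulated): 20 peaks

# consensus stage: pooled summit density -> summits -> disjoint peaks
summits <- find_consensus_summits(sim$samples)
peaks   <- build_consensus_peaks(summits)
cons    <- assign_sample_metrics(peaks, sim$samples)
cons
#> <consensus_set> 80 consensus peaks x 6 samples (3 cell types)
head(as.data.frame(cons)[, c("chrom", "start", "end", "summit", "n_cell_types")], 3)
#>   chrom start   end summit n_cell_types
#> 1  chr1 12429 12629  12529            1
#> 2  chr1 17855 18055  17955            1
#> 3  chr1 23009 23209  23109            1

# how cell-type specific is binding? (sites in exactly 1, 2, 3 cell types)
specificity_categories(cons, K = 3)
#>  1  2  3
#> 63 16  1

# stimulated vs unstimulated partition for one cell type (FDR < 1% peaks)
unlist(stim_unstim_partition(filter_fdr(sim$samples[["cellA_stim"]]),
                             filter_fdr(sim$samples[["cellA_unstim"]])))
#>   unique_stim unique_unstim        common
#>            15             9             5

# DR3 motif rate below the summits of the stimulated cellA sample
pw <- pwm_dr3()
dr3_threshold_sweep(sim$samples[["cellA_stim"]], sim$genome, pw,
                    thresholds = c(4, 9.184643))
#>   threshold pct_with_hit
#> 1  4.000000           35
#> 2  9.184643           35

# best DR3 hit at the first consensus summit
scan_summit_region(pw, sim$genome, cons$peaks$chrom[1], cons$peaks$summit[1])
#> $offset
#> [1] -7
#> $strand
#> [1] "-"
#> $score
#> [1] 16.59647
```

All 80 planted sites are recovered as consensus peaks; 63 are specific to
one cell type. The threshold sweep says 35% of the stimulated sample's
peaks carry a DR3-type sequence in ±100 bp of the summit — identical at
thresholds 4 and 9.18 here because planted motifs are near-perfect copies.
The best hit at the first consensus summit starts 7 bp upstream of the
summit (motif centred on it) on the minus strand, at the motif's maximal
score 16.60.

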