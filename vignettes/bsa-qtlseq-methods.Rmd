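---
title: "Bulked-segregant QTL-seq scans with bsaqtl: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant QTL-seq scans with bsaqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
library(bsaqtl)
library(dplyr)
```

## The problem

Bulked-segregant analysis (BSA) by whole-genome sequencing — QTL-seq —
locates large-effect loci in a segregating population without genotyping
every individual. Two pools of phenotypic extremes are formed from an F2
population (here, a salt-tolerant T-pool and salt-sensitive S-pool of 40
lines each, screened by relative shoot length under salt stress), each pool
is sequenced as one DNA sample, and per-SNP allele frequencies in the two
pools are compared along the genome. Away from any causal locus both pools
sample the same 1:2:1 segregation and their allele frequencies agree up to
sampling noise; near a causal locus the pools are enriched for opposite
parental alleles and the frequencies diverge.

`bsaqtl` implements the complete desk side of this design: a synthetic
F2-cross generator with known truth, the phenotype utilities used to build
and sanity-check the bulks, the two genome-scan statistics with their
smoothing and significance thresholds, region calling and two-method
intersection, and the post-scan candidate-gene triage against
differential-expression tables.

## The scan statistics

For a biallelic SNP with `ref`/`alt` read counts in a pool, the **SNP-index**
is the fraction of reads carrying the allele that differs from the
reference, `alt / (ref + alt)`. The **ΔSNP-index** is the S-pool index minus
the T-pool index (the sign convention is configurable; the default follows
the subtract-T-from-S convention and is recorded in every output header).
Under the null its expectation is 0; at a fixed causal locus it approaches
±1.

The **Euclidean distance (ED)** statistic compares the pools' four-base
frequency vectors at the SNP:

$$
ED = \sqrt{(A_T - A_S)^2 + (C_T - C_S)^2 + (G_T - G_S)^2 + (T_T - T_S)^2}
$$

which is 0 for identical pools and $\sqrt{2}$ for pools fixed for
different alleles. At a biallelic site this reduces to
$\sqrt{2}\,\lvert p_T - p_S \rvert$ with $p$ the alt-allele frequency —
`compute_scan()` uses the closed form, and the test suite checks the two
routes against each other.

```{r ed}
euclidean_distance(c(0.7, 0.3, 0, 0), c(0.4, 0.6, 0, 0))  # sqrt(0.18)
```

## Smoothing

Raw per-SNP statistics are dominated by read-sampling noise. `fit_scan()`
smooths each statistic with a tricube-weighted sliding window: at every SNP
the fitted value is the weighted mean of all SNPs within a physical
half-width $h$ on the same chromosome, with weights
$w = (1 - (|d|/h)^3)^3$. The kernel preserves constants, has compact
support, never crosses a chromosome boundary, and is trivially re-computable
by brute force — which is exactly how the tests check it. Following the ED
literature, raw ED is raised to a power (default 4) before smoothing to
suppress background noise relative to signal. Windows containing fewer than
`min_window_snps` markers (default 10) yield `NA` rather than an unstable
estimate.

Defaults: half-width 1 Mb, evaluated at every SNP. These are declared
package defaults, not values inferred from any reference output; both are
arguments of `fit_scan()`.

## Significance thresholds

**ΔSNP-index.** The null bound is simulated, conditional on read depth
(`delta_null_bounds()`): each pool's true allele frequency is drawn as the
mean of `2 * bulk_size` Bernoulli(0.5) chromosomes (1:2:1 F2 segregation),
read counts are binomial at the marker's depth, and the 95th/99th
percentiles of |Δ| form the per-marker bounds. A marker's depth pair
$(d_T, d_S)$ is mapped to the effective per-pool depth
$d_\mathrm{eff} = 2/(1/d_T + 1/d_S)$ — the harmonic mean, which preserves
the read-noise variance $\propto 1/d_T + 1/d_S$ — so simulation runs once
per unique effective depth. The bound-versus-depth curve is made monotone
non-increasing by isotonic regression (pooled adjacent-violators averaging),
removing Monte-Carlo wiggles. Default 10,000 simulations per depth.

**ED.** Two cutoffs are provided, and choosing between them was a genuinely
open design point:

* `ed_threshold()` — median + 3·SD of the genome-wide fitted values, with
  the SD taken about the median. A robust location/scale rule of this kind
  presumes that the genome-wide distribution of fitted values is dominated
  by background, which holds for a full-size genome (a dozen chromosomes)
  where a QTL's linkage footprint is a small fraction of all markers.
* `ed_null_threshold()` — an empirical genome-wide null threshold: whole
  no-QTL scans are simulated over the observed marker map and depths
  (pool chromosomes as Markov-chain gametes with Haldane recombination,
  binomial reads, identical powering and smoothing), and the threshold is a
  quantile (default 0.95) of the per-replicate genome-wide maxima — the
  permutation-threshold idea familiar from QTL interval mapping.

The pipeline default is the null-simulation threshold. The reason is a
failure mode we consider decisive: on a compact simulated genome (one
30-Mb chromosome), a strong QTL's linkage footprint elevates the majority
of fitted values, so the observed median and SD measure signal rather than
background and the robust cutoff can float above the true peak, calling
nothing at all. The null-simulation threshold does not read the observed
statistic values and is immune to this contamination; on a full-size
genome the two approaches agree in character. `ed_threshold()` remains
exported and tested for the multi-chromosome setting it suits.

## Region calling and the two-method candidate region

`call_regions()` marks a SNP as passing when |fitted Δ| exceeds its
simulated bound (95% by default, 99% also computed) or when fitted ED
exceeds the ED threshold, takes maximal runs of consecutive passing SNPs,
and merges runs separated by at most `merge_gap_bp` (default 500 kb).
Region bounds are the outermost passing SNP positions; Δ-method bounds are
then rounded outward to a 10-kb grid — matching the reporting convention of
window-based ΔSNP-index scans — while ED regions keep raw SNP positions.
Region size is reported as `(end − start)/1e6` Mb, rounded to two decimals,
the convention under which a region table’s coordinates and sizes stay
mutually consistent.

The candidate region of the two-method design is the intersection
(`intersect_region_sets()`): every same-chromosome overlap of positive
length between a Δ region and an ED region, labelled `"common"`.

```{r intersect}
delta_regions <- region_table(c("chr1", "chr1", "chr7"),
                              c(4590000, 7800000, 20160000),
                              c(7270000, 10720000, 24330000),
                              "delta_snp_index")
ed_regions <- region_table(c("chr7", "chr7"),
                           c(6942377, 12547138),
                           c(12109211, 26674659), "ed")
intersect_region_sets(delta_regions, ed_regions)
```

## The synthetic F2 experiment

`simulate_cross()` emulates the study design the scan is meant for:

* **Population**: 983 F2 lines by default, genotypes coded 0/1/2 as counts
  of the tolerant-parent allele, segregating 1:2:1 at every marker.
* **Linkage**: each gamete is a two-state Markov chain along the marker
  map; adjacent-marker recombination fractions come from the Haldane map
  function applied to physical distance at 4 cM/Mb — a rice-typical
  genome-wide average, configurable. No interference is modelled.
* **QTL**: one additive locus (dominance coefficient configurable, default
  0 — the usual first model for a single large-effect locus) placed at the marker nearest the requested position. The additive
  effect is scaled so the QTL explains a requested fraction of phenotypic
  variance (default 0.249) given the Gaussian residual; the trait is an
  RSL-like unitless ratio centred at 0.6 with residual SD 0.15.
* **Bulks**: `select_bulks()` takes the 40 largest and 40 smallest trait
  values (stable sort by value then line id; boundary ties warn).
* **Sequencing**: `simulate_pool_depths()` draws each pool's total depth
  from a truncated-at-≥1 Poisson with mean 27.6 (the study-scale mean
  pool depth; a fixed-depth model is also available) and the alt count as
  Binomial(depth, pool allele frequency). Reads sample pooled chromosomes
  exactly.

What the generator deliberately does **not** model: sequencing and
alignment error, reference bias, duplicated or repetitive regions,
depth overdispersion beyond Poisson, structural variation, multi-QTL
architectures and epistasis, and the F2-versus-F2:3 distinction (the
pooled DNA is taken to be the phenotyped line's own F2 genotype, as leaves
of the sequenced F2 individuals were). Passing the recovery tests
therefore shows the statistics, thresholds and interval logic are
internally sound at a realistic signal-to-noise ratio — not that the
pipeline is robust to every artefact of real resequencing data, which is
why the marker filters in `read_allele_depths()` (per-pool depth floor of
7, 99th-percentile depth cap, parent-informativeness when parents are
available) still matter on real inputs.

The phenotype side mirrors the screening workflow: `relative_value()`
(treatment/control, with zero-control records excluded and logged),
`diagnose_distribution()` (bias-corrected skewness and excess kurtosis;
a trait is flagged QTL-suitable when both absolute values are below 1),
and `compare_pools()` (medians, quartiles and a two-sided rank-sum test —
chosen over a t-test because relative root traits are zero-inflated).

## Candidate-gene triage

After mapping, `genes_in_region()` selects annotated genes overlapping the
common region (any-overlap by ≥1 bp, the inclusive convention; full
containment is available by flag since reported gene lists rarely state the rule, so it is not explicit).
`candidate_filter()` keeps those significant in at least one designated
within-variety salt-response contrast (default `IRvsTIR`, `WGvsTWG`) under
the strict rule FDR < 0.05 (equivalently −log10 FDR > 1.3), with no
fold-change cutoff by default (an optional |log2 ratio| threshold exists
but is off, as significance in the source analyses was FDR-only), ranked
by minimum FDR across designated contrasts — a deterministic order chosen
for output stability. `venn_partition()` produces the 15-subgroup
partition of four contrast sets with percentages of the union;
`ddct_relative_expression()` implements 2^−ΔΔCt for qRT-PCR confirmation;
and `genotype_anova()` is the one-way fixed-effects ANOVA used to validate
a single marker's genotype classes against the trait, with `tidy()` and
`glance()` accessors.

## Numerical and degenerate-input choices

* Ties at a bulk-selection boundary are resolved by line id (stable sort)
  and warned about, never broken randomly.
* Markers below the per-pool depth floor get no SNP-index (`NA`) and are
  dropped from the scan with a counted message.
* Constant trait vectors have undefined moments: flagged unsuitable rather
  than returning `NaN`.
* An all-equal fitted-ED vector makes the robust threshold equal that value
  with a warning (no region can exceed it).
* A genotype ANOVA on zero-variance data returns F = 0, p = 1 rather than
  0/0.
* `classify_deg()` treats a significant call with log2 ratio exactly 0 as
  directionless (`ns`, with a warning).
* All randomness flows from one integer seed through named per-stage
  streams, so `simulate`, `scan` and `candidates` can be re-run
  independently and reproduce byte-identical outputs; every output file
  header records the seed and a configuration hash.

## Validation problem sizes

The test suite and the acceptance script validate the pipeline at the
study's design point — 983 lines, bulks of 40, QTL PVE 0.249, mean depth
27.6×, 5,000 markers on a 30-Mb chromosome, 20 independent replicates —
and calibrate the Δ null bounds on a no-QTL genome of 12 chromosomes ×
834 markers at fixed depth 30. Smaller configurations (a few hundred lines
and markers) exercise composition, determinism and the degenerate paths.
These sizes are the package's own validation choices: large enough that
the binomial and segregation asymptotics the thresholds rely on hold,
small enough to re-run routinely.

## A compact end-to-end example

```{r pipeline}
cfg <- pipeline_config(
  seed = 11,
  sim = sim_config(n_lines = 200, bulk_size = 25, chrom_length_bp = 10e6,
                   n_snps_per_chrom = 400, qtl_pve = 0.3),
  smoothing = list(min_window_snps = 5),
  thresholds = list(n_sims = 1000, ed_null_reps = 3),
  candidates = list(n_genes = 50, n_causal = 3))
out <- file.path(tempdir(), "demo_run")
manifest <- run_pipeline(cfg, out)
manifest
```

```{r plot, fig.alt = "Delta SNP-index scan with fitted line and called regions"}
scan <- readr::read_tsv(file.path(out, "scan.tsv"), comment = "#",
                        show_col_types = FALSE)
class(scan) <- c("bsa_scan", class(scan))
regions <- readr::read_tsv(file.path(out, "regions.tsv"), comment = "#",
                           show_col_types = FALSE)
common <- region_table(regions$Chromosome[regions$Method == "common"],
                       regions$Start[regions$Method == "common"],
                       regions$End[regions$Method == "common"], "common")
autoplot(scan, "delta", regions = common)
```

## Known limitations

* The ICIM regional linkage mapping that would further narrow such an interval
  (LOD/PVE/additive-effect estimation from a KASP genetic map) is out of
  scope; the package stops at the two-method candidate region and its gene
  triage.
* The Δ null model assumes independent pools; with bulks drawn from one
  finite population the pools are very weakly negatively correlated, a
  second-order effect at 40 + 40 out of 983.
* The simulated DEG tables model marginal significance only (uniform null
  FDRs, planted causal responses), not correlation between contrasts or
  expression covariance along the genome.
* Depth is Poisson; real pooled libraries are overdispersed, so real-data
  null exceedance rates can run slightly above the simulated calibration.
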