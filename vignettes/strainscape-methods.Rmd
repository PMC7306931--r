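---
title: "Methods and numerical conventions in strainscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical conventions in strainscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainscape)
```

strainscape packages the inference machinery of a bacterial
population-genomics study of isolates sampled across structured habitats
(ponds, water versus sediment): coalescent-simulation-based ABC for
effective population size and divergence times, Heaps-law pan-genome
openness, recombination-event classification by habitat, and Fisher-exact
SNP–environment association. This vignette documents the models, the
tunable parameters, the numerical conventions, and what the synthetic-data
generators do and do not emulate.

## The coalescent simulator

`simulateGenealogy()` and `simulateLocus()` implement the haploid Kingman
coalescent in continuous time. With *k* lineages in a population of *N*
individuals, the waiting time to the next merger is Exponential with rate
C(*k*, 2)/*N* and a uniformly random pair merges. Two demographies are
supported:

* **single** — one constant-size population;
* **split** — two or more demes of size `ne` each coalescing internally
  until their own divergence time `tDiv` (generations), at which point
  surviving lineages join an ancestral pool of size `neAnc` that coalesces
  to the root. Demes attach to a single ancestral pool (star-like), which
  accommodates per-deme divergence ages.

Assumptions and choices:

* **Haploid scaling.** The coalescence rate C(*k*, 2)/*N* makes
  θ = 2·*N*_e·μ per site. The same scaling is used in the simulator, the
  statistics and the ABC, so estimates are internally coherent. (A
  diploid-scaled reading of the same machinery would halve the estimates.)
* **Continuous time.** The exponential approximation to discrete
  generations is standard and its error is negligible for *N*_e ≥ 10³.
* **Ancestral pool size.** Not separately identifiable in the intended use;
  defaults to `ne`. It is exposed as `neAnc` for sensitivity analysis.
* **Mutation.** Infinite-sites: each branch of length *t* receives
  Poisson(μ·L·*t*) mutations, each creating a new segregating site at a
  uniform continuous position in [0, L), carried by all descendants of the
  branch. No recombination within the locus, no migration after
  divergence, no growth. The default rate μ = 2.2 × 10⁻¹⁰ per site per
  generation is the *E. coli* estimate conventionally applied to
  environmental *Vibrio*.

The simulator is written twice on purpose: a readable R path
(`simulateGenealogy()` + `dropMutations()`, which works on `ape::phylo`
trees) and a compiled batch path used by the ABC loop. Both consume the
R RNG in the same order, and a test asserts that the compiled summaries
equal the R statistics on the same stream. The site-count distribution is
additionally cross-checked against an independent coalescent simulator
(msprime) by a two-sample Kolmogorov–Smirnov test.

## Diversity statistics

`segregatingSites()`, `nucleotideDiversity()`, `wattersonTheta()` and
`tajimasD()` follow the textbook definitions: π is the mean pairwise
difference divided by C(*n*, 2) (per site when divided by L), θ_w =
S/a_{n−1}, and *D* uses the Tajima (1989) constants. Conventions:

* **Missing calls** (draft genomes imply gaps) contribute
  pairwise-complete averages to π — each site contributes
  2·c·(n_obs − c)/(n_obs·(n_obs − 1)) — and a site is segregating only if
  at least two states are observed. Watterson's θ and the *D* constants
  use the full sample size *n*.
* **n = 3 has no Tajima's *D*.** The variance constants c₁ and c₂ vanish
  identically at *n* = 3, so *D* is 0/0 there. `tajimasD()` returns `NA`
  with a warning rather than a floating-point artefact; three-sequence
  groups are summarised by `subsampledD()` instead, which resamples *k*
  haplotypes with replacement (default *k* = 10, 1000 replicates,
  duplicates counted as distinct, so the constants use *n* = *k*) and
  reports the median over replicates with variation.
* **Windows.** `windowedD()` partitions [0, L) into `nWindows` (default
  1000) equal, non-overlapping windows — the simplest reading of a
  windowed scan when no stride is given — and excludes windows without
  variation from the mean and SD, since *D* is undefined there. With a
  single usable window the SD is `NA`.
* **Undefined statistics signal loudly.** Invariant data yield `NA` plus a
  warning, never a silent 0.

A brute-force oracle (explicit pair loops, independently written
constants) pins all three statistics to 10⁻¹² relative accuracy on 200
random matrices, and a worked 4-haplotype example is fixed in the tests
(S = 3, π_total = 10/6, θ_total = 18/11, D ≈ +0.168).

## Rejection ABC

`rejectionAbc()` draws parameters from their priors (log-uniform by
default: *N*_e over 10⁵–2 × 10⁷ individuals, divergence times over
10³–4 × 10⁶ generations), simulates a locus per draw at the template's
sample size, locus length and mutation rate, and computes the
four-component summary vector (S, genome-wide *D*, windowed-*D* mean and
SD). The distance to the observed vector is Euclidean after standardizing
each component by the simulated pool's median absolute deviation — robust
to the heavy-tailed S distribution produced by a log-uniform prior.
Components undefined in the observation are dropped; simulations with an
undefined component where the observation has one get infinite distance
(an invariant simulation says nothing about a variable observation). The
`ceiling(tol × nSims)` smallest distances are accepted (default
tol = 0.0005, i.e. the 0.05 % threshold; nSims = 100,000), and the
posterior is summarised by the accepted draws' median and 2.5/97.5
percentiles.

`twoStageAbc()` narrows every prior to the [min, max] of the accepted
draws and repeats the run; the first stage is kept in `@stage1`. A
degenerate accepted set (a single value) is widened by ±10 % with a
warning. For the three-sub-clade split model the joint posterior has four
parameters (one shared *N*_e plus three divergence times); a per-deme
divergence time can also be held fixed by omitting its prior.

Desk-scale tests use 20,000 simulations at tol = 0.005 (100 accepted), a
deliberate scale-down of the full 100,000/0.05 % protocol that preserves
the accepted count.

### A limitation worth knowing about

At the desk scale just described, the *second* stage is not reliably
narrower than the first. The reason is structural: with 20,000 draws and
0.5 % acceptance, the stage-1 effective tolerance band (the spread of S
among accepted simulations attributable to the acceptance cut) is already
far below the coalescent sampling SD of S (≈ 530 sites at n = 6,
*N*_e = 10⁶), so both stages approximate the same posterior and the width
comparison between them is dominated by quantile-estimation noise on 100
accepted draws. Across 50 independent recovery replicates the mean
stage-2/stage-1 CI-width ratio is ≈ 0.90 — a real but small systematic
narrowing — while the per-replicate "stage 2 narrower" indicator holds
only ~64 % of the time. Median recovery (within a factor of 3 of the
generating *N*_e) and 95 % CI coverage are unaffected and pass at 20/20 in
the acceptance suite. Prior narrowing remains worthwhile for its original
purpose — concentrating simulation effort — but should not be expected to
shrink credible intervals when the acceptance count is already
likelihood-limited.

## Pan-genome analysis

`classifyFamilies()` partitions families by presence count: core =
present in at least ⌈`coreFraction`·G⌉ genomes (default 0.95 — the
ceiling because "at least 95 %" is a lower bound), unique = exactly one
genome, accessory = the rest; core wins where both definitions apply.

`geneAccumulation()` counts first discoveries per position over random
genome orderings (default 1000), and `fitHeaps()` fits
n_new(N) = κ·N^(−α) by least squares of log(count) on log(N) over the
pooled (permutation, position) points with N ≥ 2. Zero counts are
log-undefined and excluded, with their fraction recorded; when ≥ 95 % of
the N ≥ 2 points are zero the fit short-circuits to the degenerate closed
result (α = +∞). Classification is closed iff α > 1. `subsampleAlpha()`
repeats the fit on random k-genome submatrices (default k = 3, 1000
replicates, families absent from the subsample dropped first, as any real
3-genome dataset would) and reports the majority call.

### The pan-genome generator

`genPangenomeMatrix()` needs care because the accumulation curve is fitted
over *random orderings* of a fixed matrix. A naive sequential construction
("genome N introduces Poisson(κ·N^(−α)) new singleton families") is not
exchangeable: permuted, its discovery curve flattens and the planted α is
unrecoverable. The generator therefore plants the decay in an
order-invariant way. For a family present in a uniformly random subset of
exactly *m* of G genomes, the probability that it is first discovered at
position N of a random ordering is a known hypergeometric expression
h(N, m). The generator solves a non-negative least-squares problem for the
expected number of families per presence class, f_m ≥ 0, such that
Σ_m f_m·h(N, m) = κ·N^(−α) for every N, draws the class counts as
independent Poissons, and places each family in a uniformly random subset
of its class size. By Poisson thinning, the number of families first seen
by the N-th genome is then Poisson with mean κ·N^(−α) under *every*
ordering — the fitted model is correct on average by construction, and the
matrix is exchangeable. Core families are simply present everywhere.
κ = 0 (or `accessory = FALSE`) produces the degenerate closed pan-genome
of identical genomes. The NNLS is solved by a small cyclic
coordinate-descent routine (the design matrix is ill-conditioned) and the
residual decay curve is exact to within a few percent at the tail for
α ≤ 2. Default κ = 1000 and core size 1254 match the order of magnitude of
fitted intercepts and core sizes in real multi-strain *Vibrio*
collections.

## Distances, trees and grouping

* **Nei (1972)**: D = −ln(J_xy / √(J_x·J_y)) from per-locus
  allele-frequency profiles; groups sharing no alleles anywhere get an
  `Inf` sentinel.
* **Bitwise distance**: pairwise proportion of differing alleles among
  pairwise-complete sites; a pair with no complete site gets `NA`.
* **Jaccard event profiles**: per strain, the set of recombination-event
  ids it participates in; dissimilarity 1 − |∩|/|∪|. Two strains with no
  events at all sit at distance 1 by convention — an empty profile carries
  no evidence of similarity. Profiles over recombinant gene families are
  available via `profile = "family"`.
* **UPGMA / NJ** delegate to `stats::hclust(method = "average")` and
  `ape::nj`; UPGMA output is ultrametric with node heights at half the
  merge distance, and NJ recovers additive trees exactly (both are
  asserted in tests).
* **Threshold grouping** (`thresholdGroups()`, default t = 0.001 as used
  for sub-clade definition on Nei distances) takes *single-linkage*
  connected components of the graph with edges where d < t — the natural
  reading of "genomes closer than t were grouped" — with complete linkage
  behind a flag. Group labels are deterministic (numbered by smallest
  member id).
* **Recombination categories**: each strain-pair event falls in exactly
  one of SPSE/SPDE/DPSE/DPDE by pond and environment agreement.
  Normalized counts divide the raw counts by the product of pan-genome
  size, strain count and the category's mean patristic distance on a
  supplied tree. These factors are *injected*, not recomputed: the
  product-denominator form is a declared convention, and callers who
  normalize differently can pass 1s. Multi-sequence events are decomposed
  into unordered pairs by `readEventList()`.

## SNP–environment association

Coordinates are 0-based and half-open everywhere (the VCF-like writer
emits 1-based POS, as that dialect requires). `extractSnps()` keeps
alignment columns with ≥ 2 distinct unambiguous bases; gaps and ambiguity
codes become missing calls. `filterBiallelic()` keeps sites with exactly
two observed alleles; `filterMaf()` (defaults: MAF ≥ 0.05, minor allele in
≥ 3 samples) drops sites *strictly below* the MAF threshold — ties at
exactly 0.05 are kept, flag-controlled — and both filters are idempotent.

`fisherAssoc()` counts one allele observation per haploid sample (no
diploid genotype conventions), builds the per-site 2 × 2 allele-by-
environment table, and computes the conventional two-sided Fisher exact
p by point-probability summation, with a mid-p variant behind a flag.
Bonferroni uses m = the number of sites actually tested (post-filter,
post-exclusion); sites with all calls missing in one environment are
excluded and reported. Significance is adjusted p < 0.01.
`privateAlleles()` counts alleles observed in exactly one group of a
grouping variable (pond, environment or clade). `mapWindows()` bins
significant positions into half-open 1-kb windows (non-overlapping — the
default reading of "moving by 1 kb") and attaches gene families whose
intervals overlap occupied windows via IRanges.

## The synthetic-data generators

`genSampleMetadata()` emulates the sampling design (nine ponds × two
habitats). `genSnpDataset()` draws one shared derived-allele frequency per
background site from Uniform(`mafFloor`, 1 − `mafFloor`); each planted
site receives water/sediment frequencies differing by exactly `effect`,
with the water frequency drawn uniformly over the interval that keeps both
group frequencies in [0, 1] *and* the pooled frequency inside
[`mafFloor`, 1 − `mafFloor`], so planted sites survive a MAF filter at
`mafFloor`; at `effect = 1` the interval collapses to complete separation
(0 versus 1). Sites that come out monomorphic are redrawn.
`genRecombEvents()` draws Poisson(rate) events per category and assigns
each to a uniformly random eligible strain pair, erroring if a positive
rate has no eligible pair. Every generator records its ground truth
(retrievable via `plantedTruth()`) and is bit-reproducible under a seed.

What the generators deliberately do **not** emulate: linkage
disequilibrium or population structure among SNP sites (sites are
independent given their frequencies), selection, gene-specific
recombination tracts, assembly or annotation artefacts beyond simple
missingness, and any correlation between the pan-genome, SNP and event
layers. Passing recovery tests therefore demonstrates that the estimators
recover what they claim from data matching their own assumptions — not
that those assumptions hold in real genomes.

## Problem sizes in the test suite

The acceptance tests run the neutrality suite at n = 20, θ_locus = 10 with
2000 replicates; ABC recovery at n = 6, L = 10⁶, μ = 2.2 × 10⁻¹⁰ with 20
repetitions of 2 × 20,000 simulations; Heaps recovery with 100 replicates
per planted α and 10–25 orderings per fit (1000 orderings is the
analysis default; the fit is seed-stable to < 0.05 in α at that depth);
GWAS calibration with 100 null replicates of 500 sites × 40 samples; and
the filter-chain fixture at full printed size (38,533 sites × 42
genomes). These sizes keep the whole suite around three minutes on one
CPU while leaving every Monte-Carlo tolerance at its stated width.
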