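# strainscape

Population-genomic inference for collections of bacterial isolates sampled
across structured habitats — for example *Vibrio* strains drawn from several
ponds, each sampled in both the water column and the sediment. The package
re-implements, as tested and reusable R code, the inference machinery such a
study needs once genomes have been assembled and gene families called:

* **Effective population size and divergence times** by rejection
  approximate Bayesian computation (ABC) over a haploid Kingman coalescent
  simulator with infinite-sites mutation (constant-size and
  population-split demographies).
* **Diversity statistics**: segregating sites *S*, nucleotide diversity π,
  Watterson's θ_w, Tajima's *D*, plus windowed and subsampled-*D* variants
  used as ABC summary statistics.
* **Pan-genome analysis**: core / accessory / unique partitioning (core =
  present in ≥ 95 % of genomes) and Heaps-law openness, fitting
  *n*(N) = κ·N^(−α) to gene-accumulation curves; α > 1 ⇒ closed, α < 1 ⇒
  open, with a 3-genome subsampling robustness test.
* **Genetic distances and clustering**: Nei (1972) distance, bitwise SNP
  distance, Jaccard distance between recombination-event profiles, UPGMA
  and neighbour-joining trees, and single-linkage grouping at a distance
  threshold (default 0.001).
* **Recombination-event classification** by pond/environment agreement
  (SPSE / SPDE / DPSE / DPDE) with injected normalization factors.
* **SNP–environment association**: variant extraction from alignments,
  biallelic and MAF/carrier filters, private-allele counts, two-sided
  Fisher exact tests with Bonferroni correction, and mapping of significant
  SNPs into 1-kb windows.
* **A synthetic-data module** that generates every input with known ground
  truth (planted *N*_e, Heaps α, associated sites, category rates), so the
  whole pipeline is testable end to end without any sequencing data.

## Model notation

The coalescent is haploid: *k* lineages in a population of size *N*
coalesce at rate C(*k*, 2)/*N*, so the per-site diversity parameter is
θ = 2·*N*_e·μ and E[π] = θ, E[S] = θ·L·a_{n−1} with
a_{n−1} = Σ_{i=1}^{n−1} 1/i. The default mutation rate is
μ = 2.2 × 10⁻¹⁰ per site per generation. ABC draws *N*_e from a log-uniform
prior (default 10⁵–2 × 10⁷ individuals; divergence times 10³–4 × 10⁶
generations), simulates a locus per draw, and accepts the `tol` fraction
(default 0.05 %) of draws closest to the observed summary vector
(*S*, *D*, windowed-*D* mean and SD) in MAD-standardized Euclidean
distance; a second stage repeats the run with priors narrowed to the
accepted range.

## Worked example

```r
library(strainscape)

## simulate one clade-like sample and estimate its Ne by two-stage ABC
cfg <- demographyConfig("single", ne = 1e6, sampleSizes = 6,
                        mu = 2.2e-10, L = 1e6)
H <- simulateLocus(cfg, seed = 2)
H
#> HaplotypeMatrix: 6 haplotypes x 795 segregating sites on a 1e+06 bp locus
diversityStats(H, nWindows = 1000, group = "demo")
#>   group n   S        pi   theta_w tajima_d d_window_mean d_window_sd     L
#> 1  demo 6 795 0.0003696 0.0003482   0.4008         0.262      0.8815 1e+06

res <- twoStageAbc(summaryVector(H), cfg, list(priorSpec("ne", 1e5, 2e7)),
                   nSimsPerStage = 20000, tol = 0.005, seed = 8)
res
#> AbcResult: 20000 simulations, tol = 0.005 (two-stage)
#>   ne: median 8.745e+05, 95% CI [3.881e+05, 2.401e+06]
```

The posterior median (8.7 × 10⁵) recovers the generating
*N*_e = 10⁶ within sampling noise, and the 95 % credible interval covers
it. π (3.7 × 10⁻⁴) and θ_w (3.5 × 10⁻⁴) sit near the expected
θ = 2·*N*_e·μ = 4.4 × 10⁻⁴ for this draw.

```r
## pan-genome openness on a synthetic 22-genome matrix with planted alpha
M <- genPangenomeMatrix(22, coreSize = 1746, kappa = 1244.2096,
                        alpha = 0.7913, seed = 9)
classifyFamilies(M)$counts
#>      core accessory    unique     total
#>      1840      3729      2334      7903
heapsFit(M, nPerm = 200, seed = 10)
#> HeapsFit: kappa = 1260.4913, alpha = 0.8033 -> open pan-genome (200 permutations)

## environment GWAS on synthetic SNPs with five planted associations
meta <- genSampleMetadata(40, seed = 11)
S <- genSnpDataset(meta, nSites = 200, nAssoc = 5, effect = 1, seed = 12)
fa <- fisherAssoc(filterMaf(filterBiallelic(S)))
setequal(fa$result$position[fa$result$significant],
         sitePositions(S)[plantedTruth(S)$associated_sites])
#> [1] TRUE
```

The fitted α (0.80) recovers the planted 0.7913 and calls the pan-genome
open; the Fisher GWAS recovers exactly the five planted sites after the
biallelic and MAF/carrier filters.

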