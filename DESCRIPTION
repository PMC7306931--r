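Package: strainscape
Title: Population Genomics of Bacterial Isolate Collections Across Habitats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-based inference and comparative genomics for
    collections of bacterial isolates sampled across structured habitats
    (ponds, water versus sediment). Provides a haploid Kingman coalescent
    simulator with infinite-sites mutation under constant-size and
    population-split demographies; rejection approximate Bayesian
    computation (ABC) with prior narrowing to estimate effective
    population size and divergence times from diversity summary
    statistics; classical diversity statistics (pi, Watterson's theta,
    Tajima's D, windowed and subsampled variants); pan-genome
    partitioning into core, accessory and unique gene families with
    Heaps-law openness fitting and subsampling robustness tests; genetic
    distances (Nei 1972, bitwise SNP distance, Jaccard event-profile
    distance), UPGMA and neighbour-joining trees and threshold grouping;
    recombination-event classification by pond and environment; and a
    Fisher-exact SNP-environment association pipeline with Bonferroni
    correction, private-allele counting and 1-kb window mapping. A
    synthetic-data module generates every input with known ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
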