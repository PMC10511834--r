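Package: breedsize
Title: Effective Number of Breeders and Spawner Abundance from Larval Cohort Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the effective number of breeders (Nb), the minimum
    number of spawners (Ns), and the extrapolated total number of spawning
    adults for single larval cohorts genotyped at biallelic SNPs. Implements
    RAD-capture SNP panel filtering (depth, HDplot paralog screening,
    Hardy-Weinberg checks, per-tag and sliding-window SNP selection), the
    linkage-disequilibrium Nb estimator with sample-size bias correction and
    jackknife confidence intervals, pairwise-likelihood sibship reconstruction
    with the sibship-frequency Nb estimator, pedigree accumulation curves with
    bias-corrected Chao extrapolation, and a cross-stream statistical layer
    (Pearson correlations with census size, VIF screening, all-subsets
    gaussian models with AICc averaging). A forward simulator of polygamous
    matings, Mendelian SNP transmission, read depths, and clustered stream
    sampling provides cohorts with known demographic truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    vcfR,
    igraph,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
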