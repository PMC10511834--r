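---
title: "Estimating effective breeder numbers and spawner abundance from larval cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating effective breeder numbers and spawner abundance from larval cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsize)
```

## The problem

Stream-spawning fish such as sea lamprey leave behind larval cohorts that can
be sampled and genotyped long after the adults have disappeared. Two
pedigree- and drift-based quantities computed from a single cohort serve as
surrogates of spawning-adult abundance:

* **Nb**, the effective number of breeders behind the cohort — the size of an
  ideal parental group that would produce the observed genetic signal; and
* **Ns**, the minimum number of spawners — the count of distinct parental
  genotypes in the cohort's reconstructed pedigree — together with an
  extrapolation of the *total* number of spawners from the shape of the
  pedigree accumulation curve.

`breedsize` implements the full chain: SNP-panel filtering from a genotype
matrix, Nb by the linkage-disequilibrium (LD) and sibship-frequency (SF)
methods, sibship reconstruction, Chao extrapolation of spawner number, and a
cross-stream statistical layer relating these estimates to census size and
stream covariates. A forward simulator with known demographic truth backs
every stage with parameter-recovery tests.

## The simulator and what it emulates

`breeding_config()` + `simulate_pedigree()` + `simulate_genotypes()` generate
cohorts from a polygamous spawning event:

* **Two-level matings.** Each sire takes `1 + Poisson(mate_mean - 1)` dams;
  each pair produces Poisson or negative-binomial offspring. The two levels
  let the variance in reproductive success (Vk) and the density of half-sib
  connections be tuned independently — real streams range from a few large
  full-sib families to webs of small half-sib families.
* **Genome layout.** 84 chromosomes of 30 Mb by default. Positions only feed
  the 1-MB selection windows and the inter-chromosomal pair rule; physical
  linkage within chromosomes is not modelled (all loci segregate freely).
* **Standing linkage disequilibrium.** Parents are not drawn from a
  linkage-equilibrium base: `n_burnin_generations` (default 8) of the same
  breeding regime are simulated first. This matters quantitatively: LD among
  unlinked loci loses half its value per generation, so a cohort one
  generation away from an LD-free base carries only ~75% of the
  drift-recombination equilibrium signal that the LD method's bias
  correction assumes, and Nb would be overestimated by ~1/3. Burn-in brings
  the estimator on target, which is exactly the situation in a stable
  natural population. Within the burn-in, survival from the larval pool to
  the next generation's adults is proportional to family size
  (largest-remainder quotas): purely random survival into a small adult
  group would add drift beyond the regime's reproductive variance, deflating
  the chain's effective size below the focal event's Nb and biasing the
  validation itself.
* **Reads and artifacts.** Per-genotype depths are negative binomial (mean
  26 by default, matching deep RAD-capture data); depths split binomially by
  allele; genotyping error, missingness, and a configurable fraction of
  paralog-merged loci (two loci whose reads are pooled, producing the
  heterozygote-excess / read-ratio-deviation signature that HDplot screens
  for) are applied on top.
* **Clustered sampling.** Each full-sib family draws a site-weight vector
  from a Dirichlet with concentration `1/site_clustering`; sampling then
  draws offspring from a subset of sites. High clustering localizes each
  family at one site, so a single-site sample contains few families — the
  mechanism behind the downward bias of Nb under opportunistic sampling.

What the simulator does **not** emulate: physical linkage and recombination
distance, sequence-level artifacts upstream of genotypes (the package starts
at the genotype matrix), multi-cohort age mixtures, inbreeding, selfing, and
sex-biased sampling. Passing recovery tests on these cohorts therefore
demonstrates correctness of the estimators under their own assumptions, not
robustness to every field complication.

## SNP filtering

The filter chain reproduces standard RAD-capture panel hygiene: genotypes
below 8x total depth are set missing; HDplot removes putative paralogs
(H > 0.6 or |D| > 7, strict inequalities, where D is the z-score of the
summed heterozygote reference reads under Binomial(n, 1/2)); loci off the
bait panel or genotyped in under 80% of individuals are dropped; an exact
conditional test flags Hardy-Weinberg deviation only when it appears in
every population. Two SNP sets are then built: the **LD set** (one SNP per
RAD tag, highest call rate, MAF at least 0.05) and the **pedigree set** (the
single SNP maximizing MAF x call rate in each non-overlapping 1-MB window).
Window tiling starts at position 0; the window winner rule is deterministic
with ties broken by lower position. We chose tiled windows over a literal
sliding window because the intent is locus spacing and independence, and
tiling is order-free; the MAF x call-rate product is the simplest score
monotone in both stated selection criteria.

## LD-based Nb

For every locus pair on *different* chromosomes, Burrows' composite
disequilibrium is computed from unphased genotypes over the individuals
non-missing at both loci (half the unbiased covariance of genotype codes),
normalized by pi = p(1-p) + (P_hom - p^2) per locus, and squared. Loci with
minor allele frequency at or below `pcrit` (default 0.05) are excluded. The
S-weighted mean r-squared, with S the per-pair joint sample size, is
bias-corrected by the expected no-drift value (1/S + 3.19/S^2 for harmonic
mean S of at least 30; 0.0018 + 0.907/S + 4.44/S^2 below, the small-sample
constants that samples of ~21 larvae force) and inverted through the drift
expectation. Negative corrected values map to an infinite estimate — never
clamped to zero, since genuinely tiny cohorts can produce sub-1 finite
estimates that are informative.

Confidence intervals use a delete-one-individual jackknife: the
bias-corrected r-squared is recomputed without each individual (a compiled
downdating loop, so the jackknife costs little more than the point
estimate), a normal-theory interval is formed on that scale and transformed
through the estimator. We implement the standard jackknife variance; the
output metadata names the variant.

## Sibship reconstruction and SF-Nb

Full-likelihood MCMC over sibship partitions (as in COLONY) is deliberately
not reimplemented. Downstream statistics consume only the pedigree, so the
package pairs a pairwise-likelihood classifier with graph clustering, and an
external-pedigree reader accepts BestConfig-style tables from dedicated
software. Each pair is scored under unrelated / half-sib / full-sib
IBD-coefficient models with genotyping error folded in; full-sib families
are connected components of the FS graph after triangle-consistency pruning
(an FS edge needs a third individual FS or HS with both ends, unless it is
an isolated dyad). Half-sib links between families pool the cross-family
pair log-likelihoods — pooling matters, because individual half-sib pairs
carry weak signal but a family pair aggregates it — and a shared parent
label is assigned when the pooled HS likelihood beats both alternatives,
with group-consistency checks so that chains of merges stay coherent.

One identifiability limit is worth stating plainly: with allele frequencies
estimated from the cohort itself, a cohort that is a *single* family cannot
be recognized as such. Conditional on the true parents, full sibs are
independent draws, and the family's own genotypes set the frequency
estimates to the parental frequencies, making the unrelated model fit
exactly. Joint multilocus methods escape this; a pairwise classifier needs
reference allele frequencies (the `allele_freqs` argument) when a sample
may contain only one or two families.

SF-Nb is Wang's random-mating estimator, 1/Nb = (Q_pat + Q_mat)/4 over all
offspring pairs, with sharing counted by parent label across both slots and
a percentile bootstrap over offspring (self-pairs excluded) for the
interval. Vk uses the sample variance (divisor Ns - 1); the convention is
recorded in the output because the source conventions differ.

## Accumulation curves and the Chao extrapolation

Parents are treated as species and offspring as incidence samples. The
accumulation curve averages unique-parent counts over random offspring
orderings (default 100 permutations). The total spawner number uses the
bias-corrected incidence-based Chao estimator
S_obs + ((N-1)/N) q1(q1-1)/(2(q2+1)) with its matching variance (zero when
q1 = 0, i.e. when the curve has reached its asymptote). The bias-corrected
form is defined for q2 = 0, has no singularity, and is what the reference
implementation returns in that branch — on such inputs the two agree
exactly, which the test suite uses as a cross-check.

## Cross-stream models

The packaged per-stream table transcribes the study's covariates and
estimates for 17 streams. Census-size correlations use only streams whose
capture-mark-recapture estimate refers to the cohort's spawning year (one
stream's census value predates its cohort and is excluded, giving the
10-stream full set and the 7-stream large-sample subset), and both
candidate spawner series (observed Ns and Chao total) are available because
the source is ambiguous about which was used. Predictors are screened by
VIF = 1/(1-R^2); the retained set {sample size, sampling distance, years
since lampricide treatment, drainage area} sits below the GVIF < 2
threshold. All-subsets gaussian identity-link models (the family is
unstated in the source; identity/gaussian is the conventional default and
the one consistent with the reported coefficient signs) are ranked by AICc
with the confidence set at delta < 2; coefficients are model-averaged with
Akaike weights, reporting both the full and the conditional average, with
unconditional standard errors and 1.96-SE intervals driving the
overlaps-zero classification.

## Numerical and design choices

* Genotypes are 0/1/2 alternate-allele counts; missing is distinct from
  depth zero; depths are kept under a masked call so read-based statistics
  still see them.
* One global seed drives a named RNG stream per stage, so pedigree,
  genotypes, sampling, bootstrap and permutations are independently
  reproducible.
* Pair skipping: LD pairs need S of at least 2 and both loci polymorphic
  within the pair's joint individuals; pairs of individuals with zero locus
  overlap are unclassifiable and treated as unrelated with a flag.
* Tie-breaks in SNP selection (position, then column index) and in
  reconstruction (descending likelihood ratio) are fixed and documented, so
  results are invariant to input order.
* Problem sizes in the validation suite: parameter recovery runs cohorts of
  ~350 offspring (25+25 and 50+50 parents), samples of 100, 600-SNP panels,
  with 100 replicates for recovery and coverage and 30-100 for the
  reconstruction-quality and sampling-bias properties. These sizes give
  stable medians while keeping the whole suite comfortably re-runnable.

## Known limitations

* The LD method's calibration assumes drift-recombination equilibrium; for
  populations recently founded from large, unstructured sources the method
  will overestimate Nb (the simulator's burn-in exists precisely to model
  the equilibrium case).
* Reconstruction quality degrades for half-sib detection between singleton
  offspring; SF-Nb is nonetheless nearly unbiased because pooled-likelihood
  merging recovers shared parents between families of realistic size.
* Vk from reconstructed pedigrees inherits reconstruction noise; the
  per-stream Vk values in the packaged table come from the original
  full-likelihood reconstructions.
* Single-family samples need external allele frequencies (above).
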