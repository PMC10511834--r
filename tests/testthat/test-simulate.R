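test_that("config validation rejects impossible settings", {
  expect_error(breeding_config(n_sires = 0), "n_sires")
  expect_error(breeding_config(genotyping_error = 1.5), "probability")
  expect_error(breeding_config(maf_min = 0), "MAF range")
  expect_error(breeding_config(maf_max = 0.7), "MAF range")
  expect_error(breeding_config(mate_mean = 0.5), "mate_mean")
})

test_that("single-pair cohort is one full-sib family and runs are seed-reproducible", {
  cfg <- breeding_config(n_sires = 1, n_dams = 1, mate_mean = 1,
                         offspring_mean = 10, seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_true(all(ped$sire == ped$sire[1]))
  expect_true(all(ped$dam == ped$dam[1]))
  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped, ped2)
})

test_that("realized family sizes match the configured offspring distribution", {
  # replicated cohorts: total offspring mean ~ n_sires * E[mates] * E[pair size]
  cfg0 <- breeding_config(n_sires = 25, n_dams = 25, mate_mean = 2,
                          offspring_mean = 4)
  tots <- vapply(1:300, function(s) {
    cfg <- breeding_config(n_sires = 25, n_dams = 25, mate_mean = 2,
                           offspring_mean = 4, seed = s)
    nrow(simulate_pedigree(cfg))
  }, numeric(1))
  # expected pairs slightly below 50 because duplicate sire-dam draws collapse
  exp_pairs <- 25 * 2 * (1 - 0.5 * (2 - 1) / 25)  # one-collision correction
  expected <- exp_pairs * 4
  se <- sd(tots) / sqrt(length(tots))
  expect_lt(abs(mean(tots) - expected), 3 * se + 0.02 * expected)
})

test_that("demographic Nb matches closed forms and known limits", {
  # 25 + 25 parents, equal contributions: per-sex Ne = 49, Nb = 98
  ped <- data.frame(
    offspring = paste0("o", 1:50),
    sire = rep(paste0("S", 1:25), each = 2),
    dam = rep(paste0("D", 1:25), each = 2)
  )
  expect_equal(demographic_nb(ped), 98)
  # all offspring from one pair: Nb -> 2 at large k
  ped1 <- data.frame(offspring = paste0("o", 1:400),
                     sire = "S1", dam = "D1")
  expect_lt(abs(demographic_nb(ped1) - 2), 0.02)
  # ideal population: each offspring draws its parents uniformly, so
  # offspring numbers are near-Poisson (Vk ~ kbar) and Nb ~ Nm + Nf
  nbs <- vapply(1:40, function(s) {
    set.seed(s)
    ped <- data.frame(offspring = paste0("o", 1:400),
                      sire = paste0("S", sample.int(25, 400, TRUE)),
                      dam = paste0("D", sample.int(25, 400, TRUE)))
    demographic_nb(ped)
  }, numeric(1))
  expect_lt(abs(mean(nbs) - 50), 3)
})

test_that("demographic Nb ignores parent labels and offspring order", {
  cfg <- breeding_config(n_sires = 8, n_dams = 12, seed = 5)
  ped <- simulate_pedigree(cfg)
  base <- demographic_nb(ped)
  shuf <- ped[sample.int(nrow(ped)), ]
  expect_equal(demographic_nb(shuf), base)
  relab <- ped
  relab$sire <- paste0("X_", relab$sire)
  relab$dam <- paste0("Y_", relab$dam)
  expect_equal(demographic_nb(relab), base)
})

test_that("more offspring-number dispersion never raises demographic Nb", {
  sizes <- c(Inf, 2, 0.3)   # Poisson -> strongly overdispersed
  mean_nb <- vapply(sizes, function(sz) {
    mean(vapply(1:25, function(s) {
      cfg <- breeding_config(n_sires = 20, n_dams = 20, mate_mean = 2,
                             offspring_mean = 5, offspring_dispersion = sz,
                             seed = s)
      demographic_nb(simulate_pedigree(cfg))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_nb) < 0))
})

test_that("offspring genotypes are Mendelian-consistent when error-free", {
  cfg <- breeding_config(n_sires = 5, n_dams = 5, n_loci = 120,
                         n_chromosomes = 6, genotyping_error = 0,
                         missing_rate = 0, paralog_fraction = 0, seed = 9)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  par_g <- attr(gm, "parent_genotypes")
  ok <- TRUE
  for (i in seq_len(nrow(ped))) {
    gs <- par_g[ped$sire[i], ]; gd <- par_g[ped$dam[i], ]
    go <- gm$genotypes[i, ]
    use <- !is.na(go)
    pr <- mapply(oracle_mendel, go[use], gs[use], gd[use])
    if (any(pr == 0)) { ok <- FALSE; break }
  }
  expect_true(ok)
})

test_that("parental allele frequencies follow the configured MAF distribution", {
  cfg <- breeding_config(n_sires = 40, n_dams = 40, n_loci = 800,
                         n_chromosomes = 20, maf_min = 0.2, maf_max = 0.4,
                         offspring_mean = 3, seed = 21)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  p <- allele_freq(gm)
  # offspring frequencies estimate the base draw ~ U(0.2, 0.4), mean 0.3;
  # burn-in drift spreads individual loci but leaves the mean unbiased
  se <- sd(p) / sqrt(length(p))
  expect_lt(abs(mean(p) - 0.3), max(3 * se, 0.02))
})

test_that("read depths average the configured mean and paralog loci run hot", {
  cfg <- breeding_config(n_sires = 10, n_dams = 10, n_loci = 400,
                         n_chromosomes = 10, depth_mean = 26,
                         paralog_fraction = 0.2, seed = 13)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  par_flag <- attr(gm, "paralog")
  depth <- gm$ref_depth + gm$alt_depth
  clean_mean <- mean(depth[, !par_flag])
  expect_lt(abs(clean_mean - 26), 0.5)
  # merged loci pool reads from two loci
  expect_gt(mean(depth[, par_flag]), 1.7 * 26)
})

test_that("paralog-merged loci show heterozygote excess at matched frequencies", {
  cfg <- breeding_config(n_sires = 50, n_dams = 50, n_loci = 600,
                         n_chromosomes = 12, paralog_fraction = 0.5,
                         offspring_mean = 4, depth_mean = 30, seed = 17)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  par_flag <- attr(gm, "paralog")
  H <- hdplot(gm)$H
  expect_gt(mean(H[par_flag]), mean(H[!par_flag]) + 0.1)
})

test_that("tag sharing requires enough loci per chromosome", {
  cfg <- breeding_config(n_sires = 2, n_dams = 2, n_loci = 10,
                         n_chromosomes = 20, tag_pair_rate = 0.5, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_error(simulate_genotypes(ped, cfg), "tag sharing")
})

test_that("cohort sampling covers the full cohort in the uniform exhaustive case", {
  cfg <- breeding_config(n_sires = 10, n_dams = 10, n_sites = 4, seed = 31)
  ped <- simulate_pedigree(cfg)
  s <- sample_cohort(ped, nrow(ped), n_sites = 4, clustering = 0, seed = 2)
  expect_equal(nrow(s), nrow(ped))
  expect_setequal(s$offspring, ped$offspring)
})

test_that("extreme clustering at one site concentrates sampling in few families", {
  n_fams <- vapply(1:40, function(s) {
    cfg <- breeding_config(n_sires = 20, n_dams = 20, mate_mean = 1.5,
                           offspring_mean = 6, n_sites = 8, seed = s)
    ped <- simulate_pedigree(cfg)
    samp <- sample_cohort(ped, min(40, nrow(ped)), n_sites = 1,
                          clustering = 50, seed = s)
    length(unique(paste(samp$sire, samp$dam)))
  }, numeric(1))
  n_fams_unif <- vapply(1:40, function(s) {
    cfg <- breeding_config(n_sires = 20, n_dams = 20, mate_mean = 1.5,
                           offspring_mean = 6, n_sites = 8, seed = s)
    ped <- simulate_pedigree(cfg)
    samp <- sample_cohort(ped, min(40, nrow(ped)), n_sites = 8,
                          clustering = 0, seed = s)
    length(unique(paste(samp$sire, samp$dam)))
  }, numeric(1))
  expect_lt(mean(n_fams), 0.6 * mean(n_fams_unif))
})

test_that("cohort sampling is reproducible and validates its inputs", {
  cfg <- breeding_config(n_sires = 6, n_dams = 6, n_sites = 3, seed = 41)
  ped <- simulate_pedigree(cfg)
  s1 <- sample_cohort(ped, 20, 2, 1, seed = 7)
  s2 <- sample_cohort(ped, 20, 2, 1, seed = 7)
  expect_identical(s1, s2)
  expect_error(sample_cohort(ped, 20, 5, 1, seed = 7), "n_sites")
  expect_error(sample_cohort(ped, nrow(ped) + 1, 1, 1, seed = 7), "cohort size")
})

test_that("VCF round-trip preserves genotypes, depths and locus metadata", {
  cfg <- breeding_config(n_sires = 4, n_dams = 4, n_loci = 60,
                         n_chromosomes = 4, missing_rate = 0.05, seed = 23)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  f <- tempfile(fileext = ".vcf.gz")
  write_vcf(gm, f)
  gm2 <- read_vcf_genotypes(f)
  expect_equal(unname(gm2$genotypes), unname(gm$genotypes))
  expect_equal(gm2$loci$tag, gm$loci$tag)
  expect_equal(gm2$loci$pos, gm$loci$pos)
  expect_equal(gm2$loci$baited, gm$loci$baited)
  mask <- !is.na(gm$genotypes)
  expect_equal(unname(gm2$ref_depth[mask]), unname(gm$ref_depth[mask]))
  unlink(f)
})
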