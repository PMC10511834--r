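#!/usr/bin/env Rscript
# Estimate Nb (LD and SF), Ns, kbar and Vk for each simulated cohort and
# compare against the known demographic truth.

library(breedsize)

in_dir <- file.path("results", "cohorts")
cohorts <- sub("_ld\\.vcf.gz$", "",
               list.files(in_dir, pattern = "_ld\\.vcf.gz$"))
stopifnot(length(cohorts) > 0)

rows <- list()
for (nm in cohorts) {
  ld_gm <- read_vcf_genotypes(file.path(in_dir, paste0(nm, "_ld.vcf.gz")))
  ped_gm <- read_vcf_genotypes(file.path(in_dir, paste0(nm, "_ped.vcf.gz")))
  truth <- read_pedigree(file.path(in_dir, paste0(nm, "_truth.tsv")))

  ld <- ld_nb(ld_gm)
  rec <- reconstruct(ped_gm, error = 0.01)
  sf <- sibship_nb(rec, seed = 1)
  st <- sibship_stats(rec)

  rows[[nm]] <- data.frame(
    cohort = nm, n = nrow(truth),
    nb_ld = round(ld$point, 1), nb_ld_lo = round(ld$ci_low, 1),
    nb_ld_hi = round(ld$ci_hi <- ld$ci_high, 1),
    nb_sf = round(sf$point, 1), nb_sf_lo = round(sf$ci_low, 1),
    nb_sf_hi = round(sf$ci_high, 1),
    ns = st$ns, kbar = round(st$kbar, 2), vk = round(st$vk, 1),
    sf_true_pedigree = round(sibship_nb(truth, n_boot = 0)$point, 1)
  )
  message(sprintf(
    "%s: LD Nb %.1f (%.1f-%.1f), SF Nb %.1f (%.1f-%.1f), Ns %d",
    nm, ld$point, ld$ci_low, ld$ci_high, sf$point, sf$ci_low, sf$ci_high,
    st$ns))
}

write.table(do.call(rbind, rows), file.path("results", "estimates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("Wrote ", file.path("results", "estimates.tsv"))
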