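#!/usr/bin/env Rscript
# Build the two analysis SNP sets for each simulated cohort.
#
# Depth filter (8x) -> HDplot paralog screen (H > 0.6 | |D| > 7) -> bait /
# 80%-call filters -> LD set (one SNP per tag, MAF >= 0.05) and pedigree set
# (best SNP per 1-MB window). Reads the VCFs written by 01_simulate_cohorts.R
# and reports how many loci each stage removes.

library(breedsize)

in_dir <- file.path("results", "cohorts")
vcfs <- list.files(in_dir, pattern = "\\.vcf.gz$", full.names = TRUE)
stopifnot(length(vcfs) > 0)

rows <- list()
for (f in vcfs) {
  nm <- sub("\\.vcf.gz$", "", basename(f))
  gm <- read_vcf_genotypes(f)
  n0 <- ncol(gm$genotypes)
  gm <- apply_depth_filter(gm, 8)
  hd <- hdplot(gm)
  gm_hd <- filter_paralogs(gm, hd)
  gm_base <- base_filters(gm_hd)
  ld <- select_ld_set(gm_base)
  ps <- select_pedigree_set(gm_base)
  rows[[nm]] <- data.frame(
    cohort = nm, input = n0, after_hdplot = ncol(gm_hd$genotypes),
    after_base = ncol(gm_base$genotypes),
    ld_set = ncol(ld$genotypes), pedigree_set = ncol(ps$genotypes),
    mean_maf_ld = round(mean(maf(ld)), 3),
    mean_maf_ped = round(mean(maf(ps)), 3)
  )
  write_vcf(ld, file.path(in_dir, paste0(nm, "_ld.vcf.gz")))
  write_vcf(ps, file.path(in_dir, paste0(nm, "_ped.vcf.gz")))
  message(sprintf("%s: %d -> HDplot %d -> base %d -> LD %d / pedigree %d",
                  nm, n0, ncol(gm_hd$genotypes), ncol(gm_base$genotypes),
                  ncol(ld$genotypes), ncol(ps$genotypes)))
}

write.table(do.call(rbind, rows), file.path("results", "snp_sets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("Wrote ", file.path("results", "snp_sets.tsv"))
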