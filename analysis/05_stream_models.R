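#!/usr/bin/env Rscript
# Cross-stream statistical layer on the packaged 17-stream table:
# column summaries, correlations between genetic estimates and census size
# (with the small-sample sensitivity split), VIF screening, all-subsets AICc
# models and model-averaged coefficients for each response.

library(breedsize)

dir.create("results", showWarnings = FALSE)
records <- read_cohort_records()

## column summaries (reproduces the reported kbar / Vk means)
cs <- column_summary(records[, c("nb_ld", "nb_sf", "ns", "chao", "kbar", "vk")])
write.table(cs, file.path("results", "column_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("Mean kbar = ", cs$mean[cs$column == "kbar"],
        "; mean Vk = ", cs$mean[cs$column == "vk"])

## estimate-vs-estimate correlations across all 17 streams
pairs <- list(c("nb_sf", "chao"), c("nb_ld", "chao"), c("nb_sf", "nb_ld"),
              c("ns", "chao"))
est_cor <- do.call(rbind, lapply(pairs, function(p) {
  pr <- pearson(records[[p[1]]], records[[p[2]]])
  data.frame(x = p[1], y = p[2], r = round(pr$r, 3), p = signif(pr$p, 3))
}))
write.table(est_cor, file.path("results", "estimate_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(est_cor)

## census-size correlations, full and large-sample (n >= 50), both spawner
## series since the source is ambiguous about which it used
nc_tab <- do.call(rbind, lapply(c("chao", "ns"), function(sp) {
  rbind(cbind(subset = "all", spawner = sp,
              nc_correlations(records, min_n = 0, spawner = sp)),
        cbind(subset = "n>=50", spawner = sp,
              nc_correlations(records, min_n = 50, spawner = sp)))
}))
nc_tab$r <- round(nc_tab$r, 3); nc_tab$p <- round(nc_tab$p, 3)
write.table(nc_tab, file.path("results", "nc_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(nc_tab)

## VIF screen on the retained predictor set
predictors <- c("sample_size", "sampling_distance_km", "years_since_tfm",
                "drainage_ha")
v <- vif(records[, predictors])
message("VIF: ", paste(names(v), round(v, 2), sep = "=", collapse = ", "))

## all-subsets AICc models + averaging per response
for (resp in c("nb_ld", "nb_sf", "chao", "vk")) {
  ms <- dredge_aicc(records, resp, predictors,
                    interactions = "sample_size:sampling_distance_km")
  conf <- ms$table[ms$table$delta < 2, ]
  write.table(conf, file.path("results", paste0("models_", resp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  av <- model_average(ms)
  av[, -1] <- round(av[, -1], 4)
  write.table(av, file.path("results", paste0("avg_coef_", resp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(resp, ": ", nrow(conf), " model(s) in the confidence set; best: ",
          conf$model[1])
}
message("Stream-model outputs written under results/")
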