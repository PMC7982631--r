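#!/usr/bin/env Rscript
# Compute the four secondary burden ratios per stratum, fit the QCI model
# (first principal component of the standardized ratios, oriented so
# higher = better care, min-max rescaled to 0-100), score every stratum,
# and score the aggregate scales by pooling counts. Reports how well the
# per-location QCI recovers the generator's latent quality.

suppressPackageStartupMessages(library(qcindex))

out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cells <- read_gbd_csv("results/data/burden_cells.csv",
                      dialect = c(measure = "measure", location = "location",
                                  sex = "sex", age_group = "age_group",
                                  year = "year", metric = "metric",
                                  value = "value", lower = "lower",
                                  upper = "upper"))
piv <- pivot_panel(cells, "count")
panels <- piv$panels[piv$panels$age_group %in% gbd_age_bins(), ]
cat(sprintf("%d complete strata, %d excluded\n",
            nrow(panels), nrow(piv$exclusions)))

indices <- compute_indices(panels)
mat <- index_matrix(indices)
model <- fit_qci(mat$matrix)
print(model)

scores <- score_qci(model, indices)
agg_location <- aggregate_qci(model, panels, by = "location")
agg_age_sex <- aggregate_qci(model, panels, by = c("age_group", "sex"))
agg_global <- aggregate_qci(model, panels)

write_table(indices, file.path(out, "secondary_indices.csv"))
write_qci_model(model, file.path(out, "qci_model.txt"))
write_table(scores, file.path(out, "qci_scores_strata.csv"))
write_table(agg_location, file.path(out, "qci_location.csv"))
write_table(agg_age_sex, file.path(out, "qci_age_sex.csv"))
write_table(agg_global, file.path(out, "qci_global.csv"))

truth <- read_table("results/data/latent_quality_truth.csv")
rho <- cor(agg_location$qci,
           truth$quality[match(agg_location$location, truth$location)],
           method = "spearman")
cat(sprintf("global QCI (pooled counts): %.2f\n", agg_global$qci))
cat(sprintf("Spearman(per-location QCI, latent quality) = %.4f\n", rho))
best <- agg_location[which.max(agg_location$qci), ]
worst <- agg_location[which.min(agg_location$qci), ]
cat(sprintf("best %s (%.2f), worst %s (%.2f)\n",
            best$location, best$qci, worst$location, worst$qci))
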