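#!/usr/bin/env Rscript
# Simulate a GBD-like thyroid-cancer burden panel with a known latent
# care-quality scalar per location, and write it in the same CSV dialect
# the real extract would arrive in. Downstream scripts consume these files
# only, so the whole workflow runs end-to-end from disk.

suppressPackageStartupMessages(library(qcindex))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(n_locations = 20, noise_sd = 0.1, seed = 20240901)
gen <- generate_panel(cfg)

write_table(gen$cells, file.path(out, "burden_cells.csv"))
write_table(gen$population, file.path(out, "population.csv"))
# latent truth sidecar, kept apart from the "observed" panel
write_table(
  tibble::tibble(location = names(gen$truth$quality),
                 quality = unname(gen$truth$quality)),
  file.path(out, "latent_quality_truth.csv")
)
write_table(gen$truth$noiseless, file.path(out, "noiseless_measures.csv"))

f <- sum(gen$cells$value[gen$cells$measure == "incidence" &
                           gen$cells$sex == "female"])
m <- sum(gen$cells$value[gen$cells$measure == "incidence" &
                           gen$cells$sex == "male"])
cat(sprintf("simulated %d locations x %d years x 2 sexes x %d age bins\n",
            cfg$n_locations, length(cfg$years), length(cfg$age_bins)))
cat(sprintf("female/male incidence ratio: %.2f (generator multiplier %.1f)\n",
            f / m, cfg$female_incidence_multiplier))
cat(sprintf("wrote burden, population and truth tables under %s/\n", out))
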