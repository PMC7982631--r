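#!/usr/bin/env Rscript
# Gender-disparity analysis of the fitted QCI: the female/male score ratio
# (GDR, 1 = parity) per location and per global age group, plus the paired
# scatter table that keeps both absolute scores -- two locations can share
# a near-one ratio at very different quality levels.

suppressPackageStartupMessages(library(qcindex))

out <- "results/tables"
model <- read_qci_model(file.path(out, "qci_model.txt"))
panels <- read_table(file.path(out, "secondary_indices.csv"))

agg_loc_sex <- aggregate_qci(model, panels, by = c("location", "sex"))
gdr_loc <- gdr_table(agg_loc_sex)
pairs <- scatter_pairs(gdr_loc$records)

agg_age_sex <- aggregate_qci(model, panels, by = c("age_group", "sex"))
gdr_age <- gdr_table(agg_age_sex)

write_table(gdr_loc$records, file.path(out, "gdr_location.csv"))
write_table(pairs, file.path(out, "gdr_scatter_pairs.csv"))
write_table(gdr_age$records, file.path(out, "gdr_age.csv"))

g <- gdr_loc$records[!gdr_loc$records$undefined, ]
cat(sprintf("location GDR: %d pairs, range %.3f (%s) to %.3f (%s)\n",
            nrow(g), min(g$gdr), g$location[which.min(g$gdr)],
            max(g$gdr), g$location[which.max(g$gdr)]))
cat(sprintf("near-parity locations (|GDR - 1| < 0.02): %d\n",
            sum(abs(g$gdr - 1) < 0.02)))
ga <- gdr_age$records[!gdr_age$records$undefined, ]
cat(sprintf("age-group GDR range: %.3f to %.3f\n", min(ga$gdr), max(ga$gdr)))
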