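#!/usr/bin/env Rscript
# Stage 4: diversity and differential features.
#
# Shannon diversity and within-arm Bray-Curtis spread summarize the
# community; species are CLR + inverse-rank transformed and tested by
# Kruskal-Wallis across days within each arm and across arms within each
# day (BH over features), with Dunn post hoc contrasts; phenotypes are
# tested untransformed on the same axes.

library(coabnet)

data_dir <- file.path("results", "data")
out <- file.path("results", "differential")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rel <- read_feature_table(file.path(data_dir, "species_relative.tsv"),
                          kind = "species", scale = "relative")
phe <- read_feature_table(file.path(data_dir, "phenotypes.tsv"),
                          kind = "phenotype", scale = "raw")
meta <- read_sample_meta(file.path(data_dir, "sample_meta.tsv"))

# community summaries
h <- shannon_index(rel)
write.table(data.frame(sample_id = names(h), shannon = h),
            file.path(out, "shannon.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
bc <- bray_curtis(rel)
wg <- within_group_dissimilarity(bc, meta)
wg_df <- do.call(rbind, lapply(names(wg), function(k)
  if (length(wg[[k]])) data.frame(subgroup = k, bc = wg[[k]]) else NULL))
write.table(wg_df, file.path(out, "within_group_bc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
med_bc <- tapply(wg_df$bc, sub("\\.d\\d+$", "", wg_df$subgroup), median)
cat("median within-arm Bray-Curtis:",
    sprintf("%s = %.3f", names(med_bc), med_bc), "\n")

# species, time axis within each arm
for (g in unique(meta$group)) {
  dt <- differential_features(rel, meta, axis = "time_within_group",
                              subset = g, transform = "clr_irn")
  write.table(dt, file.path(out, sprintf("species_time_%s.tsv", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- dt[which.min(dt$p), ]
  cat(sprintf(
    "arm %s: %d/%d species at FDR < 0.05 (%d at nominal P < 0.05); top %s, P = %.2g\n",
    g, sum(dt$fdr < 0.05), nrow(dt), sum(dt$p < 0.05), top$feature, top$p))
}

# species and phenotypes, arm axis within each day
for (day in sort(unique(meta$day))) {
  dg <- differential_features(rel, meta, axis = "group_within_time",
                              subset = day, transform = "clr_irn")
  write.table(dg, file.path(out, sprintf("species_group_d%d.tsv", day)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dp <- differential_features(phe, meta, axis = "group_within_time",
                              subset = day, transform = "none")
  write.table(dp, file.path(out, sprintf("phenotype_group_d%d.tsv", day)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "day %2d: %d species, %d phenotypes differ between arms (FDR < 0.05)\n",
    day, sum(dg$fdr < 0.05), sum(dp$fdr < 0.05)))
}
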