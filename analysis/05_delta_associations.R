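#!/usr/bin/env Rscript
# Stage 5: within-calf changes linked across data layers.
#
# Microbial CLR changes, metabolite log-intensity changes and raw
# phenotype changes between day 15 and each later day are screened per
# arm by Spearman correlation with the dual threshold |rho| > 0.7 and
# P < 0.01; associations significant only in RMT (or reversed elsewhere)
# are called RMT-specific.

library(coabnet)

data_dir <- file.path("results", "data")
out <- file.path("results", "delta_assoc")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rel <- read_feature_table(file.path(data_dir, "species_relative.tsv"),
                          kind = "species", scale = "relative")
met <- read_feature_table(file.path(data_dir, "metabolites.tsv"),
                          kind = "metabolite", scale = "intensity")
phe <- read_feature_table(file.path(data_dir, "phenotypes.tsv"),
                          kind = "phenotype", scale = "raw")
meta <- read_sample_meta(file.path(data_dir, "sample_meta.tsv"))

clr <- clr_transform(rel)
met_log <- log(met$values)
days <- sort(unique(meta$day))

for (day_b in days[-1]) {
  screens_met <- list(); screens_phe <- list()
  for (g in unique(meta$group)) {
    m_g <- meta[meta$group == g, , drop = FALSE]
    micro_d <- compute_deltas(clr[, m_g$sample_id], m_g, days[1], day_b)
    met_d <- compute_deltas(met_log[, m_g$sample_id], m_g, days[1], day_b)
    phe_d <- compute_deltas(phe$values[, m_g$sample_id], m_g, days[1], day_b)
    screens_met[[g]] <- spearman_screen(micro_d, met_d, scope = g)
    screens_phe[[g]] <- spearman_screen(micro_d, phe_d, scope = g)
  }
  am <- call_group_specific(screens_met, focal = "RMT")
  ap <- call_group_specific(screens_phe, focal = "RMT")
  tag <- sprintf("%d_%d", days[1], day_b)
  write.table(am, file.path(out, sprintf("micro_metabolite_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ap, file.path(out, sprintf("micro_phenotype_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "interval %s: metabolite links sig %d (RMT-specific %d); phenotype links sig %d (RMT-specific %d)\n",
    tag, sum(am$significant), sum(am$group_specific),
    sum(ap$significant), sum(ap$group_specific)))
}
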