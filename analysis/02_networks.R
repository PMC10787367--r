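#!/usr/bin/env Rscript
# Stage 2: per-subgroup SparCC coabundance networks.
#
# Relative abundances are prevalence-filtered (> 10% of samples),
# converted to predicted read counts with each sample's depth, and split
# into (arm, day) subgroups. SparCC is run per subgroup with 100
# feature-wise permutations; edges are kept at P < 0.01, attainable only
# by exceeding every permuted value.

library(coabnet)

seed <- 2024
data_dir <- file.path("results", "data")
out <- file.path("results", "networks")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rel <- read_feature_table(file.path(data_dir, "species_relative.tsv"),
                          kind = "species", scale = "relative")
meta <- read_sample_meta(file.path(data_dir, "sample_meta.tsv"))

rel <- prevalence_filter(rel, 0.10)
counts <- to_counts(rel, meta)
subgroups <- split_subgroups(counts, meta)

n_edges <- 0
for (k in seq_along(subgroups)) {
  sg <- subgroups[[k]]
  nm <- names(subgroups)[k]
  cfg <- sparcc_config(n_permutations = 100, seed = seed + 97L * k)
  r <- sparcc_correlations(sg$table, cfg)
  p <- sparcc_pvalues(sg$table, r, cfg)
  edges <- significant_edges(r, p, alpha = cfg$alpha,
                             n_samples = length(sg$sample_ids))
  n_edges <- n_edges + nrow(edges)
  write.table(edges, file.path(out, sprintf("edges_%s.tsv", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(feature = rownames(r), r, check.names = FALSE),
              file.path(out, sprintf("sparcc_r_%s.tsv", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-9s n = %2d  edges at P<0.01: %d\n",
              nm, length(sg$sample_ids), nrow(edges)))
}
cat(sprintf("total significant edges across subgroups: %d\n", n_edges))
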