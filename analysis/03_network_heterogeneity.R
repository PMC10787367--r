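#!/usr/bin/env Rscript
# Stage 3: cross-arm edge heterogeneity, specificity, hubs.
#
# For each day, the edges significant in any arm form the universe; every
# arm's SparCC r is filled in, Cochran's Q (Fisher-z, inverse-variance
# weights) tests heterogeneity with BH control at FDR 0.05, and the IQR
# fence rule (factor 0.75) assigns heterogeneous edges to at most one arm.
# RMT-specific subnetworks are scored for Kleinberg hubs (> 0.5).

library(coabnet)

data_dir <- file.path("results", "data")
net_dir <- file.path("results", "networks")
out <- file.path("results", "heterogeneity")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read_sample_meta(file.path(data_dir, "sample_meta.tsv"))
days <- sort(unique(meta$day))
groups <- unique(meta$group)

read_edges <- function(nm) {
  path <- file.path(net_dir, sprintf("edges_%s.tsv", nm))
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character",
                                  "numeric", "numeric"))
  df
}
read_r <- function(nm) {
  df <- read.table(file.path(net_dir, sprintf("sparcc_r_%s.tsv", nm)),
                   header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$feature
  m
}

for (day in days) {
  keys <- paste0(groups, ".d", day)
  networks <- lapply(keys, read_edges)
  r_mats <- lapply(keys, read_r)
  names(networks) <- names(r_mats) <- groups
  ns <- sapply(groups, function(g)
    sum(meta$group == g & meta$day == day))
  uni <- edge_universe(networks, r_mats, ns)
  if (nrow(uni)) {
    uni <- heterogeneity_test(uni, fdr_level = 0.05)
    uni <- specific_edges(uni, factor = 0.75, fdr_level = 0.05)
    rmt <- uni[!is.na(uni$specific_group) & uni$specific_group == "RMT",
               c("feature_a", "feature_b", "r_RMT")]
    names(rmt)[3] <- "r"
  } else {
    rmt <- data.frame(feature_a = character(0), feature_b = character(0),
                      r = numeric(0))
  }
  hubs <- hub_scores(rmt)
  write.table(uni, file.path(out, sprintf("edge_meta_d%d.tsv", day)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(hubs, file.path(out, sprintf("hubs_RMT_d%d.tsv", day)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  het_edges <- if (nrow(uni)) {
    uni[uni$heterogeneous, c("feature_a", "feature_b"), drop = FALSE]
  } else {
    data.frame(feature_a = character(0), feature_b = character(0))
  }
  gsum <- suppressMessages(genus_summary(het_edges))
  write.table(gsum, file.path(out, sprintf("genus_pairs_d%d.tsv", day)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "day %2d: universe %3d edges, heterogeneous %2d, specific calls %2d (RMT %2d), hubs>0.5 %d\n",
    day, nrow(uni), if (nrow(uni)) sum(uni$heterogeneous) else 0,
    if (nrow(uni)) sum(!is.na(uni$specific_group)) else 0, nrow(rmt),
    sum(hubs$is_hub)))
}
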