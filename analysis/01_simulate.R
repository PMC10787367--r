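#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emulates the design every downstream stage assumes: 3 arms (CON, RMT,
# RFT) x 3 days (15, 35, 56) x 12 calves, species-like compositional
# counts from a log-normal basis with multinomial reads, plus metabolite
# and phenotype tables. Planted structure (recorded as ground truth):
#  - a shared basis coabundance (F01-F02, rho = 0.8),
#  - an RMT-specific direction reversal (F03-F04: +0.8 in RMT, -0.2
#    elsewhere),
#  - a temporal drift on F06,
#  - one mediation chain F05 -> MET01 -> PHE01 (a = 0.8, b = 1, c = 0).

library(coabnet)

seed <- 2024
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- demo_config(seed = seed, n_features = 20)
sim <- simulate_counts(cfg)
traits <- simulate_traits(cfg, sim)

write_feature_table(sim$relative, file.path(out, "species_relative.tsv"))
write_feature_table(sim$counts, file.path(out, "species_counts.tsv"))
write_feature_table(traits$metabolites, file.path(out, "metabolites.tsv"))
write_feature_table(traits$phenotypes, file.path(out, "phenotypes.tsv"))
write.table(sim$meta, file.path(out, "sample_meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_ground_truth(c(sim$truth, traits$truth),
                   file.path(out, "ground_truth.txt"))

cat(sprintf("simulated %d features x %d samples (%d calves, %d arms, %d days)\n",
            nrow(sim$counts$values), ncol(sim$counts$values),
            length(unique(sim$meta$calf_id)),
            length(unique(sim$meta$group)),
            length(unique(sim$meta$day))))
cat("tables and ground truth written under", out, "\n")
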