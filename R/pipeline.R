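#' Demonstration simulation configuration
#'
#' A compact study with every kind of planted structure the pipeline
#' detects: one shared basis correlation, one arm-specific (direction
#' reversing) edge, one temporal shift, and one full mediation chain.
#' Sized so the complete pipeline runs in well under a minute.
#'
#' @param seed Integer seed.
#' @param n_features Number of microbial features.
#' @param n_calves_per_group Calves per arm.
#' @return A [simulation_config].
#' @export
demo_config <- function(seed = 1, n_features = 12, n_calves_per_group = 12) {
  shifts <- matrix(0, n_features, 3)
  shifts[6, ] <- c(0, 1, 1.5)
  simulation_config(
    n_features = n_features,
    n_calves_per_group = n_calves_per_group,
    basis_corr = data.frame(i = 1, j = 2, rho = 0.8),
    group_specific_edges = data.frame(i = 3, j = 4, group = "RMT",
                                      rho_focal = 0.8, rho_other = -0.2),
    temporal_shifts = shifts,
    mediation_chains = data.frame(microbe = 5, metabolite = 1,
                                  phenotype = 1, a = 0.8, b = 1, c = 0),
    n_metabolites = 4, n_phenotypes = 3,
    seed = seed)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full inference pipeline on simulated data
#'
#' Simulates a study, then runs every downstream stage — per-subgroup
#' SparCC networks with permutation significance, cross-arm heterogeneity
#' and IQR specificity per day, per-arm hub scores, differential features
#' on both axes, delta-association screens with arm-specific calls, and
#' mediation over gated triads — writing each stage's table as TSV under
#' `out_dir`. All randomness derives from `seed`, so two runs with the
#' same seed produce byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config A [simulation_config]; default [demo_config] at `seed`.
#' @param n_permutations Permutations per subgroup network (100 keeps the
#'   smallest attainable p at 1/101, just inside the alpha = 0.01 rule).
#' @param focal Focal arm for specificity calls.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = demo_config(seed),
                         n_permutations = 100, focal = "RMT") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(config)
  traits <- simulate_traits(config, sim)
  write_feature_table(sim$relative, file.path(out_dir, "species_relative.tsv"))
  write_tsv(sim$meta, file.path(out_dir, "sample_meta.tsv"))
  write_feature_table(traits$metabolites, file.path(out_dir, "metabolites.tsv"))
  write_feature_table(traits$phenotypes, file.path(out_dir, "phenotypes.tsv"))

  # per-subgroup SparCC networks
  subgroups <- split_subgroups(sim$counts, sim$meta)
  networks <- list()
  r_mats <- list()
  ns <- integer(0)
  for (k in seq_along(subgroups)) {
    sg <- subgroups[[k]]
    nm <- names(subgroups)[k]
    cfg <- sparcc_config(n_permutations = n_permutations,
                         seed = seed + 97L * k)
    r <- sparcc_correlations(sg$table, cfg)
    p <- sparcc_pvalues(sg$table, r, cfg)
    networks[[nm]] <- significant_edges(r, p, alpha = cfg$alpha,
                                        n_samples = length(sg$sample_ids))
    r_mats[[nm]] <- r
    ns[nm] <- length(sg$sample_ids)
    write_tsv(networks[[nm]],
              file.path(out_dir, sprintf("edges_%s.tsv", nm)))
  }

  # cross-arm heterogeneity and specificity, per day
  spec_tables <- list()
  hub_tables <- list()
  for (day in unique(sim$meta$day)) {
    keys <- names(subgroups)[vapply(subgroups, function(s) s$day == day,
                                    logical(1))]
    uni <- edge_universe(networks[keys], r_mats[keys], ns[keys])
    names(uni) <- sub("\\.d\\d+$", "", names(uni))  # r_CON.d15 -> r_CON
    attr(uni, "ns") <- stats::setNames(ns[keys], sub("\\.d\\d+$", "", keys))
    if (nrow(uni)) {
      uni <- heterogeneity_test(uni)
      uni <- specific_edges(uni)
    }
    spec_tables[[paste0("d", day)]] <- uni
    write_tsv(uni, file.path(out_dir, sprintf("edge_meta_d%d.tsv", day)))
    if (nrow(uni) && "specific_group" %in% names(uni)) {
      foc_edges <- uni[!is.na(uni$specific_group) &
                         uni$specific_group == focal,
                       c("feature_a", "feature_b", paste0("r_", focal))]
      names(foc_edges)[3] <- "r"
    } else {
      foc_edges <- data.frame(feature_a = character(0),
                              feature_b = character(0), r = numeric(0))
    }
    hubs <- hub_scores(foc_edges)
    hub_tables[[paste0("d", day)]] <- hubs
    write_tsv(hubs, file.path(out_dir, sprintf("hubs_%s_d%d.tsv", focal, day)))
  }

  # differential features on both axes
  diff_time <- list()
  for (g in config$groups) {
    dt <- differential_features(sim$relative, sim$meta,
                                axis = "time_within_group", subset = g)
    diff_time[[g]] <- dt
    write_tsv(dt, file.path(out_dir, sprintf("diff_time_%s.tsv", g)))
  }
  diff_group <- list()
  for (day in unique(sim$meta$day)) {
    dg <- differential_features(sim$relative, sim$meta,
                                axis = "group_within_time", subset = day)
    diff_group[[paste0("d", day)]] <- dg
    write_tsv(dg, file.path(out_dir, sprintf("diff_group_d%d.tsv", day)))
  }

  # delta associations, per arm, first interval
  days <- sort(unique(sim$meta$day))
  clr <- clr_transform(sim$relative)
  met_log <- log(traits$metabolites$values)
  phe_raw <- traits$phenotypes$values
  screens_met <- list()
  screens_phe <- list()
  for (g in config$groups) {
    m_g <- sim$meta[sim$meta$group == g, , drop = FALSE]
    micro_d <- compute_deltas(clr[, m_g$sample_id, drop = FALSE], m_g,
                              days[1], days[2])
    met_d <- compute_deltas(met_log[, m_g$sample_id, drop = FALSE], m_g,
                            days[1], days[2])
    phe_d <- compute_deltas(phe_raw[, m_g$sample_id, drop = FALSE], m_g,
                            days[1], days[2])
    screens_met[[g]] <- spearman_screen(micro_d, met_d, scope = g)
    screens_phe[[g]] <- spearman_screen(micro_d, phe_d, scope = g)
    if (g == focal) {
      focal_deltas <- list(micro = micro_d, met = met_d, phe = phe_d)
    }
  }
  assoc_met <- call_group_specific(screens_met, focal = focal)
  assoc_phe <- call_group_specific(screens_phe, focal = focal)
  write_tsv(assoc_met, file.path(out_dir, "delta_assoc_metabolites.tsv"))
  write_tsv(assoc_phe, file.path(out_dir, "delta_assoc_phenotypes.tsv"))

  # mediation over gated triads in the focal arm
  triads <- gate_triads(screens_met[[focal]], screens_phe[[focal]],
                        focal_deltas$met, focal_deltas$phe)
  med <- mediate_triads(triads, focal_deltas$micro, focal_deltas$met,
                        focal_deltas$phe, n_sims = 1000, seed = seed + 7777L)
  linkages <- mediation_table(med)
  write_tsv(med, file.path(out_dir, "mediation_all.tsv"))
  write_tsv(linkages, file.path(out_dir, "mediation_linkages.tsv"))

  invisible(list(sim = sim, traits = traits, networks = networks,
                 edge_meta = spec_tables, hubs = hub_tables,
                 diff_time = diff_time, diff_group = diff_group,
                 assoc_met = assoc_met, assoc_phe = assoc_phe,
                 triads = triads, mediation = med, linkages = linkages))
}
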