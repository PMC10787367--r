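#' Simulation configuration
#'
#' Describes a synthetic longitudinal study: three treatment arms sampled
#' at three days, a log-normal latent basis with planted correlations,
#' multinomial read sampling, and optional microbe-metabolite-phenotype
#' mediation chains. Defaults mirror the emulated design: 3 groups x 3
#' days x 12 calves, sequencing depth around `depth_mean` reads.
#'
#' @param n_features Number of microbial features.
#' @param n_calves_per_group Calves per treatment arm.
#' @param groups Treatment arm labels.
#' @param days Sampling days after birth.
#' @param basis_corr Planted basis correlations shared by all arms:
#'   data.frame with columns `i`, `j`, `rho`.
#' @param group_specific_edges Arm-specific basis correlations:
#'   data.frame with columns `i`, `j`, `group`, `rho_focal`, `rho_other`.
#'   The pair's correlation is `rho_focal` in `group` and `rho_other`
#'   elsewhere (a direction reversal by default, the signal the IQR
#'   specificity rule is built to detect).
#' @param temporal_shifts Optional `n_features x length(days)` matrix of
#'   log-mean drifts (defaults to none).
#' @param mediation_chains Planted chains: data.frame with columns
#'   `microbe`, `metabolite`, `phenotype` (indices) and coefficients `a`,
#'   `b`, `c` on the delta scale.
#' @param n_metabolites,n_phenotypes Trait-table dimensions.
#' @param depth_mean Mean reads per sample (sd is 10% of the mean).
#' @param noise_sd Log-scale standard deviation of the latent basis.
#' @param trait_noise_sd Noise sd of the trait deltas.
#' @param dropout Number of samples removed at random (mimics incomplete
#'   collection).
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_features = 30,
                              n_calves_per_group = 12,
                              groups = c("CON", "RMT", "RFT"),
                              days = c(15, 35, 56),
                              basis_corr = NULL,
                              group_specific_edges = NULL,
                              temporal_shifts = NULL,
                              mediation_chains = NULL,
                              n_metabolites = 10,
                              n_phenotypes = 6,
                              depth_mean = 1e5,
                              noise_sd = 1,
                              trait_noise_sd = 0.3,
                              dropout = 0,
                              seed = 1) {
  if (!is.null(basis_corr))
    stopifnot(all(c("i", "j", "rho") %in% names(basis_corr)),
              all(abs(basis_corr$rho) < 1))
  if (!is.null(group_specific_edges))
    stopifnot(all(c("i", "j", "group", "rho_focal", "rho_other") %in%
                    names(group_specific_edges)),
              all(group_specific_edges$group %in% groups),
              all(abs(group_specific_edges$rho_focal) < 1),
              all(abs(group_specific_edges$rho_other) < 1))
  if (is.null(temporal_shifts))
    temporal_shifts <- matrix(0, n_features, length(days))
  stopifnot(nrow(temporal_shifts) == n_features,
            ncol(temporal_shifts) == length(days))
  if (!is.null(mediation_chains))
    stopifnot(all(c("microbe", "metabolite", "phenotype", "a", "b", "c") %in%
                    names(mediation_chains)),
              all(mediation_chains$microbe <= n_features),
              all(mediation_chains$metabolite <= n_metabolites),
              all(mediation_chains$phenotype <= n_phenotypes))
  structure(list(n_features = n_features,
                 n_calves_per_group = n_calves_per_group,
                 groups = groups, days = days,
                 basis_corr = basis_corr,
                 group_specific_edges = group_specific_edges,
                 temporal_shifts = temporal_shifts,
                 mediation_chains = mediation_chains,
                 n_metabolites = n_metabolites,
                 n_phenotypes = n_phenotypes,
                 depth_mean = depth_mean, noise_sd = noise_sd,
                 trait_noise_sd = trait_noise_sd,
                 dropout = dropout, seed = as.integer(seed)),
            class = "simulation_config")
}

# Correlation matrix for one arm: identity + shared planted pairs +
# arm-specific overrides; repaired to the nearest PD correlation matrix if
# planting broke positive definiteness.
arm_basis_matrix <- function(config, group) {
  D <- config$n_features
  R <- diag(D)
  bc <- config$basis_corr
  if (!is.null(bc))
    for (k in seq_len(nrow(bc)))
      R[bc$i[k], bc$j[k]] <- R[bc$j[k], bc$i[k]] <- bc$rho[k]
  gs <- config$group_specific_edges
  if (!is.null(gs))
    for (k in seq_len(nrow(gs))) {
      rho <- if (gs$group[k] == group) gs$rho_focal[k] else gs$rho_other[k]
      R[gs$i[k], gs$j[k]] <- R[gs$j[k], gs$i[k]] <- rho
    }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    warning("planted correlation matrix not positive definite; ",
            "projected to the nearest PD correlation matrix")
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-12)
      stop("correlation matrix remains non-PD after repair")
  }
  R
}

#' Simulate compositional count data with known structure
#'
#' Per arm and day, latent basis abundances are drawn log-normally with
#' the arm's planted correlation matrix and day-shifted means; each
#' sample's sequencing depth is drawn around `depth_mean` and reads are
#' drawn multinomially from the basis fractions. Relative abundances are
#' the normalized counts, so columns sum to one exactly.
#'
#' @param config A [simulation_config].
#' @return List with `counts` and `relative` ([feature_table]s), `meta`
#'   (sample metadata data.frame) and `truth` (ground-truth list:
#'   per-arm basis matrices, planted edges, temporal shifts, base
#'   log-means).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  D <- config$n_features
  feat <- sprintf("F%02d", seq_len(D))
  mu <- stats::rnorm(D, 0, 1.5)
  arms <- lapply(stats::setNames(config$groups, config$groups),
                 function(g) arm_basis_matrix(config, g))
  chol_arm <- lapply(arms, chol)
  counts <- NULL
  meta <- list()
  for (g in config$groups) {
    for (ci in seq_len(config$n_calves_per_group)) {
      calf <- sprintf("%s%02d", g, ci)
      for (di in seq_along(config$days)) {
        day <- config$days[di]
        z <- mu + config$temporal_shifts[, di] +
          config$noise_sd * drop(crossprod(chol_arm[[g]], stats::rnorm(D)))
        frac <- exp(z - max(z))
        frac <- frac / sum(frac)
        depth <- max(1000L, round(stats::rnorm(1, config$depth_mean,
                                               0.1 * config$depth_mean)))
        cts <- drop(stats::rmultinom(1, depth, frac))
        counts <- cbind(counts, cts)
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sprintf("%s_d%d", calf, day), calf_id = calf,
          group = g, day = day, total_reads = depth,
          stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, meta)
  rownames(counts) <- feat
  colnames(counts) <- meta$sample_id
  if (config$dropout > 0) {
    drop_idx <- sample(ncol(counts), config$dropout)
    counts <- counts[, -drop_idx, drop = FALSE]
    meta <- meta[-drop_idx, , drop = FALSE]
  }
  meta$total_reads <- colSums(counts)
  rel <- sweep(counts, 2, colSums(counts), `/`)
  list(counts = feature_table(counts, kind = "species", scale = "count"),
       relative = feature_table(rel, kind = "species", scale = "relative"),
       meta = meta,
       truth = list(mu = mu, basis_matrices = arms,
                    basis_corr = config$basis_corr,
                    group_specific_edges = config$group_specific_edges,
                    temporal_shifts = config$temporal_shifts))
}

#' Simulate metabolite and phenotype tables over simulated counts
#'
#' Chained traits follow the planted linear structure on within-calf
#' deltas: relative to each calf's day-15 baseline, the metabolite's
#' log-intensity changes by `a` times the microbe's CLR change (plus
#' noise) and the phenotype changes by `c` times the microbe's CLR change
#' plus `b` times the metabolite's log change (plus noise). Unchained
#' traits are independent noise around their baselines.
#'
#' @param config The [simulation_config] used for [simulate_counts].
#' @param sim The result of [simulate_counts].
#' @return List with `metabolites` (intensity-scale [feature_table]),
#'   `phenotypes` (raw-scale [feature_table]) and `truth` (the chain
#'   table).
#' @export
simulate_traits <- function(config, sim) {
  set.seed(config$seed + 1L)
  meta <- sim$meta
  clr <- clr_transform(sim$relative)
  n_met <- config$n_metabolites
  n_phe <- config$n_phenotypes
  met_ids <- sprintf("MET%02d", seq_len(n_met))
  phe_ids <- sprintf("PHE%02d", seq_len(n_phe))
  calves <- unique(meta$calf_id)
  base_day <- min(config$days)
  met_base <- matrix(stats::rnorm(n_met * length(calves), 10, 1),
                     n_met, length(calves),
                     dimnames = list(met_ids, calves))
  phe_base <- matrix(stats::rnorm(n_phe * length(calves), 50, 5),
                     n_phe, length(calves),
                     dimnames = list(phe_ids, calves))
  met_log <- matrix(NA_real_, n_met, nrow(meta),
                    dimnames = list(met_ids, meta$sample_id))
  phe <- matrix(NA_real_, n_phe, nrow(meta),
                dimnames = list(phe_ids, meta$sample_id))
  chains <- config$mediation_chains
  for (s in seq_len(nrow(meta))) {
    calf <- meta$calf_id[s]
    day <- meta$day[s]
    base_sample <- sprintf("%s_d%d", calf, base_day)
    has_base <- base_sample %in% colnames(clr) && day != base_day
    met_log[, s] <- met_base[, calf] +
      if (day == base_day) 0 else stats::rnorm(n_met, 0, config$trait_noise_sd)
    phe[, s] <- phe_base[, calf] +
      if (day == base_day) 0 else stats::rnorm(n_phe, 0, config$trait_noise_sd)
    if (!is.null(chains) && has_base) {
      for (k in seq_len(nrow(chains))) {
        dclr <- clr[chains$microbe[k], meta$sample_id[s]] -
          clr[chains$microbe[k], base_sample]
        mrow <- chains$metabolite[k]
        met_log[mrow, s] <- met_log[mrow, s] + chains$a[k] * dclr
        dmet <- met_log[mrow, s] - met_base[mrow, calf]
        prow <- chains$phenotype[k]
        phe[prow, s] <- phe[prow, s] + chains$c[k] * dclr +
          chains$b[k] * dmet
      }
    }
  }
  list(metabolites = feature_table(exp(met_log), kind = "metabolite",
                                   scale = "intensity"),
       phenotypes = feature_table(phe - min(phe) + 1, kind = "phenotype",
                                  scale = "raw"),
       truth = list(chains = chains, met_base = met_base,
                    phe_base = phe_base, shift = -min(phe) + 1))
}

#' Write and read ground truth losslessly
#'
#' Serializes the ground-truth list as text (`dput` with hexadecimal
#' numeric encoding), so reading it back reproduces the object exactly.
#'
#' @param truth A ground-truth list.
#' @param path Output path.
#' @return `path` invisibly ([write_ground_truth]); the object
#'   ([read_ground_truth]).
#' @export
write_ground_truth <- function(truth, path) {
  dput(truth, file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) dget(path)
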