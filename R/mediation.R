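#' Assemble mediation triads from delta-association screens
#'
#' A (microbe, metabolite, phenotype) triad is admitted when the microbe's
#' change is associated with both the metabolite change and the phenotype
#' change (per the screens supplied), and the metabolite and phenotype
#' changes are themselves Spearman-associated at `p < p_max`.
#'
#' @param micro_metab Screen of microbial vs metabolite deltas (from
#'   [spearman_screen]), `significant` column respected.
#' @param micro_pheno Screen of microbial vs phenotype deltas.
#' @param metab_deltas,pheno_deltas Delta matrices (from [compute_deltas])
#'   used to evaluate the metabolite-phenotype gate.
#' @param p_max Metabolite-phenotype gate level.
#' @return Data.frame `treatment`, `mediator`, `outcome` (one row per
#'   admitted triad) with the gate's `rho_my`, `p_my`.
#' @export
gate_triads <- function(micro_metab, micro_pheno,
                        metab_deltas, pheno_deltas, p_max = 0.01) {
  mm <- micro_metab[micro_metab$significant, , drop = FALSE]
  mp <- micro_pheno[micro_pheno$significant, , drop = FALSE]
  microbes <- intersect(unique(mm$feature), unique(mp$feature))
  out <- list()
  calves <- intersect(colnames(metab_deltas), colnames(pheno_deltas))
  for (m in microbes) {
    mets <- mm$trait[mm$feature == m]
    phes <- mp$trait[mp$feature == m]
    for (met in mets) for (ph in phes) {
      g <- spearman_rho_p(metab_deltas[met, calves], pheno_deltas[ph, calves])
      if (!is.na(g["p"]) && g["p"] < p_max) {
        out[[length(out) + 1L]] <- data.frame(
          treatment = m, mediator = met, outcome = ph,
          rho_my = unname(g["rho"]), p_my = unname(g["p"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(treatment = character(0), mediator = character(0),
                      outcome = character(0), rho_my = numeric(0),
                      p_my = numeric(0)))
  unique(do.call(rbind, out))
}

#' Quasi-Bayesian causal mediation for a continuous triad
#'
#' Fits the linear mediator model `M = a0 + a T` and outcome model
#' `Y = c0 + c T + b M` by least squares, draws `n_sims` coefficient
#' vectors from each fit's asymptotic multivariate normal, and forms per
#' draw the average causal mediation effect `ACME = a * b`, the average
#' direct effect `ADE = c`, and `total = ACME + ADE` (an exact identity in
#' the no-interaction linear model). Point estimates are means over draws;
#' the ACME p-value is the two-sided Monte-Carlo sign test
#' `2 min(#\{ACME > 0\}, #\{ACME < 0\}) / n_sims`, floored at `2 / n_sims`.
#'
#' @param treatment,mediator,outcome Numeric vectors (complete triples,
#'   n >= 6).
#' @param n_sims Number of quasi-Bayesian draws.
#' @param seed Integer seed.
#' @return List of class `mediation_result`: `acme`, `ade`, `total`,
#'   `prop_mediated`, `p_acme`, `p_ade`, `p_total`, `n`, `n_sims`, `seed`,
#'   and the per-draw matrix `draws`.
#' @export
mediate_linear <- function(treatment, mediator, outcome,
                           n_sims = 1000, seed = 1) {
  ok <- stats::complete.cases(treatment, mediator, outcome)
  t_ <- treatment[ok]; m_ <- mediator[ok]; y_ <- outcome[ok]
  n <- length(t_)
  if (n < 6) stop("mediation needs at least 6 complete triples, got ", n)
  if (length(unique(t_)) == 1)
    stop("constant treatment: singular mediator design")
  fit_m <- stats::lm(m_ ~ t_)
  fit_y <- stats::lm(y_ ~ t_ + m_)
  set.seed(seed)
  par_m <- MASS::mvrnorm(n_sims, stats::coef(fit_m), stats::vcov(fit_m))
  par_y <- MASS::mvrnorm(n_sims, stats::coef(fit_y), stats::vcov(fit_y))
  a <- par_m[, "t_"]
  c_ <- par_y[, "t_"]
  b <- par_y[, "m_"]
  acme <- a * b
  ade <- c_
  total <- acme + ade
  sign_p <- function(d) max(2 * min(mean(d > 0), mean(d < 0)), 2 / n_sims)
  res <- list(acme = mean(acme), ade = mean(ade), total = mean(total),
              prop_mediated = mean(acme) / mean(total),
              p_acme = sign_p(acme), p_ade = sign_p(ade),
              p_total = sign_p(total),
              n = n, n_sims = n_sims, seed = as.integer(seed),
              draws = cbind(acme = acme, ade = ade, total = total))
  class(res) <- "mediation_result"
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "mediation (n = %d, %d draws)\n  ACME  %+.4f (p = %.4g)\n  ADE   %+.4f (p = %.4g)\n  total %+.4f (p = %.4g)\n  prop. mediated %.3f\n",
    x$n, x$n_sims, x$acme, x$p_acme, x$ade, x$p_ade,
    x$total, x$p_total, x$prop_mediated))
  invisible(x)
}

#' Mediate every gated triad over delta tables
#'
#' @param triads Data.frame from [gate_triads].
#' @param micro_deltas,metab_deltas,pheno_deltas Delta matrices sharing
#'   calf columns.
#' @param n_sims,seed Passed to [mediate_linear]; each triad uses an
#'   independent seed derived from `seed`.
#' @return Data.frame, one row per triad, with `acme`, `ade`, `total`,
#'   `prop_mediated`, `p_acme`, `n`.
#' @export
mediate_triads <- function(triads, micro_deltas, metab_deltas, pheno_deltas,
                           n_sims = 1000, seed = 1) {
  calves <- Reduce(intersect, list(colnames(micro_deltas),
                                   colnames(metab_deltas),
                                   colnames(pheno_deltas)))
  rows <- lapply(seq_len(nrow(triads)), function(i) {
    res <- mediate_linear(micro_deltas[triads$treatment[i], calves],
                          metab_deltas[triads$mediator[i], calves],
                          pheno_deltas[triads$outcome[i], calves],
                          n_sims = n_sims, seed = seed + i)
    data.frame(treatment = triads$treatment[i],
               mediator = triads$mediator[i],
               outcome = triads$outcome[i],
               acme = res$acme, ade = res$ade, total = res$total,
               prop_mediated = res$prop_mediated,
               p_acme = res$p_acme, n = res$n,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(treatment = character(0), mediator = character(0),
                      outcome = character(0), acme = numeric(0),
                      ade = numeric(0), total = numeric(0),
                      prop_mediated = numeric(0), p_acme = numeric(0),
                      n = integer(0)))
  do.call(rbind, rows)
}

#' Reported mediation linkages
#'
#' Filters mediated triads at `p_acme < alpha` and orders them by
#' phenotype then mediator, the grouping used for Sankey-style displays
#' (microbe to metabolite to phenotype).
#'
#' @param results Data.frame from [mediate_triads].
#' @param alpha Significance level.
#' @return The filtered, sorted data.frame.
#' @export
mediation_table <- function(results, alpha = 0.05) {
  out <- results[!is.na(results$p_acme) & results$p_acme < alpha, ,
                 drop = FALSE]
  out <- out[order(out$outcome, out$mediator, out$treatment), , drop = FALSE]
  rownames(out) <- NULL
  out
}
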