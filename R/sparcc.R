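#' SparCC configuration
#'
#' Parameters of the SparCC basis-correlation estimator and its permutation
#' test. Defaults follow the reference algorithm: 20 Dirichlet-resampled
#' inner iterations aggregated by the component-wise median, up to 10
#' exclusion rounds at threshold 0.1, and 100 permutations tested at
#' alpha = 0.01 (so an edge can only pass by exceeding every permuted
#' value).
#'
#' @param n_inner_iterations Number of Dirichlet fraction draws averaged.
#' @param n_exclusion_rounds Maximum strongly-correlated-pair exclusions.
#' @param exclusion_threshold Absolute correlation above which the
#'   strongest pair is excluded from the basis-variance system.
#' @param n_permutations Number of feature-wise permutations for p-values.
#' @param alpha Significance level for edge calls.
#' @param seed Integer seed governing Dirichlet draws and permutations.
#' @param aggregation `"median"` (reference behavior) or `"mean"` across
#'   inner iterations.
#' @param point_estimate If `TRUE`, skip Dirichlet resampling and use the
#'   deterministic fractions `(counts + 1) / sum(counts + 1)` — useful for
#'   exact tests.
#' @return A list of class `sparcc_config`.
#' @export
sparcc_config <- function(n_inner_iterations = 20,
                          n_exclusion_rounds = 10,
                          exclusion_threshold = 0.1,
                          n_permutations = 100,
                          alpha = 0.01,
                          seed = 1,
                          aggregation = c("median", "mean"),
                          point_estimate = FALSE) {
  stopifnot(n_permutations >= 1, alpha > 0, alpha < 1,
            exclusion_threshold > 0, exclusion_threshold < 1)
  structure(list(n_inner_iterations = n_inner_iterations,
                 n_exclusion_rounds = n_exclusion_rounds,
                 exclusion_threshold = exclusion_threshold,
                 n_permutations = n_permutations,
                 alpha = alpha,
                 seed = as.integer(seed),
                 aggregation = match.arg(aggregation),
                 point_estimate = point_estimate),
            class = "sparcc_config")
}

# Basis correlations from a log-ratio variation matrix T under the sparsity
# approximation. Returns list(r, flagged). The linear system is
# M %*% omega = rowSums(T restricted to non-excluded pairs), with
# M = J + (D - 2) I, updated as pairs are excluded.
sparcc_from_variation <- function(T_mat, n_exclusion_rounds, threshold) {
  D <- nrow(T_mat)
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  excluded <- matrix(FALSE, D, D)
  n_excl_per <- integer(D)
  compute_r <- function() {
    tvec <- rowSums(T_mat * !excluded)
    omega <- solve(M, tvec)
    bad <- omega <= 0
    omega_c <- pmax(omega, .Machine$double.eps)
    denom <- 2 * sqrt(outer(omega_c, omega_c))
    r <- (outer(omega_c, omega_c, `+`) - T_mat) / denom
    r[r > 1] <- 1
    r[r < -1] <- -1
    diag(r) <- 1
    list(r = r, bad = bad)
  }
  res <- compute_r()
  for (round in seq_len(n_exclusion_rounds)) {
    cand <- abs(res$r)
    cand[excluded] <- 0
    diag(cand) <- 0
    # features already excluded from nearly every pair leave the system
    dropped <- n_excl_per >= D - 3
    cand[dropped, ] <- 0
    cand[, dropped] <- 0
    m <- max(cand)
    if (m <= threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    n_excl_per[i] <- n_excl_per[i] + 1L
    n_excl_per[j] <- n_excl_per[j] + 1L
    res <- compute_r()
  }
  flagged <- res$bad | n_excl_per >= D - 3
  r <- res$r
  if (any(flagged)) {
    r[flagged, ] <- NA_real_
    r[, flagged] <- NA_real_
    diag(r) <- 1
  }
  list(r = r, flagged = flagged)
}

# One SparCC estimate on a counts matrix using the current RNG stream.
sparcc_r_once <- function(counts, config) {
  D <- nrow(counts)
  n <- ncol(counts)
  if (config$point_estimate) {
    f <- sweep(counts + 1, 2, colSums(counts + 1), `/`)
    L <- log(f)
    C <- stats::cov(t(L))
    v <- diag(C)
    T_mat <- outer(v, v, `+`) - 2 * C
    res <- sparcc_from_variation(T_mat, config$n_exclusion_rounds,
                                 config$exclusion_threshold)
    return(res$r)
  }
  acc <- array(NA_real_, c(D, D, config$n_inner_iterations))
  for (k in seq_len(config$n_inner_iterations)) {
    g <- matrix(stats::rgamma(D * n, shape = counts + 1), D, n)
    f <- sweep(g, 2, colSums(g), `/`)
    L <- log(f)
    C <- stats::cov(t(L))
    v <- diag(C)
    T_mat <- outer(v, v, `+`) - 2 * C
    res <- sparcc_from_variation(T_mat, config$n_exclusion_rounds,
                                 config$exclusion_threshold)
    acc[, , k] <- res$r
  }
  agg <- if (config$aggregation == "median") {
    apply(acc, c(1, 2), stats::median, na.rm = TRUE)
  } else {
    apply(acc, c(1, 2), mean, na.rm = TRUE)
  }
  agg[is.nan(agg)] <- NA_real_
  diag(agg) <- 1
  agg
}

#' SparCC basis correlations
#'
#' Estimates correlations between the latent basis abundances underlying
#' compositional count data. Per inner iteration, fractions are drawn per
#' sample from a Dirichlet posterior (counts + 1); log-ratio variances
#' `t_ij = var(log(x_i / x_j))` are computed; basis variances are solved
#' under the sparsity approximation with iterative exclusion of the most
#' strongly correlated pair; and
#' `r_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`, clipped to `[-1, 1]`.
#' The reported matrix is the component-wise median over inner iterations.
#' Features whose basis variance turns negative (or that get excluded from
#' nearly all pairs) have their correlations set to `NA` with a warning.
#'
#' @param counts A count-scale [feature_table] or nonnegative integer
#'   matrix (features x samples), at least 4 features and 4 samples.
#' @param config A [sparcc_config].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sparcc_correlations <- function(counts, config = sparcc_config()) {
  v <- if (inherits(counts, "feature_table")) counts$values else counts
  if (nrow(v) < 4) stop("SparCC needs at least 4 features")
  if (ncol(v) < 4) stop("SparCC needs at least 4 samples")
  set.seed(config$seed)
  r <- sparcc_r_once(v, config)
  if (anyNA(r))
    warning("negative basis variance: correlations of flagged feature(s) set to NA")
  dimnames(r) <- list(rownames(v), rownames(v))
  r
}

#' Permutation p-values for SparCC correlations
#'
#' Each permutation independently shuffles every feature's counts across
#' samples (destroying between-feature dependence while preserving
#' marginals) and recomputes the SparCC matrix. Two-sided
#' `p = (1 + #\{perm: |r_perm| >= |r_obs|\}) / (1 + n_permutations)`, so the
#' smallest attainable p with 100 permutations is 1/101, and the P < 0.01
#' rule is met only by exceeding all permuted values.
#'
#' @inheritParams sparcc_correlations
#' @param observed_r Matrix from [sparcc_correlations] on the same counts.
#' @return Matrix of permutation p-values (diagonal `NA`).
#' @export
sparcc_pvalues <- function(counts, observed_r, config = sparcc_config()) {
  v <- if (inherits(counts, "feature_table")) counts$values else counts
  stopifnot(nrow(v) == nrow(observed_r))
  D <- nrow(v); n <- ncol(v)
  set.seed(config$seed + 1L)
  exceed <- matrix(0L, D, D)
  for (b in seq_len(config$n_permutations)) {
    perm <- v
    for (i in seq_len(D)) perm[i, ] <- v[i, sample.int(n)]
    r_b <- sparcc_r_once(perm, config)
    cmp <- abs(r_b) >= abs(observed_r) - 1e-12
    cmp[is.na(cmp)] <- FALSE  # flagged features in a permutation don't count
    exceed <- exceed + cmp
  }
  p <- (1 + exceed) / (1 + config$n_permutations)
  p[is.na(observed_r)] <- NA_real_
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed_r)
  p
}

#' Extract significant edges from SparCC matrices
#'
#' @param r Correlation matrix.
#' @param p Permutation p-value matrix of the same shape.
#' @param alpha Significance level; edges with `p < alpha` are retained.
#' @param n_samples Optional subgroup sample count carried on the result.
#' @return A data.frame with columns `feature_a`, `feature_b` (each
#'   unordered pair once, `feature_a < feature_b`), `r`, `p`.
#' @export
significant_edges <- function(r, p, alpha = 0.01, n_samples = NA_integer_) {
  stopifnot(all(dim(r) == dim(p)))
  ids <- rownames(r)
  if (is.null(ids)) ids <- paste0("F", seq_len(nrow(r)))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  keep <- !is.na(p[ut]) & p[ut] < alpha
  ut <- ut[keep, , drop = FALSE]
  a <- ids[ut[, 1]]; b <- ids[ut[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(feature_a = a, feature_b = b,
                    r = r[ut], p = p[ut], stringsAsFactors = FALSE)
  out <- out[order(out$feature_a, out$feature_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_samples") <- n_samples
  out
}
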