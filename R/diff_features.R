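#' Kruskal-Wallis test for one feature across strata
#'
#' Tie-corrected H referred to a chi-square with k - 1 degrees of freedom
#' (via [stats::kruskal.test]). A completely constant input returns
#' `H = 0, p = 1` rather than the 0/0 of the tie correction.
#'
#' @param values Numeric vector.
#' @param strata Stratum labels (factor or vector), at least two strata.
#' @return Named vector `c(H, p)`.
#' @export
kruskal_strata <- function(values, strata) {
  strata <- as.factor(strata)
  if (nlevels(droplevels(strata)) < 2) stop("need at least two strata")
  if (length(unique(values)) == 1) return(c(H = 0, p = 1))
  kt <- stats::kruskal.test(values, strata)
  c(H = unname(kt$statistic), p = kt$p.value)
}

#' Dunn's post hoc pairwise z tests
#'
#' Pairwise mean-rank differences standardized by the tie-corrected pooled
#' variance `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_a + 1/n_b)`, with
#' two-sided unadjusted p-values. The family-level decision is left to the
#' Kruskal FDR.
#'
#' @inheritParams kruskal_strata
#' @return Data.frame `group_a`, `group_b`, `z`, `p` (one row per pair).
#' @export
dunn_posthoc <- function(values, strata) {
  strata <- droplevels(as.factor(strata))
  lev <- levels(strata)
  stopifnot(length(lev) >= 2)
  r <- rank(values, ties.method = "average")
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  mean_rank <- tapply(r, strata, mean)
  n <- tapply(r, strata, length)
  pairs <- utils::combn(lev, 2)
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (n[a] == 0 || n[b] == 0) next
    se <- sqrt(sigma2 * (1 / n[a] + 1 / n[b]))
    z <- (mean_rank[a] - mean_rank[b]) / se
    if (!is.finite(z)) z <- 0
    out$z[k] <- z
    out$p[k] <- 2 * stats::pnorm(-abs(z))
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the supplied family (NAs are preserved and
#' do not count toward the family size).
#'
#' @param p Numeric vector of p-values.
#' @return Vector of adjusted p-values, `fdr >= p` elementwise.
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Fisher's exact test on a contingency table
#'
#' Conditional hypergeometric two-sided test via [stats::fisher.test]
#' (the network algorithm handles small r x c tables beyond 2 x 2). For a
#' 2 x 2 table with a zero margin the odds ratio is displayed with a 0.5
#' continuity correction, but the p-value is the uncorrected exact one
#' (which equals 1 for a degenerate margin).
#'
#' @param table Matrix of nonnegative integer counts.
#' @return List with `odds_ratio` (`NA` beyond 2 x 2) and `p`.
#' @export
fisher_exact_test <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0))
  ft <- stats::fisher.test(table)
  or <- if (all(dim(table) == c(2, 2))) {
    if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
      tc <- table + 0.5
      (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
    } else unname(ft$estimate)
  } else NA_real_
  list(odds_ratio = or, p = ft$p.value)
}

#' Wilcoxon rank-sum test for two independent samples
#'
#' Exact for small untied samples, tie-corrected normal approximation
#' otherwise (the [stats::wilcox.test] defaults).
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return Named vector `c(W, p)`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (length(unique(c(a, b))) == 1)
    return(c(W = length(a) * length(b) / 2, p = 1))  # complete ties
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  c(W = unname(wt$statistic), p = wt$p.value)
}

#' Differential-feature testing across time points or groups
#'
#' For each feature, runs a Kruskal-Wallis test across the strata of the
#' chosen axis (days within one group, or groups within one day), adds Dunn
#' post hoc contrasts where three or more strata are present, and controls
#' the Kruskal p-values by Benjamini-Hochberg across features. Microbial
#' tables are CLR + inverse-rank transformed by default (ranks, and hence
#' all p-values, are unchanged by the monotone inverse-rank step; it is
#' applied for effect-size comparability); phenotype tables are tested
#' untransformed.
#'
#' @param x A [feature_table] or numeric matrix (features x samples).
#' @param meta Sample metadata.
#' @param axis `"time_within_group"` (strata = days, restricted to
#'   `subset`) or `"group_within_time"` (strata = groups, restricted to
#'   `subset`).
#' @param subset The group (for the time axis) or day (for the group axis)
#'   defining the tested stratum slice; `NULL` uses all samples and
#'   stratifies by the axis variable only.
#' @param transform `"clr_irn"` or `"none"`.
#' @return Data.frame with `feature`, `H`, `p`, `fdr` and one
#'   `z_<a>.<b>`/`p_<a>.<b>` pair per Dunn contrast.
#' @export
differential_features <- function(x, meta,
                                  axis = c("time_within_group",
                                           "group_within_time"),
                                  subset = NULL,
                                  transform = c("clr_irn", "none")) {
  axis <- match.arg(axis)
  transform <- match.arg(transform)
  v <- if (inherits(x, "feature_table")) x$values else x
  if (transform == "clr_irn") v <- inverse_rank(clr_transform(v))
  idx <- match(colnames(v), meta$sample_id)
  if (anyNA(idx)) stop("samples without metadata")
  m <- meta[idx, , drop = FALSE]
  if (axis == "time_within_group") {
    keep <- if (is.null(subset)) rep(TRUE, nrow(m)) else m$group == subset
    strata <- m$day[keep]
  } else {
    keep <- if (is.null(subset)) rep(TRUE, nrow(m)) else m$day == subset
    strata <- m$group[keep]
  }
  strata <- as.factor(strata)
  vv <- v[, keep, drop = FALSE]
  res <- t(apply(vv, 1, kruskal_strata, strata = strata))
  out <- data.frame(feature = rownames(vv), H = res[, "H"], p = res[, "p"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fdr <- bh_fdr(out$p)
  if (nlevels(strata) >= 3) {
    dunn_list <- apply(vv, 1, dunn_posthoc, strata = strata)
    pair_names <- paste0(dunn_list[[1]]$group_a, ".", dunn_list[[1]]$group_b)
    for (k in seq_along(pair_names)) {
      out[[paste0("z_", pair_names[k])]] <-
        vapply(dunn_list, function(d) d$z[k], numeric(1))
      out[[paste0("p_", pair_names[k])]] <-
        vapply(dunn_list, function(d) d$p[k], numeric(1))
    }
  }
  out
}
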