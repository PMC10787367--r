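#' Within-calf changes between two time points
#'
#' For every calf observed at both days, computes
#' `value(day_b) - value(day_a)` per feature. Calves missing either day are
#' excluded with a message.
#'
#' @param x A [feature_table] or numeric matrix (features x samples),
#'   typically already transformed (CLR for microbial features, log for
#'   metabolite intensities, raw for phenotypes).
#' @param meta Sample metadata.
#' @param day_a,day_b The two time points, `day_a < day_b`.
#' @return Numeric matrix features x calves with attribute
#'   `interval = c(day_a, day_b)`; columns named by calf id.
#' @export
compute_deltas <- function(x, meta, day_a, day_b) {
  stopifnot(day_a < day_b)
  v <- if (inherits(x, "feature_table")) x$values else x
  idx <- match(colnames(v), meta$sample_id)
  if (anyNA(idx)) stop("samples without metadata")
  m <- meta[idx, , drop = FALSE]
  if (!any(m$day == day_a) || !any(m$day == day_b))
    stop("both days must be present in the metadata")
  calves_a <- m$calf_id[m$day == day_a]
  calves_b <- m$calf_id[m$day == day_b]
  calves <- intersect(calves_a, calves_b)
  dropped <- setdiff(union(calves_a, calves_b), calves)
  if (length(dropped))
    message("calves missing one day, excluded: ",
            paste(dropped, collapse = ", "))
  col_a <- match(paste(calves, day_a), paste(m$calf_id, m$day))
  col_b <- match(paste(calves, day_b), paste(m$calf_id, m$day))
  out <- v[, col_b, drop = FALSE] - v[, col_a, drop = FALSE]
  colnames(out) <- calves
  attr(out, "interval") <- c(day_a, day_b)
  out
}

# All permutations of 1..n as an n! x n index matrix, cached per n.
perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  P <- matrix(1L, 1, 1)
  if (n > 1) {
    for (m in 2:n) {
      k <- nrow(P)
      out <- matrix(0L, k * m, m)
      for (pos in seq_len(m)) {
        rows <- ((pos - 1) * k + 1):(pos * k)
        out[rows, pos] <- m
        out[rows, -pos] <- P
      }
      P <- out
    }
  }
  perm_cache[[key]] <- P
  P
}

#' Spearman correlation with exact-permutation p for small n
#'
#' Computes Spearman's rho (Pearson on average ranks, so ties are handled)
#' and a two-sided p-value: for `n <= 9`, the exact permutation p
#' `#\{perm: |rho_perm| >= |rho_obs|\} / n!` by exhaustive enumeration; for
#' larger untied samples, the exact-null Edgeworth approximation of
#' [stats::cor.test] (`exact = TRUE`), which keeps small-sample tail
#' probabilities calibrated where the t approximation is anticonservative;
#' with ties, the t approximation. Constant input yields `NA` for both.
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact_n_max Largest n for which the exact permutation null is
#'   enumerated.
#' @return Named vector `c(rho, p)`.
#' @export
spearman_rho_p <- function(x, y, exact_n_max = 9) {
  n <- length(x)
  stopifnot(length(y) == n)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3 || length(unique(x)) == 1 || length(unique(y)) == 1)
    return(c(rho = NA_real_, p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    P <- all_permutations(n)
    xc <- rx - mean(rx)
    yc <- ry - mean(ry)
    scale <- sqrt(sum(xc^2) * sum(yc^2))
    # rho for every permutation of one margin's ranks
    rho_perm <- (matrix(yc[P], nrow(P), n) %*% xc) / scale
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    untied <- !anyDuplicated(x) && !anyDuplicated(y)
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = untied)$p.value)
  }
  c(rho = rho, p = min(p, 1))
}

#' Screen feature-change vs trait-change associations
#'
#' Tests every microbial feature against every trait on the calves shared
#' by both delta tables (at least five), flagging associations meeting the
#' dual threshold `|rho| > r_min` and `p < p_max`.
#'
#' @param micro_deltas Feature-change matrix from [compute_deltas].
#' @param trait_deltas Trait-change matrix from [compute_deltas].
#' @param r_min Minimum absolute Spearman rho (set 0 to screen on p only).
#' @param p_max Significance level.
#' @param scope Label recorded on the result (e.g. a group name or
#'   `"pooled"`).
#' @return Data.frame `feature`, `trait`, `scope`, `n`, `rho`, `p`,
#'   `significant`.
#' @export
spearman_screen <- function(micro_deltas, trait_deltas,
                            r_min = 0.7, p_max = 0.01, scope = "pooled") {
  calves <- intersect(colnames(micro_deltas), colnames(trait_deltas))
  if (length(calves) < 5)
    stop("need at least 5 shared calves, got ", length(calves))
  Mx <- micro_deltas[, calves, drop = FALSE]
  Tx <- trait_deltas[, calves, drop = FALSE]
  grid <- expand.grid(feature = rownames(Mx), trait = rownames(Tx),
                      stringsAsFactors = FALSE)
  res <- mapply(function(f, tr) spearman_rho_p(Mx[f, ], Tx[tr, ]),
                grid$feature, grid$trait)
  out <- data.frame(feature = grid$feature, trait = grid$trait,
                    scope = scope, n = length(calves),
                    rho = res["rho", ], p = res["p", ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- !is.na(out$p) & !is.na(out$rho) &
    abs(out$rho) > r_min & out$p < p_max
  out
}

#' Call group-specific delta associations
#'
#' An association is specific to the focal group when it is significant
#' there and, in every other group, is either not significant or has the
#' opposite sign of correlation. Missing group estimates count as not
#' significant.
#'
#' @param screens Named list of [spearman_screen] results, one per group,
#'   each covering the same (feature, trait) pairs.
#' @param focal Name of the focal group (default `"RMT"`).
#' @return The focal group's screen with a `group_specific` column added.
#' @export
call_group_specific <- function(screens, focal = "RMT") {
  stopifnot(focal %in% names(screens))
  foc <- screens[[focal]]
  key <- function(d) paste(d$feature, d$trait, sep = "\r")
  spec <- foc$significant
  for (g in setdiff(names(screens), focal)) {
    oth <- screens[[g]]
    idx <- match(key(foc), key(oth))
    o_sig <- !is.na(idx) & oth$significant[idx]
    o_sig[is.na(o_sig)] <- FALSE
    o_rho <- oth$rho[idx]
    opposite <- !is.na(o_rho) & sign(o_rho) != sign(foc$rho) &
      sign(foc$rho) != 0
    spec <- spec & (!o_sig | opposite)
  }
  foc$group_specific <- spec
  foc
}
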