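#' Centered log-ratio transform
#'
#' Per sample, `clr(x)_i = log(x_i + eps) - mean_i log(x_i + eps)`. The
#' default pseudocount is half the smallest nonzero value of the table,
#' the usual compositional-zero treatment.
#'
#' @param x A [feature_table] (relative abundances or counts).
#' @param pseudocount Positive value added before taking logs, or `NULL`
#'   for the default.
#' @return A numeric matrix of CLR values (features x samples) with
#'   attribute `transform_tag = "clr"`.
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  v <- if (inherits(x, "feature_table")) x$values else x
  if (is.null(pseudocount)) {
    nz <- v[v > 0]
    if (!length(nz)) stop("all-zero table: cannot choose a pseudocount")
    pseudocount <- min(nz) / 2
  }
  stopifnot(pseudocount > 0)
  lg <- log(v + pseudocount)
  out <- sweep(lg, 2, colMeans(lg))
  attr(out, "transform_tag") <- "clr"
  out
}

#' Rank-based inverse normal transform
#'
#' Each feature is transformed across samples to
#' `qnorm((rank - 0.5) / n)` (the rankit offset) with average ranks for
#' ties; Blom's offset `(rank - 3/8) / (n + 1/4)` is available. A constant
#' feature maps to all zeros (every value sits at the distribution's
#' center).
#'
#' @param x A [feature_table] or numeric matrix (features x samples).
#' @param offset `"rankit"` (default) or `"blom"`.
#' @return A numeric matrix with attribute `transform_tag = "irn"`.
#' @export
inverse_rank <- function(x, offset = c("rankit", "blom")) {
  offset <- match.arg(offset)
  v <- if (inherits(x, "feature_table")) x$values else x
  n <- ncol(v)
  out <- t(apply(v, 1, function(row) {
    r <- rank(row, ties.method = "average")
    p <- if (offset == "rankit") (r - 0.5) / n else (r - 3 / 8) / (n + 1 / 4)
    stats::qnorm(p)
  }))
  dimnames(out) <- dimnames(v)
  attr(out, "transform_tag") <- "irn"
  out
}

#' Per-sample Shannon diversity
#'
#' Samples are renormalized to sum to one over the retained features, then
#' `H = -sum(p * log(p))` (natural log) is computed via [vegan::diversity].
#' All-zero samples yield `NA` with a warning.
#'
#' @param x A [feature_table] of nonnegative abundances.
#' @return Named numeric vector of per-sample Shannon indices.
#' @export
shannon_index <- function(x) {
  v <- if (inherits(x, "feature_table")) x$values else x
  tot <- colSums(v)
  out <- rep(NA_real_, ncol(v))
  names(out) <- colnames(v)
  if (any(tot == 0)) warning("all-zero sample(s): Shannon undefined, returning NA")
  ok <- tot > 0
  if (any(ok))
    out[ok] <- vegan::diversity(t(v[, ok, drop = FALSE]), index = "shannon")
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = sum|a - b| / sum(a + b)` over features, computed with
#' [vegan::vegdist]. Pairs of all-zero samples are undefined and returned
#' as `NA`.
#'
#' @param x A [feature_table] of nonnegative abundances.
#' @return A symmetric sample-by-sample matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  v <- if (inherits(x, "feature_table")) x$values else x
  d <- as.matrix(vegan::vegdist(t(v), method = "bray"))
  zero <- colSums(v) == 0
  if (any(zero)) d[zero, zero] <- NA_real_
  diag(d) <- 0
  d
}

#' Within-subgroup pairwise dissimilarities
#'
#' For each (group, day) subgroup, collects the Bray-Curtis values of all
#' unordered sample pairs inside the subgroup — the inter-calf
#' compositional spread the transplantation arm is expected to shrink.
#'
#' @param bc A sample-by-sample dissimilarity matrix (as from
#'   [bray_curtis]).
#' @param meta Sample metadata covering the matrix's samples.
#' @return A named list (one element per subgroup, `"<group>.d<day>"`) of
#'   numeric vectors; subgroups with fewer than two samples give empty
#'   vectors.
#' @export
within_group_dissimilarity <- function(bc, meta) {
  idx <- match(rownames(bc), meta$sample_id)
  if (anyNA(idx)) stop("dissimilarity matrix contains samples without metadata")
  key <- paste0(meta$group[idx], ".d", meta$day[idx])
  out <- list()
  for (k in unique(key)) {
    sel <- which(key == k)
    if (length(sel) < 2) {
      out[[k]] <- numeric(0)
    } else {
      sub <- bc[sel, sel]
      out[[k]] <- sub[lower.tri(sub)]
    }
  }
  out
}
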