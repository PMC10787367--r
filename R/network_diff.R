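#' Build the edge universe across subgroup networks
#'
#' Takes the union of edges significant in at least one subgroup and fills
#' in every subgroup's effect size (SparCC r) for each edge, regardless of
#' that subgroup's own significance. Unordered pairs are deduplicated by
#' identity.
#'
#' @param networks Named list of per-subgroup edge data.frames (as from
#'   [significant_edges]).
#' @param r_matrices Named list (same names) of full SparCC correlation
#'   matrices.
#' @param ns Named vector of per-subgroup sample counts.
#' @return A data.frame with `feature_a`, `feature_b`, one `r_<subgroup>`
#'   column per subgroup, plus attribute `ns`.
#' @export
edge_universe <- function(networks, r_matrices, ns) {
  stopifnot(length(networks) >= 1,
            all(names(networks) %in% names(r_matrices)),
            all(names(networks) %in% names(ns)))
  pairs <- unique(do.call(rbind, lapply(networks, function(e)
    e[, c("feature_a", "feature_b")])))
  if (is.null(pairs) || !nrow(pairs)) {
    out <- data.frame(feature_a = character(0), feature_b = character(0))
    attr(out, "ns") <- ns
    return(out)
  }
  rownames(pairs) <- NULL
  out <- pairs[order(pairs$feature_a, pairs$feature_b), , drop = FALSE]
  rownames(out) <- NULL
  for (s in names(networks)) {
    R <- r_matrices[[s]]
    ia <- match(out$feature_a, rownames(R))
    ib <- match(out$feature_b, rownames(R))
    vals <- rep(NA_real_, nrow(out))
    ok <- !is.na(ia) & !is.na(ib)
    vals[ok] <- R[cbind(ia[ok], ib[ok])]
    if (any(!ok))
      message(sum(!ok), " edge(s) touch features absent from subgroup ", s)
    out[[paste0("r_", s)]] <- vals
  }
  attr(out, "ns") <- ns[names(networks)]
  out
}

#' Cochran's Q heterogeneity test for one edge
#'
#' Effect sizes are Fisher-z transformed (`atanh`, after clipping r to
#' +/- 0.999) with asymptotic variance `1 / (n - 3)`; the pooled effect is
#' the inverse-variance weighted mean and
#' `Q = sum(w * (z - pooled)^2)`, referred to a chi-square with `k - 1`
#' degrees of freedom. Subgroups with `n <= 3` are dropped with a warning;
#' fewer than two usable subgroups yield `NA`.
#'
#' @param effect_sizes Numeric vector of per-subgroup correlations.
#' @param ns Integer vector of per-subgroup sample counts.
#' @return Named vector `c(Q, p, k)`.
#' @export
cochran_q <- function(effect_sizes, ns) {
  stopifnot(length(effect_sizes) == length(ns))
  ok <- !is.na(effect_sizes) & !is.na(ns)
  if (any(ok & ns <= 3)) {
    warning("dropping subgroup(s) with n <= 3 from Cochran Q")
    ok <- ok & ns > 3
  }
  k <- sum(ok)
  if (k < 2) return(c(Q = NA_real_, p = NA_real_, k = k))
  z <- atanh(pmin(pmax(effect_sizes[ok], -0.999), 0.999))
  w <- ns[ok] - 3
  pooled <- sum(w * z) / sum(w)
  Q <- sum(w * (z - pooled)^2)
  p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  c(Q = Q, p = p, k = k)
}

#' Heterogeneity testing with BH control over an edge universe
#'
#' Applies [cochran_q] to every row of an [edge_universe] table and adjusts
#' the p-values by Benjamini-Hochberg across all tested edges.
#'
#' @param universe Data.frame from [edge_universe].
#' @param fdr_level Edges with `fdr < fdr_level` get `heterogeneous = TRUE`.
#' @return The input with columns `Q`, `p`, `fdr`, `heterogeneous` added.
#' @export
heterogeneity_test <- function(universe, fdr_level = 0.05) {
  ns <- attr(universe, "ns")
  rcols <- grep("^r_", names(universe), value = TRUE)
  subgroups <- sub("^r_", "", rcols)
  stopifnot(all(subgroups %in% names(ns)))
  qp <- t(apply(as.matrix(universe[, rcols, drop = FALSE]), 1, function(es)
    cochran_q(es, ns[subgroups])[c("Q", "p")]))
  universe$Q <- qp[, 1]
  universe$p <- qp[, 2]
  universe$fdr <- bh_fdr(universe$p)
  universe$heterogeneous <- !is.na(universe$fdr) & universe$fdr < fdr_level
  universe
}

#' IQR fence rule for group-specific effect sizes
#'
#' Computes Q1 and Q3 of the k effect sizes by linear interpolation
#' (quantile type 7), fences at `Q1 - factor * IQR` and
#' `Q3 + factor * IQR`, and assigns specificity only when exactly one of
#' the extremes falls outside its fence. Ties for the minimum or maximum
#' prevent assignment, as do missing effect sizes.
#'
#' @param effect_sizes Named numeric vector (one value per group, k >= 3).
#' @param factor Fence multiplier (the study's rule uses 0.75).
#' @return A list with `q1`, `q3`, `iqr`, `low_fence`, `high_fence`,
#'   `outlier_group` (`NA` if none), and `direction` (`"low"`, `"high"`,
#'   or `"none"`).
#' @export
iqr_specificity <- function(effect_sizes, factor = 0.75) {
  if (anyNA(effect_sizes)) {
    message("missing effect size: no specificity call")
    return(list(q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
                low_fence = NA_real_, high_fence = NA_real_,
                outlier_group = NA_character_, direction = "none"))
  }
  stopifnot(length(effect_sizes) >= 3)
  qs <- stats::quantile(effect_sizes, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  lo <- qs[1] - factor * iqr
  hi <- qs[2] + factor * iqr
  nm <- names(effect_sizes)
  if (is.null(nm)) nm <- as.character(seq_along(effect_sizes))
  candidates <- character(0)
  direction <- character(0)
  if (min(effect_sizes) < lo && sum(effect_sizes == min(effect_sizes)) == 1) {
    candidates <- c(candidates, nm[which.min(effect_sizes)])
    direction <- c(direction, "low")
  }
  if (max(effect_sizes) > hi && sum(effect_sizes == max(effect_sizes)) == 1) {
    candidates <- c(candidates, nm[which.max(effect_sizes)])
    direction <- c(direction, "high")
  }
  if (length(candidates) == 1) {
    list(q1 = qs[1], q3 = qs[2], iqr = iqr, low_fence = lo, high_fence = hi,
         outlier_group = candidates, direction = direction)
  } else {
    list(q1 = qs[1], q3 = qs[2], iqr = iqr, low_fence = lo, high_fence = hi,
         outlier_group = NA_character_, direction = "none")
  }
}

#' Call group-specific edges on a heterogeneity-tested universe
#'
#' Applies [iqr_specificity] to every edge flagged heterogeneous
#' (`fdr < fdr_level`), across the effect-size columns of the universe.
#'
#' @param universe Output of [heterogeneity_test].
#' @param factor Fence multiplier.
#' @param fdr_level Heterogeneity gate.
#' @return The input with `specific_group` and `specific_direction`
#'   columns added (`NA`/`"none"` for unflagged or unassigned edges).
#' @export
specific_edges <- function(universe, factor = 0.75, fdr_level = 0.05) {
  rcols <- grep("^r_", names(universe), value = TRUE)
  groups <- sub("^r_", "", rcols)
  universe$specific_group <- NA_character_
  universe$specific_direction <- "none"
  idx <- which(!is.na(universe$fdr) & universe$fdr < fdr_level)
  for (i in idx) {
    es <- stats::setNames(as.numeric(universe[i, rcols]), groups)
    call <- suppressMessages(iqr_specificity(es, factor = factor))
    universe$specific_group[i] <- call$outlier_group
    universe$specific_direction[i] <- call$direction
  }
  universe
}

#' Kleinberg hub scores of a specific-edge subnetwork
#'
#' Builds an undirected graph weighted by `|r|` from one group's specific
#' edges and computes Kleinberg hub scores per connected component (for an
#' undirected graph, the principal eigenvector of the weighted adjacency
#' matrix), normalized so each component's maximum is 1. Nodes with score
#' above 0.5 are flagged as hubs.
#'
#' @param edges Data.frame with `feature_a`, `feature_b`, `r`.
#' @param hub_threshold Score above which a node is a hub.
#' @return Data.frame `node`, `score`, `is_hub`; empty for an empty graph.
#' @export
hub_scores <- function(edges, hub_threshold = 0.5) {
  if (!nrow(edges))
    return(data.frame(node = character(0), score = numeric(0),
                      is_hub = logical(0)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$feature_a, to = edges$feature_b,
               weight = abs(edges$r)),
    directed = FALSE)
  comp <- igraph::components(g)
  score <- rep(NA_real_, igraph::vcount(g))
  names(score) <- igraph::V(g)$name
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::vcount(sub) == 1) {
      s <- stats::setNames(1, igraph::V(sub)$name)
    } else {
      # Kleinberg hubs on an undirected graph reduce to eigenvector
      # centrality of the weighted adjacency matrix
      s <- igraph::eigen_centrality(sub,
                                    weights = igraph::E(sub)$weight)$vector
    }
    score[names(s)] <- s
  }
  out <- data.frame(node = names(score), score = unname(score),
                    is_hub = unname(score) > hub_threshold,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$node), , drop = FALSE]
}

#' Summarize flagged edges at the genus level
#'
#' Aggregates edge counts by unordered genus pair, deriving genera from
#' MetaPhlAn-style species ids (`s__Genus_species`); unparsable names count
#' under `"unknown"`.
#'
#' @param edges Data.frame with `feature_a`, `feature_b`.
#' @return Data.frame `genus_a`, `genus_b`, `n_edges` with
#'   `genus_a <= genus_b` and `sum(n_edges) == nrow(edges)`.
#' @export
genus_summary <- function(edges) {
  if (!nrow(edges))
    return(data.frame(genus_a = character(0), genus_b = character(0),
                      n_edges = integer(0)))
  ga <- suppressMessages(genus_of(edges$feature_a))
  gb <- suppressMessages(genus_of(edges$feature_b))
  lo <- pmin(ga, gb)
  hi <- pmax(ga, gb)
  tab <- table(paste(lo, hi, sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(genus_a = vapply(parts, `[[`, "", 1),
                    genus_b = vapply(parts, `[[`, "", 2),
                    n_edges = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$n_edges, out$genus_a, out$genus_b), , drop = FALSE]
}
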