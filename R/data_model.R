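#' Filter features by prevalence
#'
#' Retains features detected (value > 0) in strictly more than
#' `min_fraction` of the samples, preserving row order. The strict
#' inequality means a feature present in exactly 10% of samples is dropped
#' at `min_fraction = 0.1`.
#'
#' @param x A [feature_table].
#' @param min_fraction Prevalence threshold in `[0, 1)`.
#' @return A filtered [feature_table]; may be empty (with a warning).
#' @export
prevalence_filter <- function(x, min_fraction = 0.1) {
  stopifnot(inherits(x, "feature_table"),
            min_fraction >= 0, min_fraction < 1)
  prev <- rowMeans(x$values > 0)
  keep <- prev > min_fraction
  if (!any(keep)) warning("prevalence filter removed every feature")
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out
}

#' Convert relative abundances to predicted read counts
#'
#' Multiplies each sample's relative abundances by its total sequence count
#' and rounds (half to even, the R default) to integer counts.
#'
#' @param x A relative-scale [feature_table].
#' @param meta Sample metadata with `sample_id` and `total_reads`.
#' @return A count-scale [feature_table].
#' @export
to_counts <- function(x, meta) {
  stopifnot(inherits(x, "feature_table"))
  if (x$scale != "relative")
    stop("to_counts() expects a relative-scale table")
  idx <- match(sample_ids(x), meta$sample_id)
  if (anyNA(idx))
    stop("missing total_reads for sample(s): ",
         paste(sample_ids(x)[is.na(idx)], collapse = ", "))
  depth <- meta$total_reads[idx]
  counts <- round(sweep(x$values, 2, depth, `*`))
  feature_table(counts, kind = x$kind, scale = "count")
}

#' Align a feature table with sample metadata
#'
#' Restricts the table to the samples present in both the table and the
#' metadata, warning about any dropped columns.
#'
#' @param x A [feature_table].
#' @param meta Sample metadata.
#' @return The aligned [feature_table].
#' @export
align_samples <- function(x, meta) {
  shared <- intersect(sample_ids(x), meta$sample_id)
  dropped <- setdiff(sample_ids(x), shared)
  if (length(dropped))
    warning("dropping sample(s) without metadata: ",
            paste(dropped, collapse = ", "))
  out <- x
  out$values <- x$values[, shared, drop = FALSE]
  out
}

#' Split a feature table into (group, day) subgroups
#'
#' Each observed combination of group and day becomes one subgroup, carrying
#' its own sub-table. Subgroups may have unequal sizes when samples are
#' missing; per-subgroup statistics downstream use each subgroup's own n.
#'
#' @param x A [feature_table].
#' @param meta Sample metadata covering every sample of `x`.
#' @return A named list; each element has `group`, `day`, `sample_ids`, and
#'   `table` (the [feature_table] restricted to the subgroup). Names are
#'   `"<group>.d<day>"`.
#' @export
split_subgroups <- function(x, meta) {
  idx <- match(sample_ids(x), meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) without metadata: ",
         paste(sample_ids(x)[is.na(idx)], collapse = ", "))
  sub <- meta[idx, , drop = FALSE]
  key <- paste0(sub$group, ".d", sub$day)
  ord <- order(match(sub$group, unique(sub$group)), sub$day)
  out <- list()
  for (k in unique(key[ord])) {
    sel <- key == k
    tab <- x
    tab$values <- x$values[, sel, drop = FALSE]
    out[[k]] <- list(group = sub$group[sel][1], day = sub$day[sel][1],
                     sample_ids = sample_ids(x)[sel], table = tab)
  }
  out
}
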