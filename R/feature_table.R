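#' Construct a feature table
#'
#' A feature table holds a numeric features-by-samples matrix together with
#' the kind of feature it describes (species, pathway, metabolite, ...) and
#' the scale its values are on. Relative-scale columns must sum to at most 1
#' (plus a small tolerance); no scale admits negative values.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row
#'   names are feature ids, column names sample ids; both are required and
#'   must be unique.
#' @param kind One of `"species"`, `"pathway"`, `"resistance_gene"`,
#'   `"virulence_gene"`, `"metabolite"`, `"phenotype"`.
#' @param scale One of `"relative"`, `"count"`, `"intensity"`, `"raw"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values,
                          kind = c("species", "pathway", "resistance_gene",
                                   "virulence_gene", "metabolite", "phenotype"),
                          scale = c("relative", "count", "intensity", "raw")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature ids as row names and sample ids as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(values < 0, na.rm = TRUE))
    stop("feature tables must not contain negative values")
  if (scale == "relative") {
    cs <- colSums(values, na.rm = TRUE)
    if (any(cs > 1 + 1e-6))
      stop("relative-scale columns must sum to <= 1; offending sample(s): ",
           paste(colnames(values)[cs > 1 + 1e-6], collapse = ", "))
  }
  structure(list(values = values, kind = kind, scale = scale),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d %s feature(s) x %d sample(s) [%s scale]\n",
              nrow(x$values), x$kind, ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature and sample ids of a feature table
#' @param x A `feature_table`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a feature-by-sample TSV table
#'
#' Reads tab-separated profiler output: first column feature id, remaining
#' columns one per sample. Leading lines starting with `#` are treated as
#' comments, except that a `#`-prefixed header row immediately above the data
#' (the MetaPhlAn merged-table dialect) is recognised and used for sample
#' names. For `kind = "species"`, full taxonomic lineage strings
#' (`k__...|p__...|...|s__Genus_species`) are reduced to their terminal
#' clade.
#'
#' @param path Path to a TSV file.
#' @inheritParams feature_table
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, kind = "species", scale = "relative") {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  is_comment <- startsWith(lines, "#")
  header_idx <- which(!is_comment)[1]
  if (is.na(header_idx)) stop("no data lines in ", path)
  # MetaPhlAn merged tables carry the header as the last '#' line
  header_line <- if (header_idx > 1) sub("^#\\s*", "", lines[header_idx - 1]) else NA
  first_fields <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  has_plain_header <- any(is.na(suppressWarnings(as.numeric(first_fields[-1]))))
  if (has_plain_header) {
    header <- first_fields
    data_lines <- lines[seq_along(lines) > header_idx & !is_comment]
  } else if (!is.na(header_line)) {
    header <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
    data_lines <- lines[seq_along(lines) >= header_idx & !is_comment]
  } else {
    stop("cannot locate a header row in ", path)
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol_expect <- length(header)
  bad <- which(lengths(fields) != ncol_expect)
  if (length(bad))
    stop("row ", bad[1], " has ", lengths(fields)[bad[1]],
         " fields, expected ", ncol_expect)
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (kind == "species") ids <- terminal_clade(ids)
  if (anyDuplicated(ids))
    stop("duplicate feature id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- matrix(NA_real_, length(fields), ncol_expect - 1L)
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric value in row '%s', column '%s'",
                   ids[i], header[j + 1L]))
    }
    num[i, ] <- v
  }
  rownames(num) <- ids
  colnames(num) <- header[-1]
  feature_table(num, kind = kind, scale = scale)
}

#' Write a feature table as TSV
#'
#' @param x A [feature_table].
#' @param path Output path.
#' @param id_column Name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_column = "feature_id") {
  df <- data.frame(x$values, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(x$values)), id_column), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduce taxonomy lineage strings to their terminal clade
#'
#' `"k__Bacteria|...|s__Bacteroides_fragilis"` becomes
#' `"s__Bacteroides_fragilis"`; strings without `|` are returned unchanged.
#'
#' @param ids Character vector of feature ids.
#' @return Character vector of terminal clades.
#' @export
terminal_clade <- function(ids) {
  vapply(strsplit(ids, "|", fixed = TRUE),
         function(parts) parts[[length(parts)]], character(1))
}

#' Extract the genus from species-level feature ids
#'
#' Expects MetaPhlAn-style terminal clades (`s__Genus_species`); anything
#' unparsable maps to `"unknown"` with a message.
#'
#' @param ids Character vector of species ids.
#' @return Character vector of genus names.
#' @export
genus_of <- function(ids) {
  out <- rep("unknown", length(ids))
  stripped <- sub("^s__", "", ids)
  ok <- grepl("^[A-Za-z]", stripped) & stripped != ids | grepl("^s__", ids)
  parts <- strsplit(stripped, "_", fixed = TRUE)
  for (i in seq_along(ids)) {
    if (grepl("^s__[A-Za-z]", ids[i]) && length(parts[[i]]) >= 1L) {
      out[i] <- parts[[i]][1]
    }
  }
  if (any(out == "unknown"))
    message(sum(out == "unknown"), " feature id(s) not parsable to genus; mapped to 'unknown'")
  out
}

#' Read a sample-metadata TSV
#'
#' Expects columns `sample_id`, `calf_id`, `group`, `day`, `total_reads`.
#' Groups must be among the study arms (`CON`, `RMT`, `RFT`); `(calf_id,
#' day)` pairs must be unique; `total_reads` must be positive.
#'
#' @param path Path to a TSV file.
#' @param groups Allowed group labels.
#' @return A data.frame of sample metadata.
#' @export
read_sample_meta <- function(path, groups = c("CON", "RMT", "RFT")) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  validate_sample_meta(meta, groups = groups)
}

#' Validate sample metadata
#'
#' @param meta A data.frame with columns `sample_id`, `calf_id`, `group`,
#'   `day`, `total_reads`.
#' @param groups Allowed group labels.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validate_sample_meta <- function(meta, groups = c("CON", "RMT", "RFT")) {
  needed <- c("sample_id", "calf_id", "group", "day", "total_reads")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(meta$group %in% groups))
    stop("unknown group label(s): ",
         paste(unique(setdiff(meta$group, groups)), collapse = ", "))
  if (anyDuplicated(meta[, c("calf_id", "day")]))
    stop("(calf_id, day) pairs must be unique")
  if (anyDuplicated(meta$sample_id)) stop("sample_id must be unique")
  if (any(meta$total_reads <= 0)) stop("total_reads must be positive")
  meta
}
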