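test_that("feature tables round-trip through TSV unchanged", {
  ft <- make_ft(matrix(c(0.5, 0.3, 0.2, 0.25, 0.5, 0.25), 3, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path, kind = "species", scale = "relative")
  expect_equal(back$values, ft$values)
  expect_equal(dim(back), c(3L, 2L))
})

test_that("MetaPhlAn-style lineages reduce to the terminal clade", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# mpa_v20 merged table",
    "#clade_name\tS1\tS2",
    "k__Bacteria|p__Bacteroidetes|g__Bacteroides|s__Bacteroides_fragilis\t0.4\t0.1",
    "k__Bacteria|p__Bacteroidetes|g__Alistipes|s__Alistipes_putredinis\t0.2\t0.3"),
    path)
  ft <- read_feature_table(path, kind = "species")
  expect_equal(feature_ids(ft),
               c("s__Bacteroides_fragilis", "s__Alistipes_putredinis"))
  expect_equal(sample_ids(ft), c("S1", "S2"))
  expect_equal(unname(ft$values[1, ]), c(0.4, 0.1))
})

test_that("malformed tables are rejected with informative errors", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1", "A\t0.5", "A\t0.2"), dup)
  expect_error(read_feature_table(dup, kind = "pathway"), "duplicate")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "A\t0.5\toops"), bad)
  expect_error(read_feature_table(bad, kind = "pathway"), "non-numeric.*S2")

  expect_error(feature_table(matrix(-1, 1, 1,
                                    dimnames = list("A", "S1")),
                             "species", "relative"),
               "negative")
})

test_that("prevalence filtering is strict and idempotent", {
  v <- rbind(c(rep(0.05, 2), rep(0, 10)),   # 2/12 = 16.7% -> kept
             c(0.05, rep(0, 11)),           # 1/12 = 8.3% -> removed
             rep(0, 12),                    # never kept
             rep(0.05, 12))
  ft <- make_ft(v)
  out <- prevalence_filter(ft, 0.10)
  expect_equal(feature_ids(out), c("F01", "F04"))
  expect_equal(feature_ids(prevalence_filter(out, 0.10)), feature_ids(out))
  # a feature present in exactly 10% of samples is excluded
  v10 <- rbind(c(0.1, rep(0, 9)), rep(0.1, 10))
  expect_equal(feature_ids(prevalence_filter(make_ft(v10), 0.10)), "F02")
  expect_warning(prevalence_filter(make_ft(matrix(0, 2, 3)), 0.10),
                 "every feature")
})

test_that("count reconstruction multiplies by depth and rounds", {
  ft <- make_ft(rbind(c(0.5, 0.123), c(0.5, 0.877), c(0, 0)))
  meta <- data.frame(sample_id = c("S01", "S02"),
                     total_reads = c(100, 1000))
  counts <- to_counts(ft, meta)
  expect_equal(unname(counts$values[, "S01"]), c(50, 50, 0))
  expect_equal(unname(counts$values[, "S02"]), c(123, 877, 0))
  expect_equal(counts$scale, "count")
  expect_error(to_counts(ft, meta[1, , drop = FALSE]), "S02")
})

test_that("renormalized counts recover relative abundances within 1/depth", {
  set.seed(1)
  v <- matrix(stats::runif(40), 8, 5)
  v <- sweep(v, 2, colSums(v), `/`)
  ft <- make_ft(v)
  meta <- data.frame(sample_id = sample_ids(ft),
                     total_reads = c(1e4, 5e4, 1e5, 2e5, 1e6))
  counts <- to_counts(ft, meta)
  rel_back <- sweep(counts$values, 2, meta$total_reads, `/`)
  for (j in seq_len(5))
    expect_true(all(abs(rel_back[, j] - v[, j]) <= 1 / meta$total_reads[j]))
})

test_that("subgroup splitting covers the full design and demands metadata", {
  meta <- make_meta(n_calves = 2)
  v <- matrix(stats::runif(4 * nrow(meta)), 4, nrow(meta))
  v <- sweep(v, 2, colSums(v), `/`)
  ft <- make_ft(v, samples = meta$sample_id)
  subs <- split_subgroups(ft, meta)
  expect_length(subs, 9)
  expect_setequal(unlist(lapply(subs, `[[`, "sample_ids")), meta$sample_id)
  expect_true(all(vapply(subs, function(s)
    all(meta$group[match(s$sample_ids, meta$sample_id)] == s$group),
    logical(1))))

  one_group <- meta[meta$group == "RMT", ]
  ft1 <- make_ft(v[, match(one_group$sample_id, meta$sample_id)],
                 samples = one_group$sample_id)
  expect_length(split_subgroups(ft1, one_group), 3)

  expect_error(split_subgroups(ft, meta[-1, ]), "without metadata")
})

test_that("sample metadata validation enforces the design invariants", {
  meta <- make_meta(n_calves = 1)
  expect_silent(validate_sample_meta(meta))
  bad_group <- meta
  bad_group$group[1] <- "XXX"
  expect_error(validate_sample_meta(bad_group), "XXX")
  dup <- rbind(meta, meta[1, ])
  dup$sample_id[nrow(dup)] <- "other"
  expect_error(validate_sample_meta(dup), "unique")
  neg <- meta
  neg$total_reads[1] <- 0
  expect_error(validate_sample_meta(neg), "positive")
})
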