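test_that("Kruskal-Wallis reproduces the untied two-stratum worked case", {
  res <- kruskal_strata(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(unname(res["H"]), 27 / 7, tolerance = 1e-10)  # 3.857
  expect_equal(unname(res["p"]),
               stats::pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  flat <- kruskal_strata(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(unname(flat), c(0, 1))

  set.seed(30)
  x <- stats::rnorm(30)
  g <- rep(letters[1:3], 10)
  expect_equal(kruskal_strata(x, g), kruskal_strata(exp(x), g))
})

test_that("Dunn post hoc contrasts rank strata correctly", {
  x <- c(1, 3, 5, 2, 4, 6)
  g <- rep(c("a", "b"), 3)
  d_same <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(d_same$z, 0)
  expect_equal(d_same$p, 1)

  set.seed(31)
  vals <- c(stats::rnorm(8), stats::rnorm(8), stats::rnorm(8) + 10)
  g3 <- rep(c("a", "b", "c"), each = 8)
  d <- dunn_posthoc(vals, g3)
  p_ac <- d$p[d$group_a == "a" & d$group_b == "c"]
  p_bc <- d$p[d$group_a == "b" & d$group_b == "c"]
  p_ab <- d$p[d$group_a == "a" & d$group_b == "b"]
  expect_lt(p_ac, p_ab)
  expect_lt(p_bc, p_ab)

  # z matches the mean-rank formula computed directly
  r <- rank(vals)
  se <- sqrt((24 * 25 / 12) * (1 / 8 + 1 / 8))
  z_ab <- (mean(r[g3 == "a"]) - mean(r[g3 == "b"])) / se
  expect_equal(d$z[d$group_a == "a" & d$group_b == "b"], z_ab,
               tolerance = 1e-12)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))

  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(32)
  for (len in c(1, 5, 20)) {
    p <- stats::runif(len)
    expect_equal(bh_fdr(p), step_up(p))
    expect_true(all(bh_fdr(p) >= p))
  }
  p <- stats::runif(10)
  perm <- sample(10)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("Fisher exact test covers homogeneous, extreme and degenerate tables", {
  hom <- fisher_exact_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(hom$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(hom$p, 1)

  ext <- fisher_exact_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(ext$p, 2 / choose(20, 10), tolerance = 1e-12)

  tab <- matrix(c(7, 2, 3, 8), 2)
  expect_equal(fisher_exact_test(tab)$p, fisher_exact_test(t(tab))$p)

  zero <- fisher_exact_test(matrix(c(0, 0, 5, 7), 2))
  expect_equal(zero$p, 1)
  expect_true(is.finite(zero$odds_ratio))

  three <- fisher_exact_test(matrix(c(8, 1, 2, 5, 4, 4), 2))
  expect_true(three$p > 0 && three$p <= 1)
})

test_that("Wilcoxon rank-sum handles exact, tied and degenerate cases", {
  sep <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(sep["p"]), 0.1)  # two-sided, 2/20
  tied <- wilcoxon_ranksum(rep(2, 4), rep(2, 4))
  expect_equal(unname(tied["p"]), 1)
  set.seed(33)
  a <- stats::rnorm(10); b <- stats::rnorm(12)
  expect_equal(wilcoxon_ranksum(a, b)["W"],
               wilcoxon_ranksum(exp(a), exp(b))["W"])
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "nonempty")
})

test_that("feature-level testing is invariant to the inverse-rank step", {
  meta <- make_meta(groups = "RMT", n_calves = 6)
  set.seed(34)
  v <- matrix(stats::rexp(8 * nrow(meta)), 8, nrow(meta))
  v <- sweep(v, 2, colSums(v), `/`)
  ft <- make_ft(v, samples = meta$sample_id)

  with_irn <- differential_features(ft, meta, axis = "time_within_group",
                                    subset = "RMT", transform = "clr_irn")
  clr_only <- t(apply(clr_transform(ft$values), 1, function(row)
    kruskal_strata(row, meta$day)))
  expect_equal(with_irn$p, unname(clr_only[, "p"]), tolerance = 1e-12)
  expect_true(all(with_irn$fdr >= with_irn$p))
  # three day strata produce Dunn contrast columns
  expect_true(any(grepl("^z_", names(with_irn))))
})
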