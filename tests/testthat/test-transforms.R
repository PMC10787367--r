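test_that("CLR matches the closed form and centers each sample", {
  ft <- make_ft(matrix(c(0.5, 0.25, 0.25), 3, 1), scale = "relative")
  out <- clr_transform(ft, pseudocount = 1e-12)
  expect_equal(unname(out[, 1]),
               log(c(0.5, 0.25, 0.25)) - mean(log(c(0.5, 0.25, 0.25))),
               tolerance = 1e-9)
  expect_equal(unname(round(out[, 1], 3)), c(0.462, -0.231, -0.231))

  uni <- clr_transform(make_ft(matrix(1 / 3, 3, 1)), pseudocount = 1e-12)
  expect_equal(unname(uni[, 1]), rep(0, 3), tolerance = 1e-9)

  set.seed(4)
  v <- matrix(stats::runif(30) + 0.01, 6, 5)
  v <- sweep(v, 2, colSums(v), `/`)
  out <- clr_transform(make_ft(v), pseudocount = 1e-15)
  expect_equal(unname(colSums(out)), rep(0, 5), tolerance = 1e-8)
})

test_that("CLR is invariant to per-sample rescaling", {
  set.seed(5)
  v <- matrix(stats::runif(24) + 0.05, 6, 4)
  a <- clr_transform(v, pseudocount = 1e-300)
  b <- clr_transform(sweep(v, 2, c(10, 0.5, 2, 7), `*`), pseudocount = 1e-300)
  expect_equal(a, b, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("inverse-rank transform maps to normal quantiles of rankits", {
  two <- inverse_rank(matrix(c(3, 8), 1, 2, dimnames = list("f", c("a", "b"))))
  expect_equal(unname(two[1, ]), stats::qnorm(c(0.25, 0.75)),
               tolerance = 1e-12)
  expect_equal(unname(round(two[1, ], 3)), c(-0.674, 0.674))

  const <- inverse_rank(matrix(5, 1, 7))
  expect_equal(unname(const[1, ]), rep(0, 7))

  set.seed(6)
  x <- matrix(stats::rnorm(20), 1, 20)
  out <- inverse_rank(x)
  expect_equal(order(out[1, ]), order(x[1, ]))

  big <- inverse_rank(matrix(stats::rexp(60), 1, 60))
  expect_lt(abs(sample_skewness(big[1, ])), 0.2)
})

test_that("Shannon index handles uniform, degenerate and worked cases", {
  expect_equal(unname(shannon_index(make_ft(matrix(0.25, 4, 1)))), log(4),
               tolerance = 1e-12)
  one <- matrix(c(1, 0, 0), 3, 1)
  expect_equal(unname(shannon_index(make_ft(one))), 0)
  p <- matrix(c(0.5, 0.3, 0.2), 3, 1)
  expect_equal(unname(shannon_index(make_ft(p))),
               -sum(c(0.5, 0.3, 0.2) * log(c(0.5, 0.3, 0.2))),
               tolerance = 1e-12)
  expect_equal(unname(round(shannon_index(make_ft(p)), 4)), 1.0297)
  withzero <- make_ft(cbind(c(0.5, 0.5), c(0, 0)), scale = "relative")
  expect_warning(h <- shannon_index(withzero), "all-zero")
  expect_true(is.na(h[2]) && !is.na(h[1]))
})

test_that("Bray-Curtis dissimilarity matches its formula and bounds", {
  same <- make_ft(cbind(c(0.6, 0.4), c(0.6, 0.4)))
  expect_equal(unname(bray_curtis(same)[1, 2]), 0)
  disjoint <- make_ft(cbind(c(0.7, 0), c(0, 0.7)), scale = "relative")
  expect_equal(unname(bray_curtis(disjoint)[1, 2]), 1)
  ab <- make_ft(cbind(c(0.6, 0.4), c(0.4, 0.6)))
  expect_equal(unname(bray_curtis(ab)[1, 2]), 0.2, tolerance = 1e-12)

  set.seed(7)
  v <- matrix(stats::rexp(50), 10, 5)
  d <- bray_curtis(make_ft(v, scale = "raw"))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
})

test_that("within-subgroup dissimilarities enumerate unordered pairs", {
  meta <- make_meta(groups = "CON", days = 15, n_calves = 12)
  set.seed(8)
  v <- matrix(stats::runif(5 * 12), 5, 12)
  ft <- make_ft(sweep(v, 2, colSums(v), `/`), samples = meta$sample_id)
  wg <- within_group_dissimilarity(bray_curtis(ft), meta)
  expect_length(wg[["CON.d15"]], choose(12, 2))

  one <- meta[1, , drop = FALSE]
  ft1 <- make_ft(v[, 1, drop = FALSE] / sum(v[, 1]),
                 samples = one$sample_id)
  expect_length(within_group_dissimilarity(bray_curtis(ft1), one)[["CON.d15"]],
                0)

  ident <- make_ft(matrix(rep(c(0.5, 0.5), 12), 2, 12),
                   samples = meta$sample_id)
  expect_true(all(within_group_dissimilarity(bray_curtis(ident),
                                             meta)[["CON.d15"]] == 0))
})
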