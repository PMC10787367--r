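test_that("Cochran Q matches the two-study closed form and metafor", {
  es <- tanh(c(0, 1))  # Fisher-z effects 0 and 1
  res <- cochran_q(es, c(30, 30))
  expect_equal(unname(res["Q"]), 13.5, tolerance = 1e-10)
  expect_equal(unname(res["p"]),
               stats::pchisq(13.5, 1, lower.tail = FALSE), tolerance = 1e-12)

  skip_if_not_installed("metafor")
  fit <- metafor::rma(yi = atanh(es), vi = 1 / (c(30, 30) - 3), method = "FE")
  expect_equal(unname(res["Q"]), fit$QE, tolerance = 1e-8)
  expect_equal(unname(res["p"]), fit$QEp, tolerance = 1e-8)
})

test_that("Cochran Q degenerate and symmetry cases behave", {
  same <- cochran_q(c(0.4, 0.4, 0.4), c(20, 25, 30))
  expect_equal(unname(same["Q"]), 0, tolerance = 1e-12)
  expect_equal(unname(same["p"]), 1)

  es <- c(0.1, 0.5, -0.2)
  ns <- c(10, 20, 30)
  perm <- c(3, 1, 2)
  expect_equal(cochran_q(es, ns)["Q"], cochran_q(es[perm], ns[perm])["Q"])

  expect_warning(small <- cochran_q(c(0.1, 0.2, 0.3), c(3, 30, 30)),
                 "n <= 3")
  expect_equal(unname(small["k"]), 2)
  expect_warning(res <- cochran_q(c(0.1, 0.2), c(3, 30)), "n <= 3")
  expect_true(is.na(res["Q"]))
})

test_that("edge universe takes the union and fills every subgroup's r", {
  ids <- sprintf("F%02d", 1:4)
  mk_r <- function(x12, x34) {
    R <- diag(4); R[1, 2] <- R[2, 1] <- x12; R[3, 4] <- R[4, 3] <- x34
    dimnames(R) <- list(ids, ids); R
  }
  rA <- mk_r(0.8, 0.1); rB <- mk_r(0.75, 0.2); rC <- mk_r(0.7, 0.6)
  eA <- data.frame(feature_a = "F01", feature_b = "F02", r = 0.8, p = 0.001)
  eB <- eA; eB$r <- 0.75
  eC <- rbind(eA, data.frame(feature_a = "F03", feature_b = "F04",
                             r = 0.6, p = 0.005))
  uni <- edge_universe(list(A = eA, B = eB, C = eC),
                       list(A = rA, B = rB, C = rC),
                       c(A = 12, B = 12, C = 12))
  expect_equal(nrow(uni), 2)  # union of {F1-F2} and {F1-F2, F3-F4}
  expect_equal(uni$r_B[uni$feature_a == "F03"], 0.2)  # filled though not significant in B
  expect_equal(uni$r_A[uni$feature_a == "F01"], 0.8)

  # identical edge sets collapse to that edge set
  uni2 <- edge_universe(list(A = eA, B = eB), list(A = rA, B = rB),
                        c(A = 12, B = 12))
  expect_equal(nrow(uni2), 1)
})

test_that("BH adjustment over the universe keeps fdr >= p", {
  ids <- sprintf("F%02d", 1:6)
  uni <- data.frame(feature_a = ids[1:3], feature_b = ids[4:6],
                    r_A = c(0.9, 0.1, 0.5), r_B = c(0.1, 0.1, 0.5),
                    r_C = c(0.2, 0.15, 0.5))
  attr(uni, "ns") <- c(A = 30, B = 30, C = 30)
  out <- heterogeneity_test(uni)
  expect_true(all(out$fdr >= out$p - 1e-15))
  expect_equal(out$fdr, stats::p.adjust(out$p, "BH"))
  expect_true(out$heterogeneous[1])  # 0.9 vs 0.1 vs 0.2 at n = 30
})

test_that("the IQR fence rule reproduces the hand-worked example", {
  call <- iqr_specificity(c(CON = 0.10, RFT = 0.12, RMT = 0.80))
  expect_equal(call$q1, 0.11)
  expect_equal(call$q3, 0.46)
  expect_equal(call$iqr, 0.35)
  expect_equal(call$high_fence, 0.7225)
  expect_equal(call$low_fence, -0.1525)
  expect_equal(call$outlier_group, "RMT")
  expect_equal(call$direction, "high")
})

test_that("IQR specificity refuses degenerate and ambiguous patterns", {
  flat <- iqr_specificity(c(A = 0.3, B = 0.3, C = 0.3))
  expect_true(is.na(flat$outlier_group))

  both <- iqr_specificity(c(A = -0.9, B = 0, C = 0.9))
  expect_true(is.na(both$outlier_group))  # min and max both outside

  tied <- iqr_specificity(c(A = 0.1, B = 0.1, C = 0.1, D = 0.9))
  expect_equal(tied$outlier_group, "D")
  tied2 <- iqr_specificity(c(A = 0.1, B = 0.1, C = 0.9, D = 0.9))
  expect_true(is.na(tied2$outlier_group))  # tie for the maximum

  expect_message(na_call <- iqr_specificity(c(A = 0.1, B = NA, C = 0.9)),
                 "missing")
  expect_true(is.na(na_call$outlier_group))
})

test_that("hub scores concentrate on star centers and normalize per component", {
  star <- data.frame(feature_a = "hub",
                     feature_b = paste0("leaf", 1:5), r = 1)
  hs <- hub_scores(star)
  expect_equal(hs$score[hs$node == "hub"], 1)
  expect_true(all(hs$score[hs$node != "hub"] < 1))
  expect_true(hs$is_hub[hs$node == "hub"])

  single <- hub_scores(data.frame(feature_a = "a", feature_b = "b", r = 0.5))
  expect_equal(single$score, c(1, 1))

  # two components: each has its own maximum at 1
  two <- rbind(star, data.frame(feature_a = "x", feature_b = "y", r = 0.3))
  hs2 <- hub_scores(two)
  expect_equal(unname(hs2$score[hs2$node %in% c("x", "y")]), c(1, 1))

  empty <- hub_scores(data.frame(feature_a = character(0),
                                 feature_b = character(0), r = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("hub scores are invariant to edge order and weight scaling", {
  set.seed(20)
  edges <- data.frame(feature_a = c("a", "a", "b", "c", "d"),
                      feature_b = c("b", "c", "c", "d", "e"),
                      r = stats::runif(5, 0.2, 0.9))
  h1 <- hub_scores(edges)
  h2 <- hub_scores(edges[sample(nrow(edges)), ])
  expect_equal(h1, h2, ignore_attr = TRUE)
  scaled <- edges; scaled$r <- scaled$r * 3.7
  h3 <- hub_scores(scaled)
  expect_equal(h1$score, h3$score, tolerance = 1e-9)

  # oracle: principal eigenvector of the |r|-weighted adjacency matrix
  nodes <- sort(unique(c(edges$feature_a, edges$feature_b)))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    A[edges$feature_a[k], edges$feature_b[k]] <- abs(edges$r[k])
    A[edges$feature_b[k], edges$feature_a[k]] <- abs(edges$r[k])
  }
  ev <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
  ev <- ev / max(ev)
  expect_equal(h1$score[match(nodes, h1$node)], unname(ev), tolerance = 1e-6)
})

test_that("genus summaries aggregate unordered pairs and conserve counts", {
  edges <- data.frame(
    feature_a = c("s__Bacteroides_fragilis", "s__Bacteroides_uniformis",
                  "s__Bacteroides_fragilis", "s__Alistipes_putredinis"),
    feature_b = c("s__Bacteroides_uniformis", "s__Bacteroides_vulgatus",
                  "s__Bacteroides_vulgatus", "s__Bacteroides_fragilis"))
  gs <- genus_summary(edges)
  expect_equal(sum(gs$n_edges), nrow(edges))
  expect_equal(gs$n_edges[gs$genus_a == "Bacteroides" &
                            gs$genus_b == "Bacteroides"], 3)
  expect_equal(gs$n_edges[gs$genus_a == "Alistipes"], 1)
  expect_true(all(gs$genus_a <= gs$genus_b))

  odd <- genus_summary(data.frame(feature_a = "whatisthis",
                                  feature_b = "s__Alistipes_putredinis"))
  expect_equal(odd$genus_a, "Alistipes")
  expect_equal(odd$genus_b, "unknown")
})
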