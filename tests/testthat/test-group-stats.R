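test_that("rank thresholding keeps the top fraction and unions the groups", {
  # all subjects share one identical 90-node map: mask = its top 20% edges
  set.seed(10)
  E <- n_edges(90)
  v <- sample(seq_len(E))           # distinct values, a permutation
  ch <- toy_cohort(matrix(rep(v, 3), 3, byrow = TRUE),
                   matrix(rep(v, 3), 3, byrow = TRUE), 90)
  rt <- rank_threshold(ch, 0.20)
  expect_equal(sum(rt$mask), 801)
  expect_setequal(which(rt$mask), order(v, decreasing = TRUE)[1:801])
})

test_that("rank thresholding on toy maps, disjoint tops and monotone invariance", {
  # 6-edge maps (4 nodes), fraction 0.2: one edge per group survives
  case <- rbind(c(6, 5, 4, 3, 2, 1), c(6, 5, 4, 3, 2, 1))
  ctrl <- rbind(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  ch <- toy_cohort(case, ctrl, 4)
  rt <- rank_threshold(ch, 0.2)
  # normalized ranks above 0.8 are edges 1-2 for cases, 5-6 for controls;
  # the groups have disjoint tops, so the union exceeds 0.2 * E
  expect_equal(which(rt$mask), c(1L, 2L, 5L, 6L))
  expect_gt(sum(rt$mask), 0.2 * 6)
  # brute-force mean-rank oracle
  mr_case <- colMeans(t(apply(case, 1, rank)) / 6)
  expect_equal(unname(rt$group_mean_rank["case", ]), mr_case)
  # invariance under strictly monotone per-subject transforms
  ch2 <- toy_cohort(exp(case / 3), exp(ctrl / 3), 4)
  expect_identical(rank_threshold(ch2, 0.2)$mask, rt$mask)
  expect_error(rank_threshold(ch, 1.2), "fraction")
})

test_that("Welch t matches the textbook formula and t.test", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  ch <- toy_cohort(cbind(x, x, x), cbind(y, y, y), 3)
  w <- welch_edges(ch)
  tt <- t.test(x, y)
  expect_equal(w$t[1], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$df[1], unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w$p[1], tt$p.value, tolerance = 1e-10)
  # direct formula
  tform <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(w$t[1], tform, tolerance = 1e-12)

  # swapping groups negates t and preserves p
  ch_sw <- toy_cohort(cbind(y, y, y), cbind(x, x, x), 3)
  w_sw <- welch_edges(ch_sw)
  expect_equal(w_sw$t, -w$t, tolerance = 1e-12)
  expect_equal(w_sw$p, w$p, tolerance = 1e-12)

  # identical groups: t = 0, p = 1; zero-variance edges flagged
  w_eq <- welch_edges(toy_cohort(cbind(x, x, x), cbind(x, x, x), 3))
  expect_equal(w_eq$t, rep(0, 3))
  expect_equal(w_eq$p, rep(1, 3))
  w_dg <- welch_edges(toy_cohort(cbind(c(1, 1, 1), x, x),
                                 cbind(c(1, 1, 1), y, y), 3))
  expect_true(w_dg$degenerate[1] && is.na(w_dg$t[1]))
})

test_that("omnibus permutation matches exhaustive label enumeration", {
  set.seed(12)
  X <- matrix(rnorm(12), 6, 2)      # 3 vs 3 subjects, 2 edges
  ch <- structure(list(edges = X, group = rep(c("case", "control"), each = 3),
                       covariates = NULL, n_nodes = 3L,
                       subject_id = sprintf("s%d", 1:6)),
                  class = "cohort_data")
  mask <- c(TRUE, TRUE, FALSE)[1:2]
  # oracle: all 20 assignments of 3 "case" labels among 6 subjects
  maxs <- apply(combn(6, 3), 2, function(ix) {
    max(abs(apply(X, 2, function(v) unname(t.test(v[ix], v[-ix])$statistic))))
  })
  om <- omnibus_permutation(ch, mask, n_perm = 3000, alpha = 0.05, seed = 4)
  expect_true(all(vapply(om$max_null, function(m)
    any(abs(m - maxs) < 1e-10), TRUE)))
  expect_gte(length(unique(round(om$max_null, 9))), 9)
  # threshold is one of the attained discrete enumeration levels
  expect_true(any(abs(om$threshold - maxs) < 1e-10))
  om2 <- omnibus_permutation(ch, mask, n_perm = 3000, alpha = 0.05, seed = 4)
  expect_identical(om$max_null, om2$max_null)
})

test_that("omnibus flags only overwhelming effects and nests in uncorrected", {
  for (rep in 1:3) {
    ch <- simulate_edge_cohort(15, 6, affected_edges = 4, effect_d = 5,
                               seed = rep)
    mask <- rep(TRUE, 15)
    om <- omnibus_permutation(ch, mask, n_perm = 500, seed = rep)
    w <- welch_edges(ch, mask)
    expect_true(om$significant[4])
    # omnibus-significant is a subset of uncorrected-significant
    expect_true(all(w$p[om$significant] < 0.05))
  }
  expect_error(omnibus_permutation(simulate_edge_cohort(4, 4, seed = 1),
                                   mask = rep(FALSE, 6)), "empty")
})

test_that("split-half sign consistency separates dominant from null edges", {
  set.seed(14)
  n <- 42; E <- n_edges(10)        # 45 edges, one carrying total dominance
  Xc <- matrix(rnorm(n * E), n, E)
  Xk <- matrix(rnorm(n * E), n, E)
  Xc[, 2] <- runif(n, -2, -1)       # every case value below every control
  Xk[, 2] <- runif(n, 1, 2)
  ch <- toy_cohort(Xc, Xk, 10)
  rb <- split_half_robustness(ch, n_iter = 400, seed = 2)
  expect_equal(rb$consistency[2], 1)
  expect_true(rb$robust[2])
  expect_equal(rb$sign[2], -1L)
  # null edges: the bulk of the consistency mass sits well below the 0.95
  # bar (the rule's intrinsic background rate on null edges is ~10%)
  expect_lt(median(rb$consistency[-2]), 0.95)
  expect_lt(mean(rb$robust[-2]), 0.25)
  expect_identical(rb, split_half_robustness(ch, n_iter = 400, seed = 2))
  expect_error(split_half_robustness(toy_cohort(Xc[1:3, ], Xk, 10)),
               ">= 4")
})

test_that("covariate regression robustness isolates the group effect", {
  set.seed(15)
  n <- 24
  covs <- data.frame(age = rnorm(2 * n, 35, 10),
                     gender = rbinom(2 * n, 1, 0.5),
                     icv = rnorm(2 * n, 1.5e6, 1e5))
  grp <- rep(c(1, 0), each = n)
  # edge 1: strong true group effect; edge 2: pure age effect, no group
  X <- cbind(-1.5 * grp + rnorm(2 * n, sd = 0.5),
             0.05 * covs$age + rnorm(2 * n, sd = 0.2),
             rnorm(2 * n))
  ch <- cohort_data(X, ifelse(grp == 1, "case", "control"),
                    covariates = covs, n_nodes = 3)
  rr <- covariate_regression_robustness(ch, n_iter = 300, seed = 5)
  expect_true(rr$robust[1])
  expect_equal(rr$sign[1], -1L)
  expect_false(rr$robust[2])
  expect_gt(rr$consistency[1], 0.95)
  expect_lt(rr$consistency[2], 0.95)
  # adding a constant to all edges is absorbed by the intercept
  ch2 <- cohort_data(X + 100, ch$group, covariates = covs, n_nodes = 3)
  rr2 <- covariate_regression_robustness(ch2, n_iter = 300, seed = 5)
  expect_equal(rr2$slope_group, rr$slope_group, tolerance = 1e-8)
  # collinear design names the offending column
  covs_bad <- covs; covs_bad$icv <- covs_bad$age
  ch3 <- cohort_data(X, ch$group, covariates = covs_bad, n_nodes = 3)
  expect_error(covariate_regression_robustness(ch3, n_iter = 10),
               "collinear")
})

test_that("t-test power matches the analytic form and is monotone", {
  expect_equal(round(ttest_power(0.8, 42), 2), 0.95)
  expect_equal(round(ttest_power(0.5, 42), 2), 0.62)
  expect_equal(ttest_power(0, 42), 0.05, tolerance = 1e-10)
  # agrees with the classical power routine
  expect_equal(ttest_power(0.65, 30),
               power.t.test(n = 30, delta = 0.65, sd = 1,
                            sig.level = 0.05)$power, tolerance = 1e-4)
  d_grid <- seq(0, 2, by = 0.1)
  expect_true(all(diff(vapply(d_grid, ttest_power, 0, n_per_group = 42)) > 0))
  n_grid <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(vapply(n_grid, function(n)
    ttest_power(0.5, n), 0)) > 0))
  expect_error(ttest_power(0.5, 10, alpha = 1.5), "alpha")
})
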