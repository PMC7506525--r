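alpha <- band_spec("alpha", 8, 13)

test_that("effect-edge sampling is exhaustive, empty and deterministic", {
  expect_equal(make_effect_edges(90, 4005, seed = 7), 1:4005)
  expect_equal(make_effect_edges(3, 0, seed = 7), integer(0))
  e1 <- make_effect_edges(10, 5, seed = 1)
  expect_identical(e1, make_effect_edges(10, 5, seed = 1))
  expect_length(e1, 5)
  expect_true(all(e1 >= 1 & e1 <= 45) && !anyDuplicated(e1))
  expect_error(make_effect_edges(5, 11, seed = 1), "only 10")
})

test_that("PSD repair yields unit-diagonal positive semidefinite targets", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.9
  C[1, 3] <- C[3, 1] <- 0.9
  C[2, 3] <- C[3, 2] <- -0.9        # jointly infeasible
  Cr <- psd_repair(C)
  expect_true(isSymmetric(Cr))
  expect_equal(diag(Cr), rep(1, 4))
  expect_gte(min(eigen(Cr, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("band signals honor the target envelope-correlation ordering", {
  n <- 6
  # identity target: measured envelope correlations concentrate near zero
  X <- generate_band_signal(n, 250, 200, alpha, diag(n), seed = 42)
  expect_equal(colMeans(X), rep(0, n), tolerance = 1e-10)
  env <- despike_downsample(
    hilbert_envelope(node_timecourses(X, 200, band = alpha)), 200)
  # envelope samples are autocorrelated (finite envelope bandwidth), so the
  # per-pair sampling noise at 250 s keeps |r| small but not negligible
  expect_lt(mean(abs(matrix_to_vec(cor(env)))), 0.1)
  expect_lt(max(abs(matrix_to_vec(cor(env)))), 0.25)

  # r = 0.9 on one pair beats every zero-target pair, across seeds
  C <- diag(n); C[1, 2] <- C[2, 1] <- 0.9
  wins <- vapply(1:20, function(seed) {
    S <- generate_band_signal(n, 60, 200, alpha, C, seed = seed)
    e <- despike_downsample(
      hilbert_envelope(node_timecourses(S, 200, band = alpha)), 200)
    r <- cor(e)
    r[1, 2] > max(abs(matrix_to_vec(r))[-1])
  }, TRUE)
  expect_gte(mean(wins), 0.9)

  expect_identical(generate_band_signal(4, 10, 200, alpha, diag(4), seed = 3),
                   generate_band_signal(4, 10, 200, alpha, diag(4), seed = 3))
  expect_error(generate_band_signal(4, 10, 200, alpha, diag(3)), "4 x 4")
  expect_error(generate_band_signal(4, 10, 20, alpha, diag(4)), "carry")
  bad <- diag(4); bad[1, 2] <- 0.5
  expect_error(generate_band_signal(4, 10, 200, alpha, bad), "symmetric")
})

test_that("leakage mixing is symmetric, variance-preserving and monotone", {
  set.seed(9)
  X <- matrix(rnorm(2000 * 5), ncol = 5)
  expect_identical(apply_leakage(X, 0), X)
  expect_error(apply_leakage(X, -0.1), ">= 0")
  incr <- vapply(1:10, function(seed) {
    Xi <- matrix(rnorm(2000 * 5), ncol = 5)
    Y <- apply_leakage(Xi, 0.3, seed = seed)
    m0 <- mean(abs(matrix_to_vec(cor(Xi))))
    m1 <- mean(abs(matrix_to_vec(cor(Y))))
    c(m1 > m0, max(abs(apply(Y, 2, sd) - apply(Xi, 2, sd))))
  }, c(TRUE, 0))
  expect_true(all(incr[1, ] == 1))
  expect_lt(max(incr[2, ]), 1e-10)
})

test_that("cohort generation matches the configured design", {
  cfg <- sim_config(n_per_group = 3, n_nodes = 10, duration = 5,
                    sampling_rate = 120,
                    bands = list(band_spec("alpha", 8, 13)),
                    affected_edge_count = 4, effect_delta = 0.5, seed = 2)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$manifest), 6)
  expect_equal(as.vector(table(ch$manifest$group)), c(3, 3))
  expect_length(ch$effect_edges, 4)
  expect_equal(ncol(ch$subjects[[1]]$alpha$data), 10)
  expect_equal(ch$subjects[[1]]$alpha$fs, 120)
  ch2 <- generate_cohort(cfg)
  expect_identical(ch$subjects[[4]]$alpha$data, ch2$subjects[[4]]$alpha$data)
  expect_identical(ch$manifest, ch2$manifest)

  # default design: 42 per group, covariates from the configured distributions
  cfg_default <- sim_config()
  expect_equal(cfg_default$n_per_group, 42L)
  expect_equal(cfg_default$n_nodes, 90L)
  expect_equal(length(cfg_default$bands), 6L)
  expect_equal(cfg_default$covariate_params$case$age_mean, 38.5)
  expect_equal(cfg_default$covariate_params$control$age_mean, 33.3)
  expect_error(sim_config(n_nodes = 5, affected_edge_count = 11), "exceeds")
})

test_that("synthetic group effect pushes affected edges down, not others", {
  n <- 8; fs <- 150; dur <- 30
  eff <- make_effect_edges(n, 6, seed = 1)
  base <- rep(0.6, n_edges(n))
  case_v <- base; case_v[eff] <- base[eff] * 0.2
  Cc <- vec_to_matrix(case_v, n, diag = 1)
  Ck <- vec_to_matrix(base, n, diag = 1)
  diffs <- matrix(0, 10, n_edges(n))
  for (seed in 1:10) {
    mcase <- cor(despike_downsample(hilbert_envelope(node_timecourses(
      generate_band_signal(n, dur, fs, alpha, Cc, seed = seed),
      fs, band = alpha)), fs))
    mctrl <- cor(despike_downsample(hilbert_envelope(node_timecourses(
      generate_band_signal(n, dur, fs, alpha, Ck, seed = seed + 500),
      fs, band = alpha)), fs))
    diffs[seed, ] <- matrix_to_vec(mcase) - matrix_to_vec(mctrl)
  }
  md <- colMeans(diffs)
  expect_lt(mean(md[eff]), 0)
  expect_lt(mean(md[eff]), mean(md[-eff]))
})

test_that("edge-level cohort simulator controls Cohen's d exactly in expectation", {
  eff <- c(2, 5, 9)
  ch <- simulate_edge_cohort(200, 6, affected_edges = eff, effect_d = 1,
                             seed = 33)
  expect_s3_class(ch, "cohort_data")
  expect_equal(dim(ch$edges), c(400, 15))
  d_hat <- colMeans(ch$edges[ch$group == "case", ]) -
    colMeans(ch$edges[ch$group == "control", ])
  expect_equal(unname(mean(d_hat[eff])), -1, tolerance = 0.25)
  expect_equal(unname(mean(d_hat[-eff])), 0, tolerance = 0.25)
  expect_identical(ch$edges,
                   simulate_edge_cohort(200, 6, eff, 1, seed = 33)$edges)
  # covariates present and plausible
  expect_true(all(c("age", "gender", "icv") %in% names(ch$covariates)))
  expect_true(all(ch$covariates$gender %in% 0:1))
})
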