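# Run expr with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Repair a target correlation matrix to positive semidefiniteness
#'
#' User-specified edge patterns need not be jointly consistent; negative
#' eigenvalues are clipped at zero and the result rescaled to unit diagonal.
#'
#' @param C Symmetric matrix with unit diagonal (approximately).
#' @return Symmetric positive semidefinite matrix with unit diagonal.
#' @export
psd_repair <- function(C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= 0) return(C)
  v <- pmax(e$values, 0)
  C2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(C2), .Machine$double.eps))
  C2 <- C2 / tcrossprod(d)
  diag(C2) <- 1
  (C2 + t(C2)) / 2
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the study conditions the generator is meant to stand in
#' for: two groups of 42 subjects, 90 cortical nodes, six canonical bands,
#' 250 s of usable recording at 600 Hz, and covariate distributions (case age
#' 38.5 +/- 12.5 y, control 33.3 +/- 9.6 y; balanced gender; an intracranial
#' volume deficit in cases).
#'
#' @param n_per_group Subjects per group (default 42).
#' @param n_nodes Number of atlas nodes (default 90).
#' @param bands List of [band_spec] (default [canonical_bands()]).
#' @param sampling_rate Hz (default 600).
#' @param duration Seconds of signal per subject (default 250).
#' @param baseline_corr Latent envelope correlation at unaffected edges,
#'   in \[0, 1) (default 0.3).
#' @param affected_edge_count Number of edges carrying the group effect
#'   (default 30).
#' @param effect_delta Fractional reduction in \[0, 1\] of the target envelope
#'   correlation at affected edges in the case group (default 0.5).
#' @param leakage_lambda Zero-lag linear mixing strength >= 0 (default 0).
#' @param envelope_bandwidth Hz of the slow envelope process (default 0.5).
#' @param covariate_params Per-group means/SDs for age, gender proportion and
#'   ICV (voxels); see defaults in the function signature.
#' @param seed Integer seed; identical seed + config give bit-identical
#'   cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 42L, n_nodes = 90L,
                       bands = canonical_bands(),
                       sampling_rate = 600, duration = 250,
                       baseline_corr = 0.3, affected_edge_count = 30L,
                       effect_delta = 0.5, leakage_lambda = 0,
                       envelope_bandwidth = 0.5,
                       covariate_params = list(
                         case    = list(age_mean = 38.5, age_sd = 12.5,
                                        gender_p = 0.5,
                                        icv_mean = 1.48e6, icv_sd = 1.3e5),
                         control = list(age_mean = 33.3, age_sd = 9.6,
                                        gender_p = 0.5,
                                        icv_mean = 1.54e6, icv_sd = 1.3e5)),
                       seed = 1L) {
  stopifnot(n_per_group >= 1, n_nodes >= 2,
            baseline_corr >= 0, baseline_corr < 1,
            effect_delta >= 0, effect_delta <= 1,
            leakage_lambda >= 0, envelope_bandwidth > 0,
            sampling_rate > 0, duration > 0)
  if (affected_edge_count > n_edges(n_nodes))
    stop("sim_config: affected_edge_count exceeds ", n_edges(n_nodes), " edges")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_nodes = as.integer(n_nodes), bands = bands,
                 sampling_rate = sampling_rate, duration = duration,
                 baseline_corr = baseline_corr,
                 affected_edge_count = as.integer(affected_edge_count),
                 effect_delta = effect_delta,
                 leakage_lambda = leakage_lambda,
                 envelope_bandwidth = envelope_bandwidth,
                 covariate_params = covariate_params,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Choose ground-truth affected edges
#'
#' Uniformly samples `affected_edge_count` distinct upper-triangle edge
#' indices without replacement; deterministic given the seed. These are the
#' ground truth that recovery tests score against.
#'
#' @param n_nodes Number of nodes.
#' @param affected_edge_count Number of edges to draw.
#' @param seed Integer seed.
#' @return Sorted integer vector of edge indices (1-based into the
#'   [edge_pairs()] ordering).
#' @export
make_effect_edges <- function(n_nodes, affected_edge_count, seed) {
  E <- n_edges(n_nodes)
  if (affected_edge_count > E)
    stop("make_effect_edges: requested ", affected_edge_count,
         " edges but only ", E, " exist")
  if (affected_edge_count == 0L) return(integer(0))
  with_seed(seed, sort(sample.int(E, affected_edge_count)))
}

#' Generate band-limited signals with controlled envelope correlation
#'
#' Each node's signal is a band-limited carrier (white noise band-passed to
#' `band`) amplitude-modulated by a strictly positive slow envelope. The
#' envelopes are exponentiated correlated low-pass Gaussian processes whose
#' latent (log-envelope) correlation equals the target matrix. The measured
#' envelope correlation attenuates relative to the latent target (carrier
#' noise, filtering), so downstream checks assert ordering, not equality.
#'
#' @param n_nodes Number of nodes.
#' @param duration Seconds.
#' @param fs Sampling rate in Hz; must be at least `2 * band$f_hi`.
#' @param band A [band_spec] for the carrier.
#' @param target_env_corr Symmetric unit-diagonal target correlation matrix
#'   (PSD-repaired internally if needed).
#' @param envelope_bandwidth Bandwidth of the slow envelope process in Hz.
#' @param seed Integer seed.
#' @param log_env_sd SD of the latent log-envelope process (default 0.5).
#' @return Time x node signal matrix with zero-mean columns.
#' @export
generate_band_signal <- function(n_nodes, duration, fs, band, target_env_corr,
                                 envelope_bandwidth = 0.5, seed = 1L,
                                 log_env_sd = 0.5) {
  stopifnot(inherits(band, "band_spec"))
  if (fs < 2 * band$f_hi)
    stop("generate_band_signal: fs = ", fs, " Hz cannot carry a band up to ",
         band$f_hi, " Hz")
  C <- as.matrix(target_env_corr)
  if (nrow(C) != ncol(C) || nrow(C) != n_nodes)
    stop("generate_band_signal: target matrix must be ", n_nodes, " x ", n_nodes)
  if (max(abs(C - t(C))) > 1e-8)
    stop("generate_band_signal: target matrix must be symmetric")
  C <- psd_repair(C)
  n_t <- as.integer(round(duration * fs))
  with_seed(seed, {
    # Slow correlated envelopes: synthesized at a coarse rate (8x bandwidth),
    # low-pass filtered, standardized, mixed by a Cholesky factor, then
    # exponentiated and interpolated to the carrier rate.
    fs_env <- max(2, 8 * envelope_bandwidth)
    n_env <- as.integer(ceiling(duration * fs_env)) + 40L  # pad for filter warm-up
    Z <- matrix(stats::rnorm(n_env * n_nodes), n_env, n_nodes)
    lp <- signal::butter(2, min(0.9, envelope_bandwidth / (fs_env / 2)),
                         type = "low")
    Z <- apply(Z, 2L, function(x) signal::filtfilt(lp, x))
    Z <- Z[seq.int(21L, 20L + ceiling(duration * fs_env)), , drop = FALSE]
    Z <- scale(Z)
    R <- chol(C + diag(1e-9, n_nodes))
    G <- Z %*% R
    t_env <- (seq_len(nrow(G)) - 1) / fs_env
    t_sig <- (seq_len(n_t) - 1) / fs
    A <- apply(G, 2L, function(g)
      stats::approx(t_env, g, xout = pmin(t_sig, max(t_env)), rule = 2)$y)
    A <- exp(log_env_sd * A)
    # Band-limited carriers, independent across nodes.
    bf <- signal::butter(4, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
    W <- matrix(stats::rnorm(n_t * n_nodes), n_t, n_nodes)
    W <- apply(W, 2L, function(x) signal::filtfilt(bf, x))
    X <- W * A
    scale(X, center = TRUE, scale = FALSE)[, , drop = FALSE]
  })
}

#' Apply zero-lag linear leakage mixing
#'
#' Mixes the node signals by `I + lambda * R`, where `R` is a fixed random
#' symmetric zero-diagonal matrix with unit-scale entries, then rescales each
#' output column to retain its input variance. This emulates the field
#' spread that symmetric orthogonalization is designed to remove.
#'
#' @param signals Time x node matrix.
#' @param leakage_lambda Mixing strength >= 0; 0 returns the input unchanged.
#' @param seed Integer seed fixing `R`.
#' @return Time x node matrix with per-column variance preserved.
#' @export
apply_leakage <- function(signals, leakage_lambda, seed = 1L) {
  if (leakage_lambda < 0) stop("apply_leakage: leakage_lambda must be >= 0")
  X <- as.matrix(signals)
  if (leakage_lambda == 0) return(X)
  n <- ncol(X)
  R <- with_seed(seed, {
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- stats::rnorm(n_edges(n))
    M + t(M)
  })
  Y <- X %*% (diag(n) + leakage_lambda * R)
  sx <- apply(X, 2L, stats::sd)
  sy <- apply(Y, 2L, stats::sd)
  sweep(Y, 2L, ifelse(sy > 0, sx / sy, 1), `*`)
}

#' Generate a synthetic cohort of band-limited node timecourses
#'
#' Case subjects use target envelope-correlation matrices reduced by
#' `effect_delta` at the designated affected edges; controls use the baseline
#' target. One independent signal realization per band. Covariates are drawn
#' from the configured per-group distributions.
#'
#' @param config A [sim_config].
#' @return List with `subjects` (named list: per subject, a named list of
#'   [node_timecourses] per band), `manifest` (data frame: subject_id, group,
#'   age, gender, icv), and `effect_edges` (ground-truth affected edge
#'   indices, 1-based into [edge_pairs()] order).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_nodes
  eff <- make_effect_edges(n, config$affected_edge_count, config$seed)
  base_v <- rep(config$baseline_corr, n_edges(n))
  case_v <- base_v
  case_v[eff] <- base_v[eff] * (1 - config$effect_delta)
  C_control <- vec_to_matrix(base_v, n, diag = 1)
  C_case <- vec_to_matrix(case_v, n, diag = 1)
  groups <- rep(c("case", "control"), each = config$n_per_group)
  ids <- sprintf("sub-%03d", seq_along(groups))
  manifest <- with_seed(config$seed + 1L, {
    cv <- lapply(groups, function(g) {
      p <- config$covariate_params[[g]]
      data.frame(age = stats::rnorm(1, p$age_mean, p$age_sd),
                 gender = stats::rbinom(1, 1, p$gender_p),
                 icv = round(stats::rnorm(1, p$icv_mean, p$icv_sd)))
    })
    cbind(data.frame(subject_id = ids, group = groups,
                     stringsAsFactors = FALSE),
          do.call(rbind, cv))
  })
  band_names <- vapply(config$bands, function(b) b$name, "")
  subjects <- lapply(seq_along(ids), function(s) {
    Cs <- if (groups[s] == "case") C_case else C_control
    per_band <- lapply(seq_along(config$bands), function(b) {
      sd_sb <- (config$seed + 7919L * s + 104729L * b) %% 2147483647L
      X <- generate_band_signal(n, config$duration, config$sampling_rate,
                                config$bands[[b]], Cs,
                                config$envelope_bandwidth, seed = sd_sb)
      if (config$leakage_lambda > 0)
        X <- apply_leakage(X, config$leakage_lambda, seed = config$seed + 13L)
      node_timecourses(X, config$sampling_rate, ids[s], config$bands[[b]])
    })
    names(per_band) <- band_names
    per_band
  })
  names(subjects) <- ids
  list(subjects = subjects, manifest = manifest, effect_edges = eff)
}

#' Simulate a cohort directly at the connectivity-edge level
#'
#' Generates subject x edge matrices of normalized connectivity outcomes
#' without synthesizing raw signals: unaffected edges are standard normal in
#' both groups, and affected edges are shifted by `-effect_d` (in SD units,
#' so `effect_d` is exactly Cohen's d) in the case group. Covariates are
#' drawn as in [generate_cohort()]. This is the unit of calibration and
#' recovery studies for the group-statistics procedures, which operate on
#' exchangeable subject-level edge data regardless of how it was measured.
#'
#' @param n_per_group Subjects per group.
#' @param n_nodes Number of nodes (defines the edge count).
#' @param affected_edges Integer edge indices carrying the effect (1-based
#'   into [edge_pairs()] order), e.g. from [make_effect_edges()].
#' @param effect_d Cohen's d of the case-control difference at affected
#'   edges; positive values mean *reduced* connectivity in cases.
#' @param seed Integer seed.
#' @param covariate_params As in [sim_config()].
#' @param icv_edge_slope Optional slope tying edge values to ICV (per voxel),
#'   to exercise the covariate-regression path; default 0.
#' @return A [cohort_data] object.
#' @export
simulate_edge_cohort <- function(n_per_group, n_nodes,
                                 affected_edges = integer(0), effect_d = 0,
                                 seed = 1L,
                                 covariate_params = sim_config()$covariate_params,
                                 icv_edge_slope = 0) {
  E <- n_edges(n_nodes)
  stopifnot(all(affected_edges >= 1), all(affected_edges <= E))
  groups <- rep(c("case", "control"), each = n_per_group)
  ids <- sprintf("sub-%03d", seq_along(groups))
  with_seed(seed, {
    X <- matrix(stats::rnorm(length(groups) * E), length(groups), E)
    X[groups == "case", affected_edges] <-
      X[groups == "case", affected_edges] - effect_d
    cov <- do.call(rbind, lapply(groups, function(g) {
      p <- covariate_params[[g]]
      data.frame(age = stats::rnorm(1, p$age_mean, p$age_sd),
                 gender = stats::rbinom(1, 1, p$gender_p),
                 icv = round(stats::rnorm(1, p$icv_mean, p$icv_sd)))
    }))
    if (icv_edge_slope != 0)
      X <- X + icv_edge_slope * (cov$icv - mean(cov$icv))
    cohort_data(X, groups, covariates = cov, n_nodes = n_nodes,
                subject_id = ids)
  })
}
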