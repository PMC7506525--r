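#' Envelope correlation with Fisher transform
#'
#' Pearson correlation between every pair of node envelopes, followed by the
#' variance-stabilizing Fisher transform `z = atanh(r)`. Correlations of
#' exactly +/-1 (degenerate inputs) are clipped to +/-(1 - 1e-12) with a
#' warning so the transform stays finite.
#'
#' @param env Time x node envelope matrix (>= 10 rows).
#' @param subject_id Subject identifier for the output.
#' @param band Band annotation for the output.
#' @return A [connectivity_matrix] at stage `fisher_z` (zero diagonal).
#' @export
envelope_correlation <- function(env, subject_id = "subject", band = NULL) {
  env <- as.matrix(env)
  if (nrow(env) < 10L)
    stop("envelope_correlation: need at least 10 envelope samples")
  v <- apply(env, 2L, stats::var)
  if (any(v <= 0))
    stop("envelope_correlation: zero-variance node(s): ",
         paste(which(v <= 0), collapse = ", "))
  r <- stats::cor(env)
  off <- abs(r) >= 1 - 1e-15
  diag(off) <- FALSE
  if (any(off)) {
    warning("envelope_correlation: |r| = 1 at ", sum(off) / 2,
            " edge(s); clipped before atanh")
    r[off] <- sign(r[off]) * (1 - 1e-12)
  }
  z <- atanh(r)
  diag(z) <- 0
  connectivity_matrix(z, "fisher_z", subject_id, band)
}

#' Normalize a connectivity map across its edges
#'
#' Standardizes the upper-triangle edge values of one subject's map to zero
#' mean and unit variance. This within-subject normalization removes
#' systematic global offsets (e.g. data-quality differences) before group
#' comparison.
#'
#' @param m A [connectivity_matrix] at stage `fisher_z` (any stage accepted).
#' @return A [connectivity_matrix] at stage `normalized_z`.
#' @export
normalize_connectivity <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  v <- matrix_to_vec(m$values)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("normalize_connectivity: zero spread across edges")
  z <- (v - mean(v)) / s
  connectivity_matrix(vec_to_matrix(z, nrow(m$values)), "normalized_z",
                      m$subject_id, m$band)
}

#' Combine normalized maps across frequency bands
#'
#' Per edge, takes the vector-sum (Euclidean norm by default) of the
#' band-specific normalized connectivity values:
#' `sqrt(sum_b z_b^2)`. A plain `sum` alternative is provided.
#'
#' @param maps List of [connectivity_matrix] objects at stage `normalized_z`,
#'   one per band, same subject and node set.
#' @param method `"norm"` (Euclidean vector-sum, default) or `"sum"`.
#' @return A [connectivity_matrix] at stage `combined`.
#' @export
combine_bands <- function(maps, method = c("norm", "sum")) {
  method <- match.arg(method)
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, TRUE, "connectivity_matrix")))
  n <- nrow(maps[[1L]]$values)
  if (!all(vapply(maps, function(m) nrow(m$values), 0L) == n))
    stop("combine_bands: maps have mismatched node counts")
  if (!all(vapply(maps, function(m) m$stage, "") == "normalized_z"))
    stop("combine_bands: all maps must be at stage normalized_z")
  vs <- vapply(maps, function(m) matrix_to_vec(m$values), numeric(n_edges(n)))
  vs <- matrix(vs, ncol = length(maps))
  comb <- switch(method,
                 norm = sqrt(rowSums(vs^2)),
                 sum  = rowSums(vs))
  connectivity_matrix(vec_to_matrix(comb, n), "combined",
                      maps[[1L]]$subject_id, "combined")
}

#' Full per-subject envelope-connectivity pipeline
#'
#' Chains, per band: band-pass filter -> symmetric orthogonalization ->
#' Hilbert envelope -> despike/downsample/trim -> envelope correlation with
#' Fisher transform -> per-subject edge normalization; then combines the
#' band maps by the vector-sum. The order is fixed.
#'
#' @param tc Broadband [node_timecourses].
#' @param bands List of [band_spec] (default [canonical_bands()]).
#' @param median_window Running-median width in seconds (default 0.25).
#' @param trim Seconds trimmed per end at 1 Hz (default 2).
#' @param filter_order Butterworth order (default 4).
#' @param combine `"norm"` or `"sum"` (see [combine_bands()]).
#' @param orthogonalize If `FALSE`, skip leakage correction (diagnostics).
#' @return List with `bands` (named list of `normalized_z`
#'   [connectivity_matrix]) and `combined` (the combined-frequency map).
#' @export
subject_pipeline <- function(tc, bands = canonical_bands(),
                             median_window = 0.25, trim = 2,
                             filter_order = 4L, combine = "norm",
                             orthogonalize = TRUE) {
  stopifnot(inherits(tc, "node_timecourses"))
  per_band <- lapply(bands, function(b) {
    x <- bandpass_filter(tc, b, order = filter_order)
    if (orthogonalize) x <- symmetric_orthogonalize(x)
    env <- hilbert_envelope(x)
    env_ds <- despike_downsample(env, x$fs, median_window, trim)
    normalize_connectivity(envelope_correlation(env_ds, tc$subject_id, b))
  })
  names(per_band) <- vapply(bands, function(b) b$name, "")
  list(bands = per_band,
       combined = combine_bands(per_band, method = combine))
}
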