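#' Node timecourses container
#'
#' Holds a subject's time x node signal matrix together with its sampling
#' rate and (optionally) the frequency band it is limited to. This is the
#' pipeline's entry point: columns are atlas nodes, rows are time samples.
#'
#' @param data Numeric matrix, time x nodes; no missing values; at least as
#'   many time samples as nodes (required for orthogonalization).
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier string.
#' @param band A [band_spec] or `NULL` for broadband.
#' @return An object of class `node_timecourses`.
#' @export
node_timecourses <- function(data, fs, subject_id = "subject", band = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("node_timecourses: data must be numeric")
  if (anyNA(data)) stop("node_timecourses: data contains missing values")
  if (nrow(data) < ncol(data))
    stop("node_timecourses: need at least as many time samples (", nrow(data),
         ") as nodes (", ncol(data), ")")
  fs <- as.numeric(fs)
  stopifnot(is.finite(fs), fs > 0)
  if (!is.null(band) && !inherits(band, "band_spec"))
    stop("node_timecourses: band must be a band_spec or NULL")
  structure(list(subject_id = as.character(subject_id), fs = fs,
                 data = data, band = band),
            class = "node_timecourses")
}

#' @export
print.node_timecourses <- function(x, ...) {
  cat(sprintf("<node_timecourses> %s: %d samples x %d nodes @ %g Hz (%s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              if (is.null(x$band)) "broadband" else x$band$name))
  invisible(x)
}

#' Connectivity matrix container
#'
#' A symmetric node x node map with a processing-stage tag. Stages are
#' `pearson_r` (raw envelope correlation), `fisher_z` (atanh-transformed),
#' `normalized_z` (edge-standardized within subject) and `combined`
#' (vector-sum across bands). The diagonal is always 0.
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param stage One of `"pearson_r"`, `"fisher_z"`, `"normalized_z"`,
#'   `"combined"`.
#' @param subject_id Subject identifier.
#' @param band A [band_spec], the string `"combined"`, or `NULL`.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, stage, subject_id = "subject",
                                band = NULL) {
  values <- as.matrix(values)
  stage <- match.arg(stage, c("pearson_r", "fisher_z", "normalized_z",
                              "combined"))
  if (nrow(values) != ncol(values))
    stop("connectivity_matrix: values must be square")
  if (max(abs(values - t(values))) > 1e-8)
    stop("connectivity_matrix: values must be symmetric")
  diag(values) <- 0
  structure(list(subject_id = as.character(subject_id), band = band,
                 values = values, stage = stage),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  bn <- if (is.null(x$band)) "?" else if (is.character(x$band)) x$band else x$band$name
  cat(sprintf("<connectivity_matrix> %s [%s, %s]: %d nodes, %d edges\n",
              x$subject_id, bn, x$stage, nrow(x$values), n_edges(nrow(x$values))))
  invisible(x)
}
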