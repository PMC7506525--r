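SCHEMA_VERSION <- "aecnet-1"

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write / read node timecourses as CSV with a JSON sidecar
#'
#' The CSV holds the time x node matrix (header = node labels); the sidecar
#' records subject id, sampling rate, band and schema version.
#'
#' @param tc A [node_timecourses].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tc, path) {
  stopifnot(inherits(tc, "node_timecourses"))
  d <- as.data.frame(tc$data)
  names(d) <- sprintf("n%03d", seq_len(ncol(d)) - 1L)
  utils::write.csv(d, path, row.names = FALSE)
  meta <- list(schema = SCHEMA_VERSION, subject_id = tc$subject_id,
               fs = tc$fs,
               band = if (is.null(tc$band)) NULL else
                 list(name = tc$band$name, f_lo = tc$band$f_lo,
                      f_hi = tc$band$f_hi))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timecourses
#' @export
read_timecourses <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  d <- as.matrix(utils::read.csv(path, check.names = FALSE))
  band <- if (length(meta$band) == 0) NULL else
    band_spec(meta$band$name, meta$band$f_lo, meta$band$f_hi)
  node_timecourses(d, meta$fs, meta$subject_id, band)
}

#' Write / read a connectivity matrix as CSV with a JSON sidecar
#'
#' @param m A [connectivity_matrix].
#' @param path CSV path (node x node values).
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  d <- as.data.frame(m$values)
  names(d) <- sprintf("n%03d", seq_len(ncol(d)) - 1L)
  utils::write.csv(d, path, row.names = FALSE)
  band <- m$band
  meta <- list(schema = SCHEMA_VERSION, subject_id = m$subject_id,
               stage = m$stage,
               band = if (is.null(band)) NULL
                      else if (is.character(band)) band
                      else list(name = band$name, f_lo = band$f_lo,
                                f_hi = band$f_hi))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.csv(path, check.names = FALSE))
  dimnames(vals) <- NULL
  band <- meta$band
  if (length(band) == 0) band <- NULL
  else if (!is.character(band))
    band <- band_spec(band$name, band$f_lo, band$f_hi)
  connectivity_matrix(vals, meta$stage, meta$subject_id, band)
}

#' Write / read a cohort manifest as JSON
#'
#' @param manifest Data frame with at least `subject_id` and `group`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(is.data.frame(manifest),
            all(c("subject_id", "group") %in% names(manifest)))
  jsonlite::write_json(list(schema = SCHEMA_VERSION, subjects = manifest),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(obj$subjects)
}

#' Write / read an edge list as a two-or-three column CSV
#'
#' Columns `i`, `j` are 0-based node indices with `i < j` (the package-wide
#' edge convention); an optional `value` column carries edge values. Files
#' violating `i < j` are rejected with the offending line number.
#'
#' @param edges Data frame with columns `i`, `j` and optionally `value`, or
#'   an integer vector of edge indices (1-based into [edge_pairs()] order)
#'   together with `n_nodes`.
#' @param path CSV path.
#' @param n_nodes Needed when `edges` is an index vector.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, n_nodes = NULL) {
  if (!is.data.frame(edges)) {
    stopifnot(!is.null(n_nodes))
    ep <- edge_pairs(n_nodes)
    edges <- data.frame(i = ep[edges, 1L], j = ep[edges, 2L])
  }
  stopifnot(all(c("i", "j") %in% names(edges)))
  if (any(edges$i >= edges$j))
    stop("write_edge_list: rows with i >= j violate the edge convention")
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("i", "j") %in% names(d)))
    stop("read_edge_list: need columns i and j in ", path)
  bad <- which(d$i >= d$j)
  if (length(bad))
    stop("read_edge_list: i >= j at data line ", bad[1L], " of ", path)
  d
}

#' Write nodal feature tables
#'
#' `write_feature_table()` writes the wide subject x feature matrix;
#' `feature_table_tidy()` reshapes it to long form (subject_id, node,
#' metric, value) for the tidy CSV export.
#'
#' @param ft A [feature_table()] matrix.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  d <- data.frame(subject_id = rownames(ft), ft, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
feature_table_tidy <- function(ft) {
  metrics <- attr(ft, "metrics")
  n <- attr(ft, "n_nodes")
  do.call(rbind, lapply(metrics, function(mt) {
    blk <- metric_block(ft, mt)
    data.frame(subject_id = rep(rownames(ft), times = n),
               node = rep(seq_len(n) - 1L, each = nrow(ft)),
               metric = mt, value = as.vector(blk))
  }))
}

#' Write tidy edge statistics
#'
#' One row per edge combining Welch, omnibus and robustness results.
#'
#' @param welch [welch_edges()] output.
#' @param omnibus [omnibus_permutation()] output (or `NULL`).
#' @param robust [split_half_robustness()] output (or `NULL`).
#' @param path CSV path.
#' @return The combined data frame, invisibly.
#' @export
write_edge_stats <- function(welch, omnibus = NULL, robust = NULL, path) {
  d <- welch
  if (!is.null(omnibus)) {
    stopifnot(identical(omnibus$edge, welch$edge))
    d$omnibus_significant <- omnibus$significant
    d$omnibus_threshold <- omnibus$threshold
  }
  if (!is.null(robust)) {
    stopifnot(identical(robust$edge, welch$edge))
    d$consistency <- robust$consistency
    d$sign <- robust$sign
    d$robust <- robust$robust
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters plus the global seed. Configurations
#' round-trip through YAML (`save_run_config()` / `load_run_config()`), and
#' every [run_pipeline()] output directory receives the resolved config.
#'
#' @param sim Named list of [sim_config()] arguments (bands are given as
#'   `list(name = c(f_lo, f_hi))`).
#' @param connectivity Named list: `median_window`, `trim`, `filter_order`,
#'   `combine`.
#' @param groupstats Named list: `fraction`, `n_perm`, `n_iter`,
#'   `n_iter_regression`, `consistency`, `alpha`.
#' @param graphs Named list: `fraction`, `mode`.
#' @param classify Named list: `n_folds`, `n_reps`, `n_perm`, `perm_reps`,
#'   `feature_sets`, `contrasts`.
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = list(), connectivity = list(),
                       groupstats = list(), graphs = list(),
                       classify = list(), seed = 1L) {
  defaults <- list(
    sim = list(n_per_group = 42L, n_nodes = 90L,
               bands = lapply(canonical_bands(),
                              function(b) c(b$f_lo, b$f_hi)),
               sampling_rate = 600, duration = 250, baseline_corr = 0.3,
               affected_edge_count = 30L, effect_delta = 0.5,
               leakage_lambda = 0, envelope_bandwidth = 0.5),
    connectivity = list(median_window = 0.25, trim = 2, filter_order = 4L,
                        combine = "norm"),
    groupstats = list(fraction = 0.20, n_perm = 10000L, n_iter = 10000L,
                      n_iter_regression = 1000L, consistency = 0.95,
                      alpha = 0.05),
    graphs = list(fraction = 0.20, mode = "thresholded"),
    classify = list(n_folds = 5L, n_reps = 100L, n_perm = 5000L,
                    perm_reps = 10L, feature_sets = "pooled",
                    contrasts = "case_vs_control"))
  sim_merged <- utils::modifyList(defaults$sim, sim)
  if (!is.null(sim$bands)) sim_merged$bands <- sim$bands  # replace, not merge
  cfg <- list(sim = sim_merged,
              connectivity = utils::modifyList(defaults$connectivity,
                                               connectivity),
              groupstats = utils::modifyList(defaults$groupstats, groupstats),
              graphs = utils::modifyList(defaults$graphs, graphs),
              classify = utils::modifyList(defaults$classify, classify),
              seed = as.integer(seed), schema = SCHEMA_VERSION)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML path.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(sim = raw$sim %||% list(),
             connectivity = raw$connectivity %||% list(),
             groupstats = raw$groupstats %||% list(),
             graphs = raw$graphs %||% list(),
             classify = raw$classify %||% list(),
             seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
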