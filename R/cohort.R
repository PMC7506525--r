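#' Cohort-level connectivity data
#'
#' Stacks subject-level edge vectors with group labels and covariates; the
#' unit of all group statistics. Edge columns follow the [edge_pairs()]
#' ordering for `n_nodes` nodes.
#'
#' @param edges Numeric subject x edge matrix.
#' @param group Character vector, one of `"case"`/`"control"` per subject
#'   (subgroup contrasts are handled at the classification stage).
#' @param covariates Optional data frame with columns `age`, `gender`
#'   (0/1) and `icv` (voxels), one row per subject.
#' @param n_nodes Number of nodes; inferred from the edge count if missing.
#' @param subject_id Optional subject identifiers.
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(edges, group, covariates = NULL, n_nodes = NULL,
                        subject_id = NULL) {
  edges <- as.matrix(edges)
  group <- as.character(group)
  if (nrow(edges) != length(group))
    stop("cohort_data: ", nrow(edges), " edge rows but ", length(group),
         " group labels")
  if (!all(group %in% c("case", "control")))
    stop("cohort_data: group labels must be 'case' or 'control'")
  if (any(table(factor(group, c("case", "control"))) == 0))
    stop("cohort_data: both groups must be nonempty")
  if (is.null(n_nodes)) {
    n_nodes <- (1 + sqrt(1 + 8 * ncol(edges))) / 2
    if (abs(n_nodes - round(n_nodes)) > 1e-9)
      stop("cohort_data: edge count ", ncol(edges), " is not n*(n-1)/2")
    n_nodes <- as.integer(round(n_nodes))
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    need <- c("age", "gender", "icv")
    if (!all(need %in% names(covariates)))
      stop("cohort_data: covariates must contain ",
           paste(need, collapse = ", "))
    if (nrow(covariates) != nrow(edges))
      stop("cohort_data: covariate rows must match subjects")
  }
  if (is.null(subject_id)) subject_id <- sprintf("sub-%03d", seq_len(nrow(edges)))
  structure(list(edges = edges, group = group, covariates = covariates,
                 n_nodes = as.integer(n_nodes),
                 subject_id = as.character(subject_id)),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d subjects (%d case / %d control), %d nodes, %d edges%s\n",
              nrow(x$edges), sum(x$group == "case"),
              sum(x$group == "control"), x$n_nodes, ncol(x$edges),
              if (is.null(x$covariates)) "" else ", covariates: age/gender/icv"))
  invisible(x)
}

#' Assemble cohort data from per-subject connectivity maps
#'
#' @param maps List of [connectivity_matrix] objects (one per subject, same
#'   stage and node count).
#' @param group Character vector of `"case"`/`"control"` labels.
#' @param covariates Optional covariate data frame (see [cohort_data()]).
#' @return A [cohort_data] object.
#' @export
cohort_from_maps <- function(maps, group, covariates = NULL) {
  stopifnot(length(maps) >= 2L,
            all(vapply(maps, inherits, TRUE, "connectivity_matrix")))
  n <- nrow(maps[[1L]]$values)
  edges <- t(vapply(maps, function(m) matrix_to_vec(m$values),
                    numeric(n_edges(n))))
  ids <- vapply(maps, function(m) m$subject_id, "")
  cohort_data(edges, group, covariates, n_nodes = n, subject_id = ids)
}
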