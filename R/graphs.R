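#' Threshold a connectivity map into a subject graph
#'
#' Retains the top `fraction` of edge values (ceiling of `fraction * E`
#' edges; ties broken by edge index order, deterministically) as an
#' undirected weighted graph. Edge weights are the retained connectivity
#' values; path computations use inverse weights as distances, so stronger
#' amplitude-amplitude coupling means shorter paths. Retained edges with
#' nonpositive weight stay in the graph for degree and clustering but are
#' excluded from path computations (with a warning).
#'
#' @param m A [connectivity_matrix] (stage `normalized_z` or `combined`).
#' @param fraction Fraction of edges retained, in (0, 1]; `1` gives the
#'   unthresholded mode.
#' @return An object of class `subject_graph`: `n_nodes`, `edges` (data
#'   frame `i`, `j` 0-based, `w`, `dist` = 1/w or Inf), `fraction`, `mode`.
#' @export
threshold_individual <- function(m, fraction = 0.20) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (!(fraction > 0 && fraction <= 1))
    stop("threshold_individual: fraction must lie in (0, 1]")
  v <- matrix_to_vec(m$values)
  E <- length(v)
  k <- ceiling(fraction * E)
  keep <- order(-v, seq_along(v))[seq_len(k)]
  ep <- edge_pairs(nrow(m$values))
  w <- v[keep]
  if (any(w <= 0))
    warning("threshold_individual: ", sum(w <= 0), " retained edge(s) have ",
            "nonpositive weight; excluded from path computations")
  g <- structure(list(n_nodes = nrow(m$values),
                      edges = data.frame(i = ep[keep, 1L], j = ep[keep, 2L],
                                         w = w,
                                         dist = ifelse(w > 0, 1 / w, Inf)),
                      fraction = fraction,
                      mode = if (fraction < 1) "thresholded" else "unthresholded",
                      subject_id = m$subject_id),
                 class = "subject_graph")
  g
}

#' @export
print.subject_graph <- function(x, ...) {
  cat(sprintf("<subject_graph> %s: %d nodes, %d edges (%s, fraction %.2f)\n",
              x$subject_id, x$n_nodes, nrow(x$edges), x$mode, x$fraction))
  invisible(x)
}

# igraph over the positive-weight edges, with 1/w distances as edge weights.
as_igraph_paths <- function(g) {
  e <- g$edges[g$edges$w > 0, , drop = FALSE]
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  if (nrow(e) > 0) {
    ig <- igraph::add_edges(ig, rbind(e$i + 1L, e$j + 1L))
    igraph::E(ig)$weight <- e$dist
  }
  ig
}

#' All-pairs shortest-path distances of a subject graph
#'
#' Dijkstra over the inverse-weight edge distances; unreachable pairs get
#' `Inf`, the diagonal is 0.
#'
#' @param g A [threshold_individual()] graph.
#' @return Symmetric `n_nodes x n_nodes` distance matrix.
#' @export
shortest_path_distances <- function(g) {
  stopifnot(inherits(g, "subject_graph"))
  igraph::distances(as_igraph_paths(g), algorithm = "dijkstra")
}

#' Six nodal graph metrics
#'
#' Characterizes each node of a subject graph by: `degree` (number of
#' retained incident edges, unweighted); `betweenness` (fraction of shortest
#' paths containing the node, endpoints excluded, normalized by
#' (n-1)(n-2)/2); `eccentricity` (maximal shortest-path distance to any
#' reachable node; isolated nodes get 0); `global_efficiency` (mean inverse
#' shortest-path distance to all other nodes, unreachable contributing 0);
#' `local_efficiency` (mean inverse shortest-path distance between the
#' node's neighbors within the neighbor-induced subgraph); and `clustering`
#' (Onnela weighted coefficient on weights rescaled by the graph maximum).
#' All path-based metrics use the inverse-weight distances; clustering uses
#' the raw connectivity weights. Nodes with fewer than two neighbors get
#' clustering and local efficiency 0.
#'
#' @param g A [subject_graph].
#' @return Data frame with one row per node and columns `node` (0-based),
#'   `degree`, `betweenness`, `eccentricity`, `global_efficiency`,
#'   `local_efficiency`, `clustering`.
#' @export
node_metrics <- function(g) {
  stopifnot(inherits(g, "subject_graph"))
  n <- g$n_nodes
  e_all <- g$edges
  deg <- tabulate(c(e_all$i, e_all$j) + 1L, nbins = n)
  ig <- as_igraph_paths(g)
  D <- igraph::distances(ig, algorithm = "dijkstra")
  btw_norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  btw <- igraph::betweenness(ig, directed = FALSE) / btw_norm
  Doff <- D; diag(Doff) <- NA
  ecc <- apply(Doff, 1L, function(d) {
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else max(d)
  })
  geff <- apply(Doff, 1L, function(d) {
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    sum(inv, na.rm = TRUE) / (n - 1)
  })
  # Weight matrices: positive part for paths/clustering, binary for degree.
  Wpos <- matrix(0, n, n)
  epos <- e_all[e_all$w > 0, , drop = FALSE]
  Wpos[cbind(epos$i + 1L, epos$j + 1L)] <- epos$w
  Wpos <- Wpos + t(Wpos)
  wmax <- max(Wpos)
  Chat <- if (wmax > 0) (Wpos / wmax)^(1 / 3) else Wpos
  tri <- diag(Chat %*% Chat %*% Chat)
  clus <- ifelse(deg >= 2, tri / (deg * (deg - 1)), 0)
  leff <- vapply(seq_len(n), function(v) {
    nb <- which(Wpos[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- igraph::induced_subgraph(ig, nb)
    Ds <- igraph::distances(sub, algorithm = "dijkstra")
    inv <- 1 / Ds
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
  data.frame(node = seq_len(n) - 1L, degree = deg, betweenness = unname(btw),
             eccentricity = unname(ecc), global_efficiency = unname(geff),
             local_efficiency = leff, clustering = unname(clus))
}

#' Nodal feature table for a cohort of maps
#'
#' Thresholds each subject's map, computes the six nodal metrics and lays
#' them out as one row per subject with 6 * n_nodes columns (metric blocks
#' in the order degree, betweenness, eccentricity, global_efficiency,
#' local_efficiency, clustering) — the pooled feature vector. Single-metric
#' blocks can be extracted with [metric_block()].
#'
#' @param maps List of [connectivity_matrix] objects, same node count.
#' @param fraction Edge fraction retained per subject (default 0.20).
#' @param mode `"thresholded"` (default) or `"unthresholded"` (ignore
#'   `fraction`, keep all edges).
#' @return Numeric matrix, subjects x (6 * n_nodes), with row names from the
#'   maps' subject ids and a `metrics` attribute naming the blocks.
#' @export
feature_table <- function(maps, fraction = 0.20,
                          mode = c("thresholded", "unthresholded")) {
  mode <- match.arg(mode)
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, TRUE, "connectivity_matrix")))
  n <- nrow(maps[[1L]]$values)
  if (!all(vapply(maps, function(m) nrow(m$values), 0L) == n))
    stop("feature_table: maps have mismatched node counts")
  frac <- if (mode == "unthresholded") 1 else fraction
  metrics <- c("degree", "betweenness", "eccentricity", "global_efficiency",
               "local_efficiency", "clustering")
  rows <- lapply(maps, function(m) {
    nm <- node_metrics(threshold_individual(m, frac))
    unlist(nm[metrics], use.names = FALSE)
  })
  ft <- do.call(rbind, rows)
  colnames(ft) <- as.vector(vapply(metrics, function(mt)
    sprintf("%s_n%03d", mt, seq_len(n) - 1L), character(n)))
  rownames(ft) <- vapply(maps, function(m) m$subject_id, "")
  attr(ft, "metrics") <- metrics
  attr(ft, "n_nodes") <- n
  ft
}

#' Extract one metric's column block from a feature table
#'
#' @param ft A [feature_table()] matrix.
#' @param metric One of the six metric names, or `"pooled"` for all columns.
#' @return Numeric matrix, subjects x n_nodes (or x 6*n_nodes for pooled).
#' @export
metric_block <- function(ft, metric) {
  if (metric == "pooled") return(ft)
  metrics <- attr(ft, "metrics")
  if (!metric %in% metrics)
    stop("metric_block: unknown metric '", metric, "'")
  ft[, startsWith(colnames(ft), paste0(metric, "_")), drop = FALSE]
}
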