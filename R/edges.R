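#' Upper-triangle edge index pairs
#'
#' Edges of an undirected `n`-node graph are indexed by upper-triangle node
#' pairs `(i, j)` with `i < j`, 0-based, in lexicographic order:
#' (0,1), (0,2), ..., (0,n-1), (1,2), .... This convention is fixed across
#' all modules; edge vectors produced anywhere in the package follow it.
#'
#' @param n_nodes Number of nodes.
#' @return Integer matrix with columns `i`, `j` (0-based) and
#'   `n_nodes*(n_nodes-1)/2` rows.
#' @examples
#' edge_pairs(4)
#' @export
edge_pairs <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 2L)
  i <- rep.int(seq_len(n_nodes - 1L) - 1L, times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(k) k:(n_nodes - 1L)),
              use.names = FALSE)
  cbind(i = i, j = j)
}

#' Number of edges for n nodes
#' @param n_nodes Number of nodes.
#' @return `n_nodes*(n_nodes-1)/2`.
#' @export
n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1) / 2)

#' Extract the upper-triangle edge vector of a symmetric matrix
#'
#' @param m Square symmetric numeric matrix.
#' @return Numeric vector of length `n(n-1)/2`, ordered as in [edge_pairs()].
#' @seealso [vec_to_matrix()] for the inverse.
#' @export
matrix_to_vec <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ep <- edge_pairs(nrow(m))
  m[cbind(ep[, 1L] + 1L, ep[, 2L] + 1L)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' @param v Edge vector in [edge_pairs()] order.
#' @param n_nodes Number of nodes; inferred from `length(v)` if missing.
#' @param diag Value placed on the diagonal (default 0).
#' @return Symmetric `n_nodes x n_nodes` matrix.
#' @export
vec_to_matrix <- function(v, n_nodes = NULL, diag = 0) {
  if (is.null(n_nodes)) {
    n_nodes <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (abs(n_nodes - round(n_nodes)) > 1e-9)
      stop("vec_to_matrix: length ", length(v), " is not a triangular number")
    n_nodes <- as.integer(round(n_nodes))
  }
  if (length(v) != n_edges(n_nodes))
    stop("vec_to_matrix: expected ", n_edges(n_nodes), " values, got ", length(v))
  m <- matrix(diag, n_nodes, n_nodes)
  ep <- edge_pairs(n_nodes)
  m[cbind(ep[, 1L] + 1L, ep[, 2L] + 1L)] <- v
  m[cbind(ep[, 2L] + 1L, ep[, 1L] + 1L)] <- v
  m
}
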