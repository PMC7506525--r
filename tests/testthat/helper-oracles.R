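# Independent brute-force oracles used across tests. These deliberately
# share no code with the package implementation: distances come from
# exhaustive simple-path enumeration, betweenness from explicit shortest-path
# counting, clustering from a direct triple loop.

# Random symmetric connectivity map (normalized_z-like values).
random_map <- function(n, subject_id = "s", stage = "normalized_z") {
  v <- rnorm(aecnet::n_edges(n))
  v <- (v - mean(v)) / sd(v)
  aecnet::connectivity_matrix(aecnet::vec_to_matrix(v, n), stage, subject_id)
}

# Weight matrix (n x n, 0 = absent) from a subject_graph.
graph_weight_matrix <- function(g) {
  W <- matrix(0, g$n_nodes, g$n_nodes)
  W[cbind(g$edges$i + 1L, g$edges$j + 1L)] <- g$edges$w
  W + t(W)
}

# Enumerate all simple paths s -> t over positive-weight edges; returns the
# list of path lengths and the node sequences.
enumerate_paths <- function(D, s, t) {
  n <- nrow(D)
  lens <- numeric(0)
  paths <- list()
  walk <- function(v, visited, len) {
    if (v == t) {
      lens[[length(lens) + 1L]] <<- len
      paths[[length(paths) + 1L]] <<- visited
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (D[v, u] > 0 && !(u %in% visited))
        walk(u, c(visited, u), len + D[v, u])
    }
  }
  walk(s, s, 0)
  list(lens = lens, paths = paths)
}

# Brute-force versions of all six nodal metrics. `dist_w` is the matrix of
# path distances per edge (1/w, 0 = absent); `conn_w` the raw connectivity
# weights; `deg_w` a binary adjacency counting every retained edge.
brute_metrics <- function(deg_adj, conn_w, dist_w) {
  n <- nrow(deg_adj)
  eps <- 1e-12
  # all-pairs shortest distances by path enumeration
  Dsp <- matrix(Inf, n, n); diag(Dsp) <- 0
  sigma <- matrix(0, n, n)          # number of shortest paths
  sp_paths <- vector("list", n * n) # shortest path node sets
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    pe <- enumerate_paths(dist_w, s, t)
    if (length(pe$lens) == 0) next
    lens <- unlist(pe$lens)
    dmin <- min(lens)
    Dsp[s, t] <- Dsp[t, s] <- dmin
    on_min <- which(lens <= dmin * (1 + eps) + eps)
    sigma[s, t] <- sigma[t, s] <- length(on_min)
    sp_paths[[(s - 1) * n + t]] <- pe$paths[on_min]
  }
  degree <- rowSums(deg_adj > 0)
  # betweenness: count shortest paths through v (endpoints excluded)
  btw <- numeric(n)
  for (v in 1:n) {
    tot <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || sigma[s, t] == 0) next
      pl <- sp_paths[[(s - 1) * n + t]]
      tot <- tot + sum(vapply(pl, function(p) v %in% p, TRUE)) / sigma[s, t]
    }
    btw[v] <- tot / if (n > 2) ((n - 1) * (n - 2) / 2) else 1
  }
  ecc <- vapply(1:n, function(v) {
    d <- Dsp[v, -v]; d <- d[is.finite(d)]
    if (!length(d)) 0 else max(d)
  }, 0)
  geff <- vapply(1:n, function(v) {
    inv <- 1 / Dsp[v, -v]; inv[!is.finite(inv)] <- 0
    sum(inv) / (n - 1)
  }, 0)
  leff <- vapply(1:n, function(v) {
    nb <- which(conn_w[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- dist_w[nb, nb, drop = FALSE]
    tot <- 0
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      pe <- enumerate_paths(sub, a, b)
      if (length(pe$lens)) tot <- tot + 2 / min(unlist(pe$lens))
    }
    tot / (k * (k - 1))
  }, 0)
  wmax <- max(conn_w)
  What <- if (wmax > 0) conn_w / wmax else conn_w
  clus <- vapply(1:n, function(v) {
    k <- degree[v]
    if (k < 2) return(0)
    tot <- 0
    for (u in 1:n) for (w in 1:n) {
      if (u == v || w == v || u == w) next
      tot <- tot + (What[v, u] * What[v, w] * What[u, w])^(1 / 3)
    }
    tot / (k * (k - 1))
  }, 0)
  data.frame(degree = degree, betweenness = btw, eccentricity = ecc,
             global_efficiency = geff, local_efficiency = leff,
             clustering = clus)
}

# Run both implementation and oracle on a subject_graph with positive weights.
compare_metrics_to_oracle <- function(g) {
  W <- graph_weight_matrix(g)
  Dw <- ifelse(W > 0, 1 / W, 0)
  got <- aecnet::node_metrics(g)
  want <- brute_metrics(W, W, Dw)
  max(abs(as.matrix(got[names(want)]) - as.matrix(want)))
}

# Random connected-ish positive-weight subject_graph on n nodes.
random_subject_graph <- function(n, p_edge = 0.5) {
  v <- runif(aecnet::n_edges(n), 0.2, 2)
  drop <- runif(length(v)) > p_edge
  v[drop] <- -Inf                   # never retained
  k <- sum(!drop)
  if (k < 1) return(random_subject_graph(n, p_edge))
  m <- aecnet::connectivity_matrix(
    aecnet::vec_to_matrix(ifelse(is.finite(v), v, -1), n), "combined")
  aecnet::threshold_individual(m, (k - 0.5) / length(v))
}

# Toy cohort with specified per-group edge matrices.
toy_cohort <- function(case_edges, control_edges, n_nodes,
                       covariates = NULL) {
  aecnet::cohort_data(rbind(case_edges, control_edges),
                      rep(c("case", "control"),
                          c(nrow(case_edges), nrow(control_edges))),
                      covariates = covariates, n_nodes = n_nodes)
}

# Independent oracle for the closest-orthogonal-matrix problem: with
# X = Q R (thin QR), the optimum lies in the column space of X, so the
# objective reduces to min over 3x3 orthogonal W and scales s of
# ||R - W diag(s)||_F. W is parameterized by Euler angles (both determinant
# branches tried); optimized with a general-purpose quasi-Newton method.
closest_orth_residual_oracle <- function(X) {
  R <- qr.R(qr(X))
  rot <- function(a) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
    Rz(a[1]) %*% Ry(a[2]) %*% Rz(a[3])
  }
  best <- Inf
  for (flip in list(diag(3), diag(c(1, 1, -1)))) {
    obj <- function(par) {
      W <- rot(par[1:3]) %*% flip
      sum((R - W %*% diag(par[4:6]))^2)
    }
    for (try in 1:8) {
      p0 <- c(runif(3, -pi, pi), diag(R) * runif(3, 0.5, 1.5))
      o <- optim(p0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
  }
  sqrt(best)
}
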