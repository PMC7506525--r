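# graph builders for hand-enumerated cases
graph_from_edges <- function(n, i, j, w) {
  v <- rep(-1, n_edges(n))
  ep <- edge_pairs(n)
  for (k in seq_along(i)) {
    idx <- which(ep[, 1] == i[k] & ep[, 2] == j[k])
    v[idx] <- w[k]
  }
  m <- connectivity_matrix(vec_to_matrix(v, n), "combined")
  threshold_individual(m, (length(i) - 0.5) / n_edges(n))
}

test_that("individual thresholding retains the top fraction deterministically", {
  set.seed(20)
  m <- random_map(90)
  g <- threshold_individual(m, 0.20)
  expect_equal(nrow(g$edges), 801)   # ceiling(0.2 * 4005)
  expect_equal(g$mode, "thresholded")
  v <- matrix_to_vec(m$values)
  expect_setequal(g$edges$w, sort(v, decreasing = TRUE)[1:801])
  # fraction 1: unthresholded mode keeps everything, warning about the
  # nonpositive weights that path metrics will skip
  expect_warning(g_all <- threshold_individual(m, 1), "nonpositive")
  expect_equal(nrow(g_all$edges), 4005)
  expect_equal(g_all$mode, "unthresholded")
  # 6-edge toy: only the largest edge survives fraction 0.2
  m6 <- connectivity_matrix(vec_to_matrix(1:6, 4), "combined")
  g6 <- threshold_individual(m6, 0.2)
  expect_equal(nrow(g6$edges), 2)    # ceiling(0.2 * 6)
  expect_setequal(g6$edges$w, c(6, 5))
  expect_error(threshold_individual(m6, 0), "fraction")
  # inverse-weight distances
  expect_equal(g6$edges$dist, 1 / g6$edges$w)
})

test_that("shortest-path distances follow inverse weights", {
  tri <- graph_from_edges(3, c(0, 0, 1), c(1, 2, 2), c(1, 1, 1))
  D <- shortest_path_distances(tri)
  expect_equal(D, matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  path <- graph_from_edges(3, c(0, 1), c(1, 2), c(1, 1))
  Dp <- shortest_path_distances(path)
  expect_equal(Dp[1, 3], 2)
  # disconnected pair is infinite
  iso <- graph_from_edges(3, 0, 1, 1)
  expect_equal(shortest_path_distances(iso)[1, 3], Inf)
  # random 8-node graphs match the exhaustive path-enumeration oracle
  set.seed(21)
  for (r in 1:5) {
    g <- random_subject_graph(8, 0.4)
    W <- graph_weight_matrix(g)
    Dw <- ifelse(W > 0, 1 / W, 0)
    got <- shortest_path_distances(g)
    n <- nrow(W)
    for (s in 1:(n - 1)) for (t2 in (s + 1):n) {
      pe <- enumerate_paths(Dw, s, t2)
      want <- if (length(pe$lens)) min(unlist(pe$lens)) else Inf
      expect_equal(got[s, t2], want, tolerance = 1e-10)
    }
  }
})

test_that("nodal metrics on hand-enumerated toy graphs", {
  tri <- graph_from_edges(3, c(0, 0, 1), c(1, 2, 2), c(1, 1, 1))
  mt <- node_metrics(tri)
  expect_equal(mt$degree, rep(2, 3))
  expect_equal(mt$clustering, rep(1, 3))
  expect_equal(mt$betweenness, rep(0, 3))

  path <- graph_from_edges(3, c(0, 1), c(1, 2), c(1, 1))
  mp <- node_metrics(path)
  expect_equal(mp$betweenness[2], 1)  # single a-c path passes b; norm = 1
  expect_equal(mp$eccentricity, c(2, 1, 2))
  expect_equal(mp$clustering, rep(0, 3))

  # 5-node star, unit weights
  star <- graph_from_edges(5, rep(0, 4), 1:4, rep(1, 4))
  ms <- node_metrics(star)
  expect_equal(ms$degree, c(4, 1, 1, 1, 1))
  expect_equal(ms$global_efficiency[2], (1 + 3 * 0.5) / 4)  # = 0.625
  expect_equal(ms$betweenness[1], 1)  # hub carries all 6 leaf pairs
  expect_equal(ms$eccentricity, c(1, 2, 2, 2, 2))
})

test_that("all six metrics match the brute-force oracle on random graphs", {
  set.seed(22)
  for (r in 1:12) {
    n <- sample(4:8, 1)
    g <- random_subject_graph(n, runif(1, 0.3, 0.9))
    expect_lt(compare_metrics_to_oracle(g), 1e-10)
  }
})

test_that("metrics transform correctly under relabeling and weight scaling", {
  set.seed(23)
  g <- random_subject_graph(7, 0.6)
  W <- graph_weight_matrix(g)
  mt <- node_metrics(g)
  # node relabeling permutes the rows
  perm <- sample(7)
  Wp <- W[perm, perm]
  vp <- matrix_to_vec(ifelse(Wp == 0, -1, Wp))
  gp <- threshold_individual(
    connectivity_matrix(vec_to_matrix(vp, 7), "combined"),
    (nrow(g$edges) - 0.5) / n_edges(7))
  mtp <- node_metrics(gp)
  for (col in c("degree", "betweenness", "eccentricity", "global_efficiency",
                "local_efficiency", "clustering"))
    expect_equal(mtp[[col]], mt[[col]][perm], tolerance = 1e-10)
  # scaling weights by c > 0: degree/betweenness/clustering invariant,
  # eccentricity scales by 1/c, efficiencies by c
  cs <- 3.7
  vs <- matrix_to_vec(ifelse(W == 0, -1, cs * W))
  gs <- threshold_individual(
    connectivity_matrix(vec_to_matrix(vs, 7), "combined"),
    (nrow(g$edges) - 0.5) / n_edges(7))
  mts <- node_metrics(gs)
  expect_equal(mts$degree, mt$degree)
  expect_equal(mts$betweenness, mt$betweenness, tolerance = 1e-10)
  expect_equal(mts$clustering, mt$clustering, tolerance = 1e-10)
  expect_equal(mts$eccentricity, mt$eccentricity / cs, tolerance = 1e-10)
  expect_equal(mts$global_efficiency, mt$global_efficiency * cs,
               tolerance = 1e-10)
  expect_equal(mts$local_efficiency, mt$local_efficiency * cs,
               tolerance = 1e-10)
})

test_that("adding an edge never decreases degree or global efficiency", {
  set.seed(24)
  for (r in 1:5) {
    n <- 7
    v <- runif(n_edges(n), 0.2, 2)
    drop <- sample(n_edges(n), 8)
    v1 <- v; v1[drop] <- -1
    v2 <- v1; v2[drop[1]] <- v[drop[1]]   # one extra edge
    k1 <- sum(v1 > 0); k2 <- k1 + 1L
    g1 <- threshold_individual(connectivity_matrix(vec_to_matrix(v1, n),
                                                   "combined"),
                               (k1 - 0.5) / n_edges(n))
    g2 <- threshold_individual(connectivity_matrix(vec_to_matrix(v2, n),
                                                   "combined"),
                               (k2 - 0.5) / n_edges(n))
    m1 <- node_metrics(g1); m2 <- node_metrics(g2)
    expect_true(all(m2$degree >= m1$degree))
    expect_true(all(m2$global_efficiency >= m1$global_efficiency - 1e-12))
  }
})

test_that("feature tables pool the six metrics per subject", {
  set.seed(25)
  maps <- lapply(1:4, function(s) random_map(10, sprintf("sub-%d", s)))
  maps[[4]] <- connectivity_matrix(maps[[1]]$values, "normalized_z", "sub-4")
  ft <- feature_table(maps, 0.2)
  expect_equal(dim(ft), c(4, 60))
  expect_equal(unname(ft[4, ]), unname(ft[1, ]))  # identical maps, identical rows
  expect_equal(dim(metric_block(ft, "clustering")), c(4, 10))
  expect_identical(metric_block(ft, "pooled"), ft)
  # unthresholded mode differs but stays finite
  ftu <- suppressWarnings(feature_table(maps, mode = "unthresholded"))
  expect_true(all(is.finite(ftu)))
  expect_false(isTRUE(all.equal(ft, ftu, check.attributes = FALSE)))
  expect_error(metric_block(ft, "nope"), "unknown metric")
})
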