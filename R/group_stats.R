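# Vectorized Welch t across edge columns. X1, X2: subjects x edges.
# Sign convention: positive t means group 1 (case) > group 2 (control).
welch_t_cols <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X2^2) - n2 * m2^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df)
}

#' Rank-consensus valid-edge selection
#'
#' Ranks every connection within each participant's map (ties get average
#' ranks, normalized by edge count into (0, 1]), averages the rank maps
#' within each group, and marks an edge "valid" for a group when its mean
#' normalized rank exceeds `1 - fraction` (a rank of 0.8 for the default
#' top-20% fraction). The returned mask is the union of the two per-group
#' selections, so strong signal confined to one cohort is not discarded.
#'
#' @param cohort A [cohort_data].
#' @param fraction Top fraction of edges kept per group, in (0, 1);
#'   default 0.20.
#' @return List with `mask` (logical per edge), `group_mean_rank` (matrix,
#'   2 x edges, rows `case`/`control`) and `fraction`.
#' @export
rank_threshold <- function(cohort, fraction = 0.20) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!(fraction > 0 && fraction < 1))
    stop("rank_threshold: fraction must lie in (0, 1)")
  E <- ncol(cohort$edges)
  R <- t(apply(cohort$edges, 1L, function(v) rank(v, ties.method = "average"))) / E
  mr <- rbind(case    = colMeans(R[cohort$group == "case", , drop = FALSE]),
              control = colMeans(R[cohort$group == "control", , drop = FALSE]))
  sel <- mr > (1 - fraction)
  list(mask = sel["case", ] | sel["control", ],
       group_mean_rank = mr, fraction = fraction)
}

#' Welch t-tests at valid edges
#'
#' Per masked edge: Welch's unequal-variance t statistic, the
#' Welch-Satterthwaite degrees of freedom, and a two-sided p-value.
#' Positive t means case > control.
#'
#' @param cohort A [cohort_data].
#' @param mask Logical edge mask (e.g. from [rank_threshold()]); default all
#'   edges.
#' @return Data frame with one row per masked edge: `edge` (1-based index
#'   into [edge_pairs()] order), `i`, `j` (0-based nodes), `t`, `df`, `p`.
#'   Edges with zero variance in both groups get `NA` statistics and are
#'   flagged in the `degenerate` column.
#' @export
welch_edges <- function(cohort, mask = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.null(mask)) mask <- rep(TRUE, ncol(cohort$edges))
  idx <- which(mask)
  if (length(idx) == 0L) stop("welch_edges: empty edge mask")
  if (min(table(cohort$group)) < 2L)
    stop("welch_edges: need at least 2 subjects per group")
  X1 <- cohort$edges[cohort$group == "case", idx, drop = FALSE]
  X2 <- cohort$edges[cohort$group == "control", idx, drop = FALSE]
  w <- welch_t_cols(X1, X2)
  degen <- !is.finite(w$t)
  p <- 2 * stats::pt(-abs(w$t), w$df)
  ep <- edge_pairs(cohort$n_nodes)
  data.frame(edge = idx, i = ep[idx, 1L], j = ep[idx, 2L],
             t = ifelse(degen, NA_real_, w$t),
             df = ifelse(degen, NA_real_, w$df),
             p = ifelse(degen, NA_real_, p),
             degenerate = degen)
}

#' Omnibus max-statistic permutation correction
#'
#' Family-wise error control by randomization: group labels are reassigned
#' (preserving group sizes) `n_perm` times; the maximum of |Welch t| over
#' the valid edges is recorded per permutation; the omnibus threshold is the
#' empirical (1 - alpha) quantile of that null maximum distribution, and
#' edges whose observed |t| reaches it are flagged significant.
#'
#' @param cohort A [cohort_data].
#' @param mask Logical edge mask; must select at least one edge.
#' @param n_perm Number of label permutations (default 10000).
#' @param alpha Omnibus level (default 0.05).
#' @param seed Integer seed; results are deterministic given it.
#' @return List with `threshold`, `significant` (logical over masked edges),
#'   `edge` (masked edge indices), `t_obs`, `max_null` (the permutation
#'   distribution), `alpha`, `n_perm`.
#' @export
omnibus_permutation <- function(cohort, mask = NULL, n_perm = 10000L,
                                alpha = 0.05, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.null(mask)) mask <- rep(TRUE, ncol(cohort$edges))
  idx <- which(mask)
  if (length(idx) == 0L) stop("omnibus_permutation: empty edge mask")
  if (n_perm < 100L) warning("omnibus_permutation: n_perm < 100 is unreliable")
  X <- cohort$edges[, idx, drop = FALSE]
  is_case <- cohort$group == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case); ns <- n1 + n2
  if (min(n1, n2) < 2L) stop("omnibus_permutation: need >= 2 per group")
  t_obs <- welch_t_cols(X[is_case, , drop = FALSE],
                        X[!is_case, , drop = FALSE])$t
  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      lab <- logical(ns)
      lab[sample.int(ns, n1)] <- TRUE
      tt <- welch_t_cols(X[lab, , drop = FALSE], X[!lab, , drop = FALSE])$t
      max(abs(tt), na.rm = TRUE)
    }, numeric(1))
  })
  thr <- stats::quantile(max_null, 1 - alpha, type = 1, names = FALSE)
  list(threshold = thr, significant = abs(t_obs) >= thr, edge = idx,
       t_obs = t_obs, max_null = max_null, alpha = alpha, n_perm = n_perm)
}

# Shared half-cohort sign tabulation: FUN(half_case_idx, half_ctrl_idx)
# must return the per-edge statistic whose sign is tabulated, or NULL to
# reject a degenerate draw (e.g. a rank-deficient half-cohort design), in
# which case the half is redrawn.
tabulate_signs <- function(n_edge, n_iter, n1, n2, seed, FUN) {
  h1 <- n1 %/% 2L; h2 <- n2 %/% 2L
  pos <- neg <- numeric(n_edge)
  n_redrawn <- 0L
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      s <- NULL
      for (attempt in 1:100) {
        s <- FUN(sample.int(n1, h1), sample.int(n2, h2))
        if (!is.null(s)) break
        n_redrawn <- n_redrawn + 1L
      }
      if (is.null(s))
        stop("tabulate_signs: 100 consecutive degenerate half-cohort draws")
      pos <- pos + (s > 0)
      neg <- neg + (s < 0)
    }
  })
  if (n_redrawn > 0L)
    warning("tabulate_signs: ", n_redrawn,
            " degenerate half-cohort draw(s) redrawn")
  list(pos = pos / n_iter, neg = neg / n_iter)
}

#' Split-half sign-consistency robustness
#'
#' Per iteration, draws floor(n_g/2) subjects per group without replacement,
#' computes the case - control mean difference at each valid edge, and
#' records its sign. An edge is robust when one sign occurs in at least
#' `consistency` of the iterations; exact-zero differences count against
#' both signs.
#'
#' @param cohort A [cohort_data] with >= 4 subjects per group.
#' @param mask Logical edge mask.
#' @param n_iter Number of resampling iterations (default 10000).
#' @param consistency Required sign agreement fraction (default 0.95).
#' @param seed Integer seed.
#' @return Data frame per masked edge: `edge`, `consistency` (max of the
#'   positive/negative fractions), `sign` (+1/-1 of the dominant direction),
#'   `robust`.
#' @export
split_half_robustness <- function(cohort, mask = NULL, n_iter = 10000L,
                                  consistency = 0.95, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.null(mask)) mask <- rep(TRUE, ncol(cohort$edges))
  idx <- which(mask)
  if (length(idx) == 0L) stop("split_half_robustness: empty edge mask")
  Xc <- cohort$edges[cohort$group == "case", idx, drop = FALSE]
  Xk <- cohort$edges[cohort$group == "control", idx, drop = FALSE]
  if (min(nrow(Xc), nrow(Xk)) < 4L)
    stop("split_half_robustness: need >= 4 subjects per group")
  tab <- tabulate_signs(length(idx), n_iter, nrow(Xc), nrow(Xk), seed,
                        function(i1, i2)
                          colMeans(Xc[i1, , drop = FALSE]) -
                          colMeans(Xk[i2, , drop = FALSE]))
  frac <- pmax(tab$pos, tab$neg)
  data.frame(edge = idx, consistency = frac,
             sign = ifelse(tab$pos >= tab$neg, 1L, -1L),
             robust = frac >= consistency)
}

#' Covariate-adjusted regression robustness
#'
#' Ordinary least squares of each valid edge on an intercept, the group
#' indicator (case = 1) and three covariates (age, gender, ICV in raw voxel
#' units), fitted on random half-cohorts; the sign of the group slope is
#' tabulated across iterations and an edge is robust when one sign reaches
#' the `consistency` fraction.
#'
#' A collinear full-cohort design is an error (naming the offending
#' columns); a randomly drawn half-cohort whose design is rank-deficient
#' (e.g. a single-gender draw in a small cohort) is redrawn, with a warning
#' reporting how many draws were rejected.
#'
#' @param cohort A [cohort_data] with covariates.
#' @param mask Logical edge mask.
#' @param n_iter Number of split-half randomizations (default 1000).
#' @param consistency Required sign agreement (default 0.95).
#' @param seed Integer seed.
#' @return Data frame per masked edge: full-cohort slopes (`slope_group`,
#'   `slope_age`, `slope_gender`, `slope_icv`), `consistency`, `sign`,
#'   `robust`.
#' @export
covariate_regression_robustness <- function(cohort, mask = NULL,
                                            n_iter = 1000L,
                                            consistency = 0.95, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.null(cohort$covariates))
    stop("covariate_regression_robustness: cohort has no covariates")
  if (is.null(mask)) mask <- rep(TRUE, ncol(cohort$edges))
  idx <- which(mask)
  if (length(idx) == 0L) stop("covariate_regression_robustness: empty edge mask")
  X <- cohort$edges[, idx, drop = FALSE]
  D <- cbind(intercept = 1, group = as.numeric(cohort$group == "case"),
             age = cohort$covariates$age, gender = cohort$covariates$gender,
             icv = cohort$covariates$icv)
  check_rank <- function(Dm, where) {
    q <- qr(Dm)
    if (q$rank < ncol(Dm)) {
      bad <- colnames(Dm)[q$pivot[seq.int(q$rank + 1L, ncol(Dm))]]
      stop("covariate_regression_robustness: collinear design (", where,
           "); offending columns: ", paste(bad, collapse = ", "))
    }
    q
  }
  q_full <- check_rank(D, "full cohort")
  beta_full <- qr.coef(q_full, X)
  ic <- which(cohort$group == "case"); ik <- which(cohort$group == "control")
  tab <- tabulate_signs(length(idx), n_iter, length(ic), length(ik), seed,
    function(i1, i2) {
      rows <- c(ic[i1], ik[i2])
      Dh <- D[rows, , drop = FALSE]
      qh <- qr(Dh)
      # a random half can be degenerate (e.g. single-gender draw); reject
      # the draw rather than abort the whole tabulation
      if (qh$rank < ncol(Dh)) return(NULL)
      qr.coef(qh, X[rows, , drop = FALSE])["group", ]
    })
  frac <- pmax(tab$pos, tab$neg)
  data.frame(edge = idx,
             slope_group = beta_full["group", ],
             slope_age = beta_full["age", ],
             slope_gender = beta_full["gender", ],
             slope_icv = beta_full["icv", ],
             consistency = frac,
             sign = ifelse(tab$pos >= tab$neg, 1L, -1L),
             robust = frac >= consistency)
}

#' Post-hoc power of the two-sample t test
#'
#' Classical power analysis for a two-sided two-sample t test with equal
#' group sizes: noncentrality `d * sqrt(n/2)`, pooled degrees of freedom
#' `2n - 2`, power = P(|T'| > t_crit) under the noncentral t distribution.
#'
#' @param d Cohen's d (>= 0).
#' @param n_per_group Subjects per group (>= 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power as a probability in (0, 1).
#' @examples
#' ttest_power(0.8, 42)  # ~0.95
#' ttest_power(0.5, 42)  # ~0.62
#' @export
ttest_power <- function(d, n_per_group, alpha = 0.05) {
  stopifnot(d >= 0, n_per_group >= 2)
  if (!(alpha > 0 && alpha < 1)) stop("ttest_power: alpha must be in (0, 1)")
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}
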