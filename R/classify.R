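# Stratified fold assignment: within each class, a shuffled, as-even-as-
# possible split into n_folds; every fold's class proportions deviate from
# the global ones by at most one subject.
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds)
      stop("stratified_folds: class '", cl, "' has fewer subjects (",
           length(idx), ") than folds (", n_folds, ")")
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

# One CV repetition: returns per-subject predicted class (character).
cv_predict_once <- function(X, y, n_folds, cost = 1) {
  folds <- stratified_folds(y, n_folds)
  pred <- character(length(y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sg, `/`)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu), 2L, sg, `/`)
    fit <- e1071::svm(Xtr, factor(y[tr]), kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[!tr] <- as.character(stats::predict(fit, Xte))
  }
  pred
}

#' Repeated stratified cross-validated linear SVM
#'
#' Trains a linear support vector machine (cost 1) under `n_reps`
#' repetitions of stratified `n_folds`-fold cross-validation with a fresh
#' fold assignment per repetition. Features are standardized using
#' training-fold statistics only, so no test-set information leaks into
#' training. Accuracy, sensitivity (true positive rate for the case class)
#' and specificity are computed per repetition from the pooled test-fold
#' predictions and summarized as mean +/- SD; each subject's mean predicted
#' label is the fraction of repetitions in which it was predicted as a case.
#'
#' @param features Subject x feature numeric matrix.
#' @param labels Character/factor with exactly two classes.
#' @param n_folds Folds (default 5).
#' @param n_reps CV repetitions (default 100).
#' @param seed Integer seed; results are deterministic given it.
#' @param positive Label of the positive (case) class; default `"case"`.
#' @return An object of class `classifier_report`: per-repetition
#'   `accuracy`, `sensitivity`, `specificity` (proportions), their
#'   `*_mean_pct`/`*_sd_pct` summaries (%), `mean_predicted_label` per
#'   subject, and the run parameters.
#' @export
cross_validated_svm <- function(features, labels, n_folds = 5L,
                                n_reps = 100L, seed = 1L,
                                positive = "case") {
  X <- as.matrix(features)
  y <- as.character(labels)
  if (anyNA(X)) stop("cross_validated_svm: missing feature values")
  classes <- unique(y)
  if (length(classes) != 2L)
    stop("cross_validated_svm: need exactly 2 classes, got ",
         length(classes))
  if (!positive %in% classes)
    stop("cross_validated_svm: positive class '", positive, "' absent")
  if (min(table(y)) < n_folds)
    stop("cross_validated_svm: fewer subjects than folds in a class")
  acc <- sens <- spec <- numeric(n_reps)
  n_case_pred <- numeric(length(y))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      pred <- cv_predict_once(X, y, n_folds)
      acc[r] <- mean(pred == y)
      sens[r] <- mean(pred[y == positive] == positive)
      spec[r] <- mean(pred[y != positive] != positive)
      n_case_pred <- n_case_pred + (pred == positive)
    }
  })
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 acc_mean_pct = 100 * mean(acc), acc_sd_pct = 100 * stats::sd(acc),
                 sens_mean_pct = 100 * mean(sens), sens_sd_pct = 100 * stats::sd(sens),
                 spec_mean_pct = 100 * mean(spec), spec_sd_pct = 100 * stats::sd(spec),
                 mean_predicted_label = n_case_pred / n_reps,
                 subject = rownames(X), labels = y, positive = positive,
                 n_folds = n_folds, n_reps = n_reps, seed = seed,
                 p_perm = NA_real_, n_perm = NA_integer_),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> accuracy %.1f%% +/- %.1f, ",
                     "sensitivity %.1f%%, specificity %.1f%% ",
                     "(%d reps x %d folds)%s\n"),
              x$acc_mean_pct, x$acc_sd_pct, x$sens_mean_pct, x$spec_mean_pct,
              x$n_reps, x$n_folds,
              if (is.na(x$p_perm)) "" else sprintf(", perm p = %.4g", x$p_perm)))
  invisible(x)
}

#' Label-permutation p-value for classifier accuracy
#'
#' Shuffles the labels `n_perm` times, recomputes the mean cross-validated
#' accuracy for each shuffle (with a reduced repetition count per shuffle,
#' `perm_reps`, since the permutation distribution of a mean accuracy is
#' insensitive to the repetition count), and returns the one-tailed
#' +1-corrected p-value
#' `(1 + #\{perm accuracy >= observed\}) / (n_perm + 1)`.
#'
#' @param features Subject x feature matrix.
#' @param labels Two-class labels.
#' @param observed_accuracy Observed mean accuracy as a proportion (e.g.
#'   `mean(report$accuracy)`).
#' @param n_perm Number of label shuffles (default 5000).
#' @param n_folds,perm_reps CV parameters per shuffle (defaults 5 and 10).
#' @param seed Integer seed.
#' @param positive Positive class label.
#' @return One-tailed p-value in (0, 1].
#' @export
permutation_pvalue <- function(features, labels, observed_accuracy,
                               n_perm = 5000L, n_folds = 5L, perm_reps = 10L,
                               seed = 1L, positive = "case") {
  X <- as.matrix(features)
  y <- as.character(labels)
  if (n_perm < 100L) warning("permutation_pvalue: n_perm < 100 is unreliable")
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      yp <- sample(y)
      mean(vapply(seq_len(perm_reps), function(r)
        mean(cv_predict_once(X, yp, n_folds) == yp), numeric(1)))
    }, numeric(1))
  })
  (1 + sum(null_acc >= observed_accuracy)) / (n_perm + 1)
}

# Resolve a contrast "A_vs_B" against a manifest with columns group and
# (optionally) subgroup; A and B may be "case", "control" or subgroup labels.
contrast_subjects <- function(manifest, contrast) {
  parts <- strsplit(contrast, "_vs_", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("contrast must be of the form 'A_vs_B', got '", contrast, "'")
  member <- function(lab) {
    if (lab %in% c("case", "control")) return(manifest$group == lab)
    if (!"subgroup" %in% names(manifest) || !lab %in% manifest$subgroup)
      stop("contrast_subjects: undefined subgroup '", lab, "'")
    !is.na(manifest$subgroup) & manifest$subgroup == lab
  }
  a <- member(parts[1L]); b <- member(parts[2L])
  if (any(a & b)) stop("contrast_subjects: overlapping groups in '", contrast, "'")
  idx <- which(a | b)
  list(idx = idx,
       labels = ifelse(a[idx], "case", "control"),
       sides = parts)
}

#' Run classification over feature sets and group contrasts
#'
#' One [cross_validated_svm()] report (with permutation p-value) per
#' combination of feature set (the six nodal metrics and/or `"pooled"`) and
#' contrast. Contrasts are strings `"A_vs_B"` where the sides are
#' `"case"`, `"control"` or subgroup labels from the manifest's `subgroup`
#' column (e.g. `"del22q11_vs_control"`); the first side plays the positive
#' class.
#'
#' @param ft A [feature_table()] matrix for all subjects, rows aligned with
#'   `manifest`.
#' @param manifest Data frame with `subject_id`, `group` and optionally
#'   `subgroup`.
#' @param feature_sets Character vector of metric names and/or `"pooled"`.
#' @param contrasts Character vector of `"A_vs_B"` contrasts.
#' @param n_folds,n_reps CV parameters (defaults 5, 100).
#' @param n_perm,perm_reps Permutation-test parameters (defaults 5000, 10);
#'   set `n_perm = 0` to skip p-values.
#' @param seed Integer seed.
#' @return Named list of `classifier_report`s (`<feature_set>.<contrast>`),
#'   with a `summary` data frame attribute; see [summary.contrast_reports()].
#' @export
run_contrasts <- function(ft, manifest,
                          feature_sets = c(attr(ft, "metrics"), "pooled"),
                          contrasts = "case_vs_control",
                          n_folds = 5L, n_reps = 100L,
                          n_perm = 5000L, perm_reps = 10L, seed = 1L) {
  stopifnot(nrow(ft) == nrow(manifest))
  reports <- list()
  k <- 0L
  for (fs in feature_sets) {
    Xfs <- metric_block(ft, fs)
    for (ct in contrasts) {
      k <- k + 1L
      sel <- contrast_subjects(manifest, ct)
      X <- Xfs[sel$idx, , drop = FALSE]
      rep_seed <- (seed + 7L * k) %% 2147483647L
      rpt <- cross_validated_svm(X, sel$labels, n_folds, n_reps,
                                 seed = rep_seed)
      if (n_perm > 0)
        rpt$p_perm <- permutation_pvalue(X, sel$labels, mean(rpt$accuracy),
                                         n_perm, n_folds, perm_reps,
                                         seed = rep_seed + 1L)
      rpt$n_perm <- as.integer(n_perm)
      rpt$feature_set <- fs
      rpt$contrast <- ct
      reports[[paste(fs, ct, sep = ".")]] <- rpt
    }
  }
  class(reports) <- "contrast_reports"
  reports
}

#' Summarize a set of contrast reports
#'
#' @param object A [run_contrasts()] result.
#' @param ... Unused.
#' @return Data frame: feature_set, contrast, acc_mean, acc_sd, sens_mean,
#'   spec_mean (all %), p.
#' @export
summary.contrast_reports <- function(object, ...) {
  do.call(rbind, lapply(object, function(r)
    data.frame(feature_set = r$feature_set, contrast = r$contrast,
               acc_mean = r$acc_mean_pct, acc_sd = r$acc_sd_pct,
               sens_mean = r$sens_mean_pct, spec_mean = r$spec_mean_pct,
               p = r$p_perm, row.names = NULL)))
}
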