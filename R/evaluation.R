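# Monte-Carlo cross-validation of the decoding pipeline, confusion
# statistics, chance-level estimation and method comparison.

# deterministic child seed from a master seed and a stage name
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# stratified random train/test split; proportional per class with the
# remainder assigned round-robin across classes (in label order)
stratified_split <- function(labels, test_fraction) {
  classes <- sort(unique(labels))
  n <- length(labels)
  n_test <- round(n * test_fraction)
  if (n_test < 1) stop("stratified_split: test_fraction selects no trials")
  base <- vapply(classes, function(cl)
    floor(sum(labels == cl) * test_fraction), 0)
  rem <- n_test - sum(base)
  # remainder assigned round-robin over a randomly rotated class order so
  # no class is systematically favoured in small folds
  rr <- sample(length(classes))
  i <- 1L
  while (rem > 0) {
    cl <- rr[((i - 1L) %% length(classes)) + 1L]
    if (base[cl] < sum(labels == classes[cl]) - 1L) {
      base[cl] <- base[cl] + 1L
      rem <- rem - 1L
    }
    i <- i + 1L
    if (i > 10L * length(classes) * (n_test + 1L)) break
  }
  test <- integer(0)
  for (ci in seq_along(classes)) {
    rows <- which(labels == classes[ci])
    test <- c(test, sample(rows, base[ci]))
  }
  sort(test)
}

#' Percentage statistics of a confusion matrix
#'
#' Rows are true classes, columns predicted. Accuracy is the trace over
#' the total; for 2x2 matrices sensitivity and specificity are reported
#' with the first class as "positive" (sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP)).
#'
#' @param confusion square count matrix.
#' @return List with `accuracy`, and for 2x2 input `sensitivity` and
#'   `specificity`, all in percent.
#' @export
confusion_stats <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0))
    stop("confusion_stats: need a square non-negative count matrix")
  total <- sum(confusion)
  if (total == 0) stop("confusion_stats: empty confusion matrix")
  out <- list(accuracy = 100 * sum(diag(confusion)) / total)
  if (nrow(confusion) == 2) {
    out$sensitivity <- 100 * confusion[1, 1] / sum(confusion[1, ])
    out$specificity <- 100 * confusion[2, 2] / sum(confusion[2, ])
  }
  out
}

#' Monte-Carlo cross-validation of a decoding pipeline
#'
#' Repeats `n_reps` times: draw a stratified random train/test split
#' (default 90/10), rank features by Welch t-tests on the training trials
#' only (per class pair; multiclass runs take the union of per-pair top-n
#' sets), fit the classifier on the selected training features and
#' accumulate a confusion matrix on the test trials. With a vector of
#' subset sizes the selection sweep reuses one ranking per repetition
#' (subsets are nested) and an accuracy-vs-size curve is reported; the
#' headline accuracy is the curve maximum. The split sequence is a pure
#' function of the seed, label vector and test fraction, so runs with
#' different classifiers but one seed share identical splits.
#'
#' @param features a [feature_matrix] or plain `trial x feature` matrix.
#' @param labels class label per trial.
#' @param classifier `"lrbsf"` (default) or `"svm"`.
#' @param n_features subset size(s) to evaluate (default 50).
#' @param alpha significance screen for the ranking (default 0.05).
#' @param n_reps number of Monte-Carlo repetitions (default 100).
#' @param test_fraction held-out fraction per repetition (default 0.1).
#' @param seed integer seed governing all splits.
#' @param eta LRBSF decision threshold (default 1).
#' @param tune_eta if `TRUE`, [select_eta()] is run on the training
#'   log-LR scores each repetition (two-class LRBSF only).
#' @param svm_kernel,svm_cost soft-margin SVM parameters for the baseline.
#' @return An object of class `cv_report`.
#' @export
monte_carlo_cv <- function(features, labels,
                           classifier = c("lrbsf", "svm"),
                           n_features = 50, alpha = 0.05, n_reps = 100,
                           test_fraction = 0.1, seed = 1, eta = 1,
                           tune_eta = FALSE, svm_kernel = "linear",
                           svm_cost = 1) {
  classifier <- match.arg(classifier)
  X <- feature_values(features)
  n <- nrow(X)
  if (length(labels) != n)
    stop("monte_carlo_cv: 'labels' must have one entry per trial")
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("monte_carlo_cv: 'test_fraction' must lie in (0, 1)")
  classes <- sort(unique(labels))
  K <- length(classes)
  if (any(table(labels) < 2))
    stop("monte_carlo_cv: every class needs at least 2 trials")
  sizes <- sort(unique(as.integer(n_features)))
  pairs <- utils::combn(classes, 2, simplify = FALSE)

  set.seed(derive_seed(seed, "mc-splits"))
  splits <- lapply(seq_len(n_reps), function(r)
    stratified_split(labels, test_fraction))

  confusions <- lapply(sizes, function(s) vector("list", n_reps))
  rep_acc <- matrix(0, n_reps, length(sizes))
  n_test <- length(splits[[1]])
  correct <- lapply(sizes, function(s) matrix(NA, n_reps, n_test))
  selected_first <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    test <- splits[[r]]
    train <- setdiff(seq_len(n), test)
    ytr <- labels[train]; yte <- labels[test]
    Xtr <- X[train, , drop = FALSE]; Xte <- X[test, , drop = FALSE]
    if (K == 2) {
      rankings <- list(rank_features(Xtr, ytr, classes, alpha))
    } else {
      rankings <- lapply(pairs, function(pr)
        rank_features(Xtr, ytr, pr, alpha))
    }
    for (si in seq_along(sizes)) {
      idx <- if (K == 2) top_features(rankings[[1]], sizes[si])
             else union_top_features(rankings, sizes[si])
      if (si == 1L) selected_first[[r]] <- idx
      pred <- fit_and_predict(Xtr[, idx, drop = FALSE], ytr,
                              Xte[, idx, drop = FALSE], classifier,
                              eta, tune_eta, svm_kernel, svm_cost)
      cm <- table(factor(yte, levels = classes),
                  factor(pred, levels = classes))
      cm <- matrix(as.integer(cm), K, K,
                   dimnames = list(true = classes, predicted = classes))
      confusions[[si]][[r]] <- cm
      rep_acc[r, si] <- 100 * sum(diag(cm)) / sum(cm)
      correct[[si]][r, seq_along(pred)] <- pred == yte
    }
  }
  acc_by_size <- colMeans(rep_acc)
  best_i <- which.max(acc_by_size)
  pooled <- Reduce(`+`, confusions[[best_i]])
  stats <- confusion_stats(pooled)
  # cluster-robust SE: repetitions reuse test trials, so rep accuracies are
  # correlated; aggregate correctness per distinct trial first
  trial_id <- unlist(splits)
  corr_best <- as.vector(t(correct[[best_i]]))
  keep <- !is.na(corr_best)
  per_trial <- tapply(corr_best[keep], trial_id[keep], mean)
  cluster_se <- 100 * stats::sd(per_trial) / sqrt(length(per_trial))
  structure(list(
    classifier = classifier, classes = classes, sizes = sizes,
    accuracy_by_size = acc_by_size, rep_accuracy = rep_acc,
    confusions = confusions, test_indices = splits,
    n_repetitions = n_reps, test_fraction = test_fraction, seed = seed,
    headline_size = sizes[best_i],
    mean_accuracy = acc_by_size[best_i],
    se_accuracy = stats::sd(rep_acc[, best_i]) / sqrt(n_reps),
    cluster_se_accuracy = cluster_se,
    selected_first_size = selected_first,
    sensitivity = stats$sensitivity, specificity = stats$specificity,
    best = max(rep_acc[, best_i]), worst = min(rep_acc[, best_i])
  ), class = "cv_report")
}

fit_and_predict <- function(Xtr, ytr, Xte, classifier, eta, tune_eta,
                            svm_kernel, svm_cost) {
  if (classifier == "svm") {
    fit <- e1071::svm(Xtr, factor(ytr), kernel = svm_kernel,
                      cost = svm_cost, scale = FALSE)
    as.integer(as.character(stats::predict(fit, Xte)))
  } else {
    fit <- lrbsf(Xtr, ytr, eta = eta)
    if (tune_eta && length(fit$classes) == 2) {
      tr_scores <- predict(fit, Xtr, type = "loglr")
      fit$eta <- select_eta(tr_scores, ytr, m1 = fit$classes[2])
    }
    predict(fit, Xte)
  }
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "CVReport [%s]: %d reps, %d%% test, classes %s\n",
    x$classifier, x$n_repetitions, round(100 * x$test_fraction),
    paste(x$classes, collapse = "/")))
  cat(sprintf("  mean accuracy %.1f%% (se %.2f) at %d features",
              x$mean_accuracy, x$se_accuracy, x$headline_size))
  if (!is.null(x$sensitivity))
    cat(sprintf("; sensitivity %.1f%%, specificity %.1f%%",
                x$sensitivity, x$specificity))
  cat("\n")
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  print(object)
  if (length(object$sizes) > 1) {
    cat("  accuracy by subset size:\n")
    print(stats::setNames(round(object$accuracy_by_size, 2),
                          object$sizes))
  }
  invisible(object)
}

#' @export
plot.cv_report <- function(x, ...) {
  graphics::plot(x$sizes, x$accuracy_by_size, type = "b", pch = 16,
                 xlab = "number of selected features",
                 ylab = "mean accuracy (%)",
                 main = sprintf("MC-CV accuracy (%s)", x$classifier), ...)
  graphics::abline(h = 100 / length(x$classes), lty = 3)
  invisible(x)
}

#' Pairwise one-vs-one sweep over all class pairs
#'
#' Runs [monte_carlo_cv()] for every unordered class pair (`K(K-1)/2`
#' pairs; 10 for five classes) over the given subset sizes, and tabulates
#' mean accuracy, sensitivity, specificity and the best/worst repetition
#' per pair.
#'
#' @param features a [feature_matrix] or matrix.
#' @param labels class labels.
#' @param sizes subset sizes (default `subset_sizes()`).
#' @param ... passed to [monte_carlo_cv()].
#' @return An object of class `pairwise_sweep`: list with `reports` (one
#'   `cv_report` per pair) and `summary` (one row per pair).
#' @export
pairwise_sweep <- function(features, labels, sizes = subset_sizes(), ...) {
  X <- feature_values(features)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("pairwise_sweep: need at least 2 classes")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  reports <- list()
  rows <- list()
  for (pr in pairs) {
    sel <- labels %in% pr
    rep <- monte_carlo_cv(X[sel, , drop = FALSE], labels[sel],
                          n_features = sizes, ...)
    nm <- sprintf("%s.vs.%s", pr[1], pr[2])
    reports[[nm]] <- rep
    rows[[nm]] <- data.frame(
      pair = nm, accuracy = rep$mean_accuracy,
      sensitivity = rep$sensitivity, specificity = rep$specificity,
      best = rep$best, worst = rep$worst,
      n_features = rep$headline_size)
  }
  structure(list(reports = reports,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "pairwise_sweep")
}

#' @export
print.pairwise_sweep <- function(x, ...) {
  cat(sprintf("Pairwise sweep: %d class pairs\n", nrow(x$summary)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' One-vs-one soft-margin SVM baseline under the identical CV protocol
#'
#' Convenience wrapper for [monte_carlo_cv()] with `classifier = "svm"`;
#' with the same seed it uses exactly the same splits as the LRBSF run.
#'
#' @inheritParams monte_carlo_cv
#' @param ... passed to [monte_carlo_cv()].
#' @return A `cv_report`.
#' @export
svm_baseline <- function(features, labels, ...) {
  monte_carlo_cv(features, labels, classifier = "svm", ...)
}

#' Chance-level accuracy thresholds
#'
#' Upper bound of the null accuracy distribution for `n_samples` test
#' trials over `K` equiprobable classes: empirically, the `(1 - alpha)`
#' quantile of accuracy over `n_permutations` draws of uniform random
#' guesses against balanced true labels; analytically, the binomial
#' `(1 - alpha)` quantile `m/n` with the smallest `m` such that
#' `pbinom(m, n, 1/K) >= 1 - alpha`. At `n = 100`, `K = 2`,
#' `alpha = 0.05` the analytic threshold is 58%.
#'
#' An optional `refit` functional replaces the uniform-guess null with a
#' label-permutation null that re-runs a full classifier: it is called
#' once per permutation with a permuted label vector and must return the
#' achieved accuracy in percent.
#'
#' @param n_samples number of scored trials.
#' @param n_classes number of classes K (default 2).
#' @param alpha level (default 0.05).
#' @param n_permutations permutation draws (default 1000).
#' @param seed integer seed.
#' @param refit optional `function(permuted_labels) -> accuracy %`; when
#'   supplied, `labels` must be given too.
#' @param labels true labels, only used with `refit`.
#' @return An object of class `chance_level` with `empirical` and
#'   `analytic` thresholds in percent.
#' @export
permutation_chance <- function(n_samples, n_classes = 2, alpha = 0.05,
                               n_permutations = 1000, seed = 1,
                               refit = NULL, labels = NULL) {
  stopifnot(n_samples >= 1, n_classes >= 2)
  set.seed(derive_seed(seed, "chance"))
  if (is.null(refit)) {
    true <- rep(seq_len(n_classes), length.out = n_samples)
    accs <- vapply(seq_len(n_permutations), function(i)
      100 * mean(sample.int(n_classes, n_samples, replace = TRUE) == true),
      0)
  } else {
    if (is.null(labels)) stop("permutation_chance: 'refit' needs 'labels'")
    accs <- vapply(seq_len(n_permutations), function(i)
      refit(sample(labels)), 0)
  }
  k <- ceiling((1 - alpha) * n_permutations)
  empirical <- sort(accs)[k]
  analytic <- 100 * stats::qbinom(1 - alpha, n_samples, 1 / n_classes) /
    n_samples
  structure(list(n_samples = n_samples, n_classes = n_classes,
                 alpha = alpha, n_permutations = n_permutations,
                 empirical = empirical, analytic = analytic,
                 null_accuracies = accs),
            class = "chance_level")
}

#' @export
print.chance_level <- function(x, ...) {
  cat(sprintf(
    "Chance level (n=%d, K=%d, alpha=%g): empirical %.1f%%, analytic %.1f%% (pure %.1f%%)\n",
    x$n_samples, x$n_classes, x$alpha, x$empirical, x$analytic,
    100 / x$n_classes))
  invisible(x)
}

#' Compare per-condition accuracies of several methods
#'
#' Paired two-sided t-tests of a reference method against every other
#' method over aligned condition lists, plus a one-way ANOVA across all
#' methods simultaneously. A self-comparison (all differences zero) is
#' reported as t = 0, p = 1.
#'
#' @param acc numeric matrix or data frame, one row per condition, one
#'   column per method (named).
#' @param reference column (name or index) of the reference method
#'   (default 1).
#' @return List with `paired` (data frame: method, t, p) and `anova_p`.
#' @export
compare_methods <- function(acc, reference = 1) {
  acc <- as.matrix(acc)
  if (is.null(colnames(acc)))
    colnames(acc) <- sprintf("method_%d", seq_len(ncol(acc)))
  if (ncol(acc) < 2) stop("compare_methods: need at least 2 methods")
  if (any(!is.finite(acc)))
    stop("compare_methods: misaligned accuracy tables (non-finite values)")
  ref <- acc[, reference]
  others <- setdiff(seq_len(ncol(acc)),
                    if (is.character(reference))
                      match(reference, colnames(acc)) else reference)
  rows <- lapply(others, function(j) {
    d <- ref - acc[, j]
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) data.frame(method = colnames(acc)[j], t = 0, p = 1)
      else data.frame(method = colnames(acc)[j],
                      t = sign(mean(d)) * Inf, p = 0)
    } else {
      tt <- stats::t.test(ref, acc[, j], paired = TRUE)
      data.frame(method = colnames(acc)[j],
                 t = unname(tt$statistic), p = tt$p.value)
    }
  })
  long <- data.frame(value = as.vector(acc),
                     method = factor(rep(colnames(acc), each = nrow(acc))))
  an <- stats::anova(stats::aov(value ~ method, data = long))
  list(paired = do.call(rbind, rows), anova_p = an[["Pr(>F)"]][1])
}

#' Write a CV report to JSON and a Table-shaped TSV
#'
#' @param report a `cv_report` or `pairwise_sweep`.
#' @param path_json JSON output path.
#' @param path_tsv optional TSV path (pair, accuracy, sensitivity,
#'   specificity, best, worst) for `pairwise_sweep` input.
#' @export
write_cv_report <- function(report, path_json, path_tsv = NULL) {
  if (inherits(report, "pairwise_sweep")) {
    if (!is.null(path_tsv))
      utils::write.table(report$summary, path_tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    out <- list(
      summary = report$summary,
      reports = lapply(report$reports, cv_report_json))
  } else {
    out <- cv_report_json(report)
  }
  jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_json)
}

cv_report_json <- function(x) {
  list(classifier = x$classifier, classes = x$classes,
       n_repetitions = x$n_repetitions, test_fraction = x$test_fraction,
       seed = x$seed, sizes = x$sizes,
       accuracy_by_size = x$accuracy_by_size,
       mean_accuracy = x$mean_accuracy, se_accuracy = x$se_accuracy,
       sensitivity = x$sensitivity, specificity = x$specificity,
       best = x$best, worst = x$worst,
       confusions = lapply(x$confusions, function(sz)
         lapply(sz, function(cm) unname(as.matrix(cm)))))
}
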