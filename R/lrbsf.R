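# Likelihood-ratio-based score fusion: per-class, per-feature Gaussian
# kernel density estimates combined by summed log densities (class-
# conditional independence across the selected features), decided either
# pairwise against a likelihood-ratio threshold eta or multiclass by the
# maximum summed score.

DENSITY_FLOOR <- 1e-300

#' Fit a one-dimensional Gaussian kernel density estimate
#'
#' Silverman's rule-of-thumb bandwidth
#' `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)`. A degenerate training sample
#' (zero spread) falls back to a tiny bandwidth proportional to the value
#' scale so the density stays proper.
#'
#' @param values numeric training sample, length >= 2.
#' @param scale optional value scale used for the degenerate fallback
#'   bandwidth (`1e-6 * scale`); defaults to `max(|values|, 1)`.
#' @return An object of class `kde1d` with `x` (training values), `h`
#'   (bandwidth) and `n`.
#' @export
fit_kde <- function(values, scale = NULL) {
  if (length(values) < 2)
    stop("fit_kde: need at least 2 training values")
  h <- silverman_bw(values)
  if (!is.finite(h) || h <= 0) {
    if (is.null(scale) || !is.finite(scale) || scale <= 0)
      scale <- max(abs(values), 1)
    h <- 1e-6 * scale
  }
  structure(list(x = as.numeric(values), h = h, n = length(values)),
            class = "kde1d")
}

silverman_bw <- function(v) {
  s <- stats::sd(v)
  iqr <- stats::IQR(v)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  0.9 * spread * length(v)^(-1 / 5)
}

#' Evaluate a fitted kernel density
#'
#' Mean of Gaussian kernels centred at the training values, floored at
#' 1e-300 so that log densities stay finite everywhere.
#'
#' @param kde a `kde1d`.
#' @param x evaluation points.
#' @return Density values, same length as `x`.
#' @export
kde_density <- function(kde, x) {
  stopifnot(inherits(kde, "kde1d"))
  out <- vapply(x, function(xi) mean(stats::dnorm(xi, kde$x, kde$h)), 0)
  pmax(out, DENSITY_FLOOR)
}

# column-wise Silverman bandwidths (identical to silverman_bw per column,
# vectorised: type-7 quartiles read off one sorted pass)
col_silverman_bw <- function(train) {
  n <- nrow(train)
  m <- colMeans(train)
  s <- sqrt(pmax(colSums(train^2) - n * m^2, 0) / (n - 1))
  srt <- apply(train, 2, sort)
  q7 <- function(pr) {
    hq <- (n - 1) * pr + 1
    lo <- floor(hq)
    srt[lo, ] + (hq - lo) * (srt[pmin(lo + 1, n), ] - srt[lo, ])
  }
  iqr <- q7(0.75) - q7(0.25)
  spread <- ifelse(iqr > 0, pmin(s, iqr / 1.34), s)
  0.9 * spread * n^(-1 / 5)
}

# per-class density model over a fixed selected-feature set
class_density <- function(train, feature_ids, scales = NULL) {
  h <- col_silverman_bw(train)
  bad <- !is.finite(h) | h <= 0
  if (any(bad)) {
    sc <- if (!is.null(scales)) scales
          else pmax(apply(abs(train), 2, max), 1)
    sc[!is.finite(sc) | sc <= 0] <- 1
    h[bad] <- 1e-6 * sc[bad]
  }
  structure(list(train = train, h = h, feature_ids = feature_ids),
            class = "class_density")
}

# n_test x p matrix of log marginal densities under one class model
class_log_density <- function(model, X) {
  p <- ncol(model$train)
  out <- matrix(0, nrow(X), p)
  for (j in seq_len(p)) {
    tr <- model$train[, j]; h <- model$h[j]
    d <- rowMeans(stats::dnorm(outer(X[, j], tr, `-`) / h)) / h
    out[, j] <- log(pmax(d, DENSITY_FLOOR))
  }
  out
}

#' Fit the likelihood-ratio score-fusion classifier
#'
#' For every class and every (already selected) feature a Gaussian KDE is
#' fitted on the training trials of that class. A test vector is scored
#' per class by the sum of its log marginal densities,
#' \eqn{S_k = \sum_j \log \hat f_{k,j}(x_j)}, and classified pairwise by
#' the log likelihood ratio against `log(eta)` (two classes) or by the
#' maximum score (more classes).
#'
#' @param x numeric `trial x feature` matrix of selected features.
#' @param y class label per trial (integer or factor); every class needs
#'   at least 2 trials.
#' @param eta likelihood-ratio decision threshold (default 1, i.e. a
#'   log-threshold of 0). Only used for two-class prediction.
#' @param feature_ids optional identifiers of the feature columns (used to
#'   guard against scoring with a mismatched feature set).
#' @param alpha nominal test level, recorded for reference only; the
#'   threshold actually used is `eta`.
#' @return An object of class `lrbsf` with per-class `class_density`
#'   models, the class table and `eta`.
#' @seealso [predict.lrbsf()], [select_eta()]
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' fit <- lrbsf(x, rep(1:2, each = 20))
#' fit
#' predict(fit, x[c(1, 39), , drop = FALSE])
lrbsf <- function(x, y, eta = 1, feature_ids = NULL, alpha = 0.05) {
  x <- as.matrix(x)
  if (length(y) != nrow(x)) stop("lrbsf: 'y' must have one label per row")
  if (eta <= 0) stop("lrbsf: 'eta' must be > 0")
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("lrbsf: need at least 2 classes")
  if (is.null(feature_ids)) feature_ids <- seq_len(ncol(x))
  scales <- apply(x, 2, stats::sd)
  models <- lapply(classes, function(cl) {
    rows <- which(y == cl)
    if (length(rows) < 2)
      stop("lrbsf: class ", cl, " has fewer than 2 training trials")
    class_density(x[rows, , drop = FALSE], feature_ids, scales)
  })
  names(models) <- as.character(classes)
  structure(list(models = models, classes = classes, eta = eta,
                 alpha = alpha, feature_ids = feature_ids,
                 n_features = ncol(x), n_train = nrow(x)),
            class = "lrbsf")
}

#' @export
print.lrbsf <- function(x, ...) {
  cat(sprintf(
    "LRBSF model: %d classes, %d features, %d training trials, eta = %g\n",
    length(x$classes), x$n_features, x$n_train, x$eta))
  invisible(x)
}

#' @export
summary.lrbsf <- function(object, ...) {
  cat(sprintf("Likelihood-ratio score-fusion classifier\n"))
  cat(sprintf("  classes: %s\n", paste(object$classes, collapse = ", ")))
  cat(sprintf("  features: %d; training trials: %d; eta: %g\n",
              object$n_features, object$n_train, object$eta))
  bw <- t(vapply(object$models, function(m) range(m$h), numeric(2)))
  colnames(bw) <- c("min bandwidth", "max bandwidth")
  print(bw)
  invisible(object)
}

#' Per-class fused log-density scores
#'
#' `S_k = sum_j log f_hat_{k,j}(x_j)` for every class model, densities
#' floored at 1e-300. All models must share one selected-feature set.
#'
#' @param x test vector (or `trial x feature` matrix).
#' @param models list of `class_density` models (e.g. `fit$models`).
#' @return Numeric matrix `n_test x K` of scores (a vector input gives a
#'   1-row matrix).
#' @export
class_scores <- function(x, models) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  fid <- lapply(models, `[[`, "feature_ids")
  if (length(unique(fid)) != 1L)
    stop("class_scores: models were fitted on different feature sets")
  if (ncol(x) != ncol(models[[1]]$train))
    stop("class_scores: feature count mismatch (", ncol(x), " vs ",
         ncol(models[[1]]$train), ")")
  out <- matrix(0, nrow(x), length(models))
  colnames(out) <- names(models)
  for (k in seq_along(models))
    out[, k] <- rowSums(class_log_density(models[[k]], x))
  out
}

#' Log likelihood ratio between two class models
#'
#' `sum_j [log f_hat_1(x_j) - log f_hat_0(x_j)]` with floored densities;
#' always finite.
#'
#' @param x test vector or matrix.
#' @param model1 `class_density` of the alternative class (M1).
#' @param model0 `class_density` of the null class (M0).
#' @return Numeric vector of log likelihood ratios.
#' @export
loglr <- function(x, model1, model0) {
  s <- class_scores(x, list(m0 = model0, m1 = model1))
  unname(s[, "m1"] - s[, "m0"])
}

#' Pairwise likelihood-ratio decision rule
#'
#' @param eta likelihood-ratio threshold (> 0, default 1).
#' @param m1,m0 class ids returned for the alternative / null decision.
#' @param alpha nominal level, recorded but unused by thresholding.
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(eta = 1, m1 = 1L, m0 = 0L, alpha = 0.05) {
  if (eta <= 0) stop("decision_rule: 'eta' must be > 0")
  structure(list(eta = eta, m1 = m1, m0 = m0, alpha = alpha),
            class = "decision_rule")
}

#' Decide a two-class case from a log likelihood ratio
#'
#' Assigns M1 iff `loglr >= log(eta)` (the boundary goes to M1), else M0.
#'
#' @param loglr_value log likelihood ratio(s).
#' @param rule a [decision_rule].
#' @return Class id(s) (`rule$m1` or `rule$m0`).
#' @export
decide_pairwise <- function(loglr_value, rule = decision_rule()) {
  stopifnot(inherits(rule, "decision_rule"))
  ifelse(loglr_value >= log(rule$eta), rule$m1, rule$m0)
}

#' Decide a multiclass case from fused scores
#'
#' Argmax over the per-class scores; ties go to the smallest class index.
#'
#' @param scores numeric vector `S_1..S_K` (or matrix, one row per test
#'   trial).
#' @param classes optional class ids (default `1..K`).
#' @return Class id(s).
#' @export
decide_multiclass <- function(scores, classes = NULL) {
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  if (is.null(classes)) classes <- seq_len(ncol(scores))
  idx <- apply(scores, 1, which.max)   # which.max: first (smallest) on ties
  classes[idx]
}

#' Choose the decision threshold from training scores
#'
#' Maximises training accuracy over the finite candidate set of midpoints
#' between consecutive sorted distinct log-LR scores, plus the neutral
#' threshold `eta = 1`. Ties pick the candidate closest to 1; if all
#' scores coincide the neutral threshold is returned.
#'
#' @param scores training log likelihood ratios.
#' @param labels training labels.
#' @param m1 the class treated as the alternative M1 (scores at or above
#'   the threshold); default the larger label.
#' @return The selected `eta` (on the likelihood-ratio scale).
#' @export
select_eta <- function(scores, labels, m1 = NULL) {
  u <- sort(unique(scores))
  if (is.null(m1)) m1 <- max(labels)
  if (length(u) < 2) return(1)
  cand <- unique(c(0, (u[-1] + u[-length(u)]) / 2))
  acc <- vapply(cand, function(thr)
    mean((scores >= thr) == (labels == m1)), 0)
  best <- which(acc == max(acc))
  thr <- cand[best][which.min(abs(cand[best]))]
  exp(thr)
}

#' Predict classes (or scores) from a fitted LRBSF model
#'
#' Two-class models are decided by the pairwise likelihood-ratio rule with
#' the model's `eta` (M1 being the larger class label, so positive log-LR
#' favours it); models with three or more classes use the maximum-score
#' rule. At `eta = 1` the two coincide except on exact ties.
#'
#' @param object an [lrbsf] fit.
#' @param newdata `trial x feature` matrix over the model's feature set.
#' @param type `"class"` (default), `"scores"` (per-class fused
#'   log-densities) or `"loglr"` (two-class log likelihood ratio).
#' @param eta threshold override (default the fitted one).
#' @param ... unused.
#' @return Predicted class ids, a score matrix, or a log-LR vector.
#' @export
predict.lrbsf <- function(object, newdata,
                          type = c("class", "scores", "loglr"),
                          eta = object$eta, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  s <- class_scores(newdata, object$models)
  if (type == "scores") return(s)
  if (type == "loglr" || (type == "class" && length(object$classes) == 2)) {
    lr <- s[, 2] - s[, 1]      # columns follow sorted classes: M0, M1
    if (type == "loglr") return(unname(lr))
    rule <- decision_rule(eta, m1 = object$classes[2], m0 = object$classes[1])
    return(decide_pairwise(unname(lr), rule))
  }
  decide_multiclass(s, object$classes)
}

#' Serialize / restore a fitted LRBSF model as JSON
#'
#' Training values, bandwidths and feature ids are stored in full so
#' predictions replay exactly.
#'
#' @param fit an [lrbsf] model.
#' @param path file path.
#' @export
write_lrbsf <- function(fit, path) {
  stopifnot(inherits(fit, "lrbsf"))
  x <- list(classes = fit$classes, eta = fit$eta, alpha = fit$alpha,
            feature_ids = fit$feature_ids, n_features = fit$n_features,
            n_train = fit$n_train,
            models = lapply(fit$models, function(m)
              list(train = as.data.frame(m$train), h = m$h)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lrbsf
#' @export
read_lrbsf <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_ids <- x$feature_ids
  models <- lapply(x$models, function(m) {
    tr <- as.matrix(m$train); dimnames(tr) <- NULL
    structure(list(train = tr, h = as.numeric(m$h),
                   feature_ids = feature_ids),
              class = "class_density")
  })
  structure(list(models = models, classes = x$classes, eta = x$eta,
                 alpha = x$alpha, feature_ids = feature_ids,
                 n_features = x$n_features, n_train = x$n_train),
            class = "lrbsf")
}
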