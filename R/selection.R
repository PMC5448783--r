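#' Welch two-sample t statistic
#'
#' The unequal-variance two-sample statistic
#' \deqn{t = (\bar x_A - \bar x_B) / \sqrt{s_A^2/|A| + s_B^2/|B|}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' When both groups are constant and equal the statistic is defined as 0
#' with p = 1; a constant difference with zero pooled scale is flagged as
#' degenerate (infinite t, p = 0).
#'
#' @param x_a,x_b numeric sample vectors, each of length >= 2.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3, 4), c(5, 6, 7, 8))
welch_t <- function(x_a, x_b) {
  if (length(x_a) < 2 || length(x_b) < 2)
    stop("welch_t: both samples need at least 2 values")
  if (any(!is.finite(c(x_a, x_b))))
    stop("welch_t: non-finite values")
  r <- welch_t_cols(matrix(x_a, ncol = 1), matrix(x_b, ncol = 1))
  list(t = r$t[1], p = r$p[1], df = r$df[1], degenerate = r$degenerate[1])
}

# column-wise Welch test: XA, XB are trial x feature matrices
welch_t_cols <- function(XA, XB) {
  nA <- nrow(XA); nB <- nrow(XB)
  mA <- colMeans(XA); mB <- colMeans(XB)
  vA <- pmax(colSums(XA^2) - nA * mA^2, 0) / (nA - 1)
  vB <- pmax(colSums(XB^2) - nB * mB^2, 0) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t <- numeric(length(mA)); p <- numeric(length(mA))
  df <- rep(NA_real_, length(mA))
  zero <- se2 == 0
  eq <- zero & (mA == mB)
  deg <- zero & !eq
  t[eq] <- 0; p[eq] <- 1
  t[deg] <- sign(mA[deg] - mB[deg]) * Inf; p[deg] <- 0
  ok <- !zero
  t[ok] <- (mA[ok] - mB[ok]) / sqrt(se2[ok])
  df[ok] <- se2[ok]^2 /
    ((vA[ok] / nA)^2 / (nA - 1) + (vB[ok] / nB)^2 / (nB - 1))
  p[ok] <- 2 * stats::pt(-abs(t[ok]), df[ok])
  list(t = t, p = p, df = df, degenerate = deg)
}

#' Rank features by class-pair significance
#'
#' Computes a Welch t-test per feature between two classes, keeps features
#' significant at `alpha` (p < alpha) and ranks them by ascending p-value
#' (ties broken by descending |t|, then ascending feature index). Features
#' with p >= alpha are excluded from the ranking.
#'
#' @param features a [feature_matrix] or plain `trial x feature` matrix.
#' @param labels class label per trial.
#' @param class_pair length-2 vector naming the two classes to contrast;
#'   default the two smallest label values present.
#' @param alpha significance screen (default 0.05).
#' @return An object of class `selection_result` with `t_values`,
#'   `p_values`, `ranked_indices`, `alpha`, `class_pair`, `n_features`.
#' @export
rank_features <- function(features, labels, class_pair = NULL,
                          alpha = 0.05) {
  X <- feature_values(features)
  if (length(labels) != nrow(X))
    stop("rank_features: 'labels' must have one entry per trial")
  if (is.null(class_pair)) {
    cls <- sort(unique(labels))
    if (length(cls) < 2) stop("rank_features: need two classes")
    class_pair <- cls[1:2]
  }
  iA <- which(labels == class_pair[1]); iB <- which(labels == class_pair[2])
  if (length(iA) < 2 || length(iB) < 2)
    stop("rank_features: class absent or with fewer than 2 trials: ",
         paste(class_pair[c(length(iA) < 2, length(iB) < 2)], collapse = ", "))
  r <- welch_t_cols(X[iA, , drop = FALSE], X[iB, , drop = FALSE])
  keep <- which(r$p < alpha)
  ord <- keep[order(r$p[keep], -abs(r$t[keep]), keep)]
  structure(list(t_values = r$t, p_values = r$p,
                 ranked_indices = ord, alpha = alpha,
                 class_pair = class_pair, n_features = ncol(X)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "SelectionResult: classes %s vs %s; %d of %d features significant at alpha=%g\n",
    x$class_pair[1], x$class_pair[2], length(x$ranked_indices),
    x$n_features, x$alpha))
  invisible(x)
}

#' Top-n selected features
#'
#' The first `n` entries of the significance ranking (fewer if fewer
#' features passed the screen). When nothing passed the screen the single
#' smallest-p feature is returned so downstream models stay fittable.
#'
#' @param selection a `selection_result`.
#' @param n subset size.
#' @return Integer vector of feature column indices.
#' @export
top_features <- function(selection, n) {
  stopifnot(inherits(selection, "selection_result"))
  if (length(selection$ranked_indices) == 0L)
    return(which.min(selection$p_values))
  utils::head(selection$ranked_indices, n)
}

#' Nested subset sizes for the accuracy-vs-feature-count sweep
#'
#' An arithmetic sequence of subset sizes; the defaults (50 to 5000 in
#' steps of 50) give 100 levels.
#'
#' @param start first size (default 50).
#' @param stop last size (default 5000).
#' @param step increment (default 50).
#' @return Integer vector of sizes.
#' @export
subset_sizes <- function(start = 50, stop = 5000, step = 50) {
  stopifnot(start >= 1, step >= 1, stop >= start)
  as.integer(seq(start, stop, by = step))
}

# union of per-pair top-n rankings, for multiclass models
union_top_features <- function(rankings, n) {
  sort(unique(unlist(lapply(rankings, top_features, n = n))))
}

#' Write a selection result to TSV (+ JSON summary)
#'
#' One row per ranked feature: rank, feature index, t, p, and any
#' provenance columns available from the feature matrix.
#'
#' @param selection a `selection_result`.
#' @param path TSV output path; a `.json` summary is written alongside.
#' @param features optional [feature_matrix] supplying provenance columns.
#' @export
write_selection_tsv <- function(selection, path, features = NULL) {
  stopifnot(inherits(selection, "selection_result"))
  idx <- selection$ranked_indices
  tab <- data.frame(rank = seq_along(idx), feature = idx,
                    t = selection$t_values[idx],
                    p = selection$p_values[idx])
  if (inherits(features, "feature_matrix"))
    tab <- cbind(tab, features$provenance[idx, , drop = FALSE])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(alpha = selection$alpha,
         class_pair = selection$class_pair,
         n_features = selection$n_features,
         n_significant = length(idx)),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
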