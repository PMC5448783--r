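#' Specification of the 1-D convolutional feature bank
#'
#' Architecture of the single-layer convolutional feature extractor: `M`
#' random kernels of length `filter_len` slide over each channel row of an
#' epoch ("valid" positions only, no padding), a pointwise nonlinearity is
#' applied, and each feature map is down-sampled by non-overlapping pooling
#' windows of `pool_width` samples. With 250-sample rows, 130-sample
#' filters and width-11 pooling each of the 100 maps yields
#' `floor((250 - 130 + 1) / 11) = 11` values, i.e. 1100 features per
#' channel row.
#'
#' Kernels are random and fixed (drawn once from a centred Gaussian, never
#' trained); the extractor is a random projection feature bank, and its
#' output is identical for identical seeds.
#'
#' @param n_maps number of kernels / feature maps `M` (default 100).
#' @param filter_len kernel length in samples (default 130).
#' @param pool_width pooling window in samples (default 11).
#' @param activation `"sigmoid"` (default), `"tanh"`, or `"identity"` (a
#'   testing hook that bypasses the nonlinearity).
#' @param pooling `"mean"` (default) or `"max"`.
#' @param init_sd standard deviation of the kernel weights (default 0.1).
#' @param seed integer seed for the kernel draw.
#' @param weights optional `n_maps x filter_len` matrix of kernel weights;
#'   when supplied (e.g. replayed from JSON) no drawing happens.
#' @param biases optional length-`n_maps` bias vector (default zeros).
#' @return An object of class `convnet_spec`.
#' @export
convnet_spec <- function(n_maps = 100, filter_len = 130, pool_width = 11,
                         activation = c("sigmoid", "tanh", "identity"),
                         pooling = c("mean", "max"), init_sd = 0.1,
                         seed = 1, weights = NULL, biases = NULL) {
  activation <- match.arg(activation)
  pooling <- match.arg(pooling)
  stopifnot(n_maps >= 1, filter_len >= 1, pool_width >= 1, init_sd >= 0)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == c(n_maps, filter_len)))
      stop("convnet_spec: 'weights' must be n_maps x filter_len")
    if (is.null(biases)) biases <- numeric(n_maps)
    if (length(biases) != n_maps)
      stop("convnet_spec: 'biases' must have length n_maps")
  }
  structure(list(n_maps = as.integer(n_maps),
                 filter_len = as.integer(filter_len),
                 pool_width = as.integer(pool_width),
                 activation = activation, pooling = pooling,
                 init_sd = init_sd, seed = as.integer(seed),
                 weights = weights, biases = biases),
            class = "convnet_spec")
}

#' @export
print.convnet_spec <- function(x, ...) {
  cat(sprintf(
    "ConvNetSpec: %d maps, 1x%d filters, 1x%d %s pooling, %s activation%s\n",
    x$n_maps, x$filter_len, x$pool_width, x$pooling, x$activation,
    if (is.null(x$weights)) " (kernels not yet drawn)" else ""))
  invisible(x)
}

#' Draw the random kernels of a convolutional spec
#'
#' Fills `weights` with i.i.d. Gaussian(0, `init_sd`^2) draws and `biases`
#' with zeros, deterministically under the spec's seed. Re-initialising the
#' same spec reproduces identical kernels.
#'
#' @param spec a [convnet_spec].
#' @return The spec with `weights` and `biases` populated.
#' @export
init_filters <- function(spec) {
  stopifnot(inherits(spec, "convnet_spec"))
  set.seed(spec$seed)
  spec$weights <- matrix(stats::rnorm(spec$n_maps * spec$filter_len,
                                      sd = spec$init_sd),
                         spec$n_maps, spec$filter_len)
  spec$biases <- numeric(spec$n_maps)
  spec
}

#' Pointwise activation
#'
#' `sigmoid` is the classical logistic \eqn{1 / (1 + e^{-\sigma})}, with
#' values in (0, 1); `tanh` maps to (-1, 1); `identity` passes through.
#' All saturate gracefully at extreme arguments.
#'
#' @param x numeric vector/matrix.
#' @param activation activation name.
#' @return Transformed values, same shape as `x`.
#' @export
activate <- function(x, activation = c("sigmoid", "tanh", "identity")) {
  activation <- match.arg(activation)
  switch(activation,
         sigmoid = 1 / (1 + exp(-x)),
         tanh = tanh(x),
         identity = x)
}

#' Convolve one channel row with every kernel
#'
#' Valid (no-padding) sliding dot products: output position `p` of map `m`
#' is `activate(sum_j W[m, j] * row[p + j - 1] + b[m])`, a
#' cross-correlation (no kernel flip; with random symmetric-law kernels the
#' distinction is immaterial). Output length is
#' `L_out = length(row) - filter_len + 1`.
#'
#' @param row numeric vector of `N_s` samples.
#' @param spec an initialised [convnet_spec].
#' @return `n_maps x L_out` matrix of activated map values.
#' @export
conv_forward <- function(row, spec) {
  stopifnot(inherits(spec, "convnet_spec"))
  if (is.null(spec$weights))
    stop("conv_forward: kernels not initialised; call init_filters() first")
  fl <- spec$filter_len
  if (length(row) < fl)
    stop("conv_forward: row shorter than filter_len (", length(row),
         " < ", fl, ")")
  l_out <- length(row) - fl + 1L
  idx <- outer(seq_len(l_out) - 1L, seq_len(fl), `+`)   # L_out x fl
  windows <- matrix(row[idx], l_out, fl)
  raw <- windows %*% t(spec$weights)                    # L_out x M
  raw <- sweep(raw, 2, spec$biases, `+`)
  t(activate(raw, spec$activation))                     # M x L_out
}

#' Pool feature maps by non-overlapping windows
#'
#' Down-samples each map with consecutive windows of `pool_width` samples
#' (mean or max per window); trailing samples that do not fill a window
#' (`L_out %% pool_width`) are discarded.
#'
#' @param maps `n_maps x L_out` matrix (rows are maps).
#' @param pool_width window width in samples.
#' @param pooling `"mean"` or `"max"`.
#' @return `n_maps x floor(L_out / pool_width)` matrix.
#' @export
pool_maps <- function(maps, pool_width, pooling = c("mean", "max")) {
  pooling <- match.arg(pooling)
  if (!is.matrix(maps)) maps <- matrix(maps, nrow = 1)
  l_out <- ncol(maps)
  if (pool_width > l_out)
    stop("pool_maps: pool_width (", pool_width, ") exceeds map length (",
         l_out, ")")
  np <- l_out %/% pool_width
  kept <- maps[, seq_len(np * pool_width), drop = FALSE]
  if (pooling == "mean") {
    # block-mean via matrix product with a window-indicator matrix
    P <- matrix(0, np * pool_width, np)
    P[cbind(seq_len(np * pool_width),
            rep(seq_len(np), each = pool_width))] <- 1 / pool_width
    kept %*% P
  } else {
    arr <- array(t(kept), c(pool_width, np, nrow(maps)))
    t(apply(arr, c(2, 3), max))  # maps x np
  }
}

#' Extract convolutional features from every trial
#'
#' For every trial and every channel row: [conv_forward()] then
#' [pool_maps()], flattened map-major (map 1 positions 1..P, map 2, ...),
#' with channels concatenated in order. The same initialised spec (hence
#' the same kernels) is applied to every trial. Provenance records the
#' originating channel, map and pooled position of every feature.
#'
#' @param epochs an [epoch_set].
#' @param spec a [convnet_spec]; initialised automatically if its kernels
#'   have not been drawn yet.
#' @return A [feature_matrix] with `n_channels * n_maps * P` columns where
#'   `P = floor((N_s - filter_len + 1) / pool_width)`.
#' @export
#' @examples
#' es <- generate_epochs(synthetic_spec(n_classes = 2, images_per_class = 2,
#'                                      n_channels = 2, fs = 50, seed = 1))
#' fm <- extract_convnet_features(es, convnet_spec(n_maps = 3,
#'                                                 filter_len = 10,
#'                                                 pool_width = 5))
#' fm
extract_convnet_features <- function(epochs, spec = convnet_spec()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "convnet_spec"))
  if (is.null(spec$weights)) spec <- init_filters(spec)
  ns <- epochs$n_samples
  if (spec$filter_len > ns)
    stop("extract_convnet_features: incompatible geometry: N_s=", ns,
         ", filter_len=", spec$filter_len, ", pool_width=", spec$pool_width)
  l_out <- ns - spec$filter_len + 1L
  if (l_out < spec$pool_width)
    stop("extract_convnet_features: incompatible geometry: N_s=", ns,
         ", filter_len=", spec$filter_len, ", pool_width=", spec$pool_width)
  np <- l_out %/% spec$pool_width
  per_row <- spec$n_maps * np
  n_feat <- epochs$n_channels * per_row
  values <- matrix(0, epochs$n_trials, n_feat)
  idx <- outer(seq_len(l_out) - 1L, seq_len(spec$filter_len), `+`)
  tw <- t(spec$weights)
  pool_P <- NULL
  if (spec$pooling == "mean") {
    pool_P <- matrix(0, np * spec$pool_width, np)
    pool_P[cbind(seq_len(np * spec$pool_width),
                 rep(seq_len(np), each = spec$pool_width))] <- 1 / spec$pool_width
  }
  for (tr in seq_len(epochs$n_trials)) {
    for (ch in seq_len(epochs$n_channels)) {
      row <- epochs$data[tr, ch, ]
      windows <- matrix(row[idx], l_out, spec$filter_len)
      raw <- windows %*% tw
      raw <- sweep(raw, 2, spec$biases, `+`)
      act <- activate(raw, spec$activation)             # L_out x M
      pooled <- if (spec$pooling == "mean") {
        t(act[seq_len(np * spec$pool_width), , drop = FALSE]) %*%
          pool_P[seq_len(np * spec$pool_width), , drop = FALSE]  # M x np
      } else {
        pool_maps(t(act), spec$pool_width, "max")
      }
      # map-major flattening: map 1 positions 1..np, then map 2, ...
      values[tr, ((ch - 1) * per_row + 1):(ch * per_row)] <-
        as.vector(t(pooled))
    }
  }
  prov <- data.frame(
    channel = rep(seq_len(epochs$n_channels), each = per_row),
    map = rep(rep(seq_len(spec$n_maps), each = np), epochs$n_channels),
    position = rep(seq_len(np), spec$n_maps * epochs$n_channels))
  feature_matrix(values, prov, "convnet")
}

#' Flatten raw epoch samples into a feature matrix
#'
#' Baseline "raw" representation: each trial's `channel x sample` matrix is
#' flattened channel-major into one row (channel 1 samples 1..N_s, then
#' channel 2, ...).
#'
#' @param epochs an [epoch_set].
#' @return A [feature_matrix] with `n_channels * n_samples` columns and
#'   method tag `"raw"`.
#' @export
extract_raw_features <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- epochs$n_trials
  values <- matrix(0, n, epochs$n_channels * epochs$n_samples)
  for (tr in seq_len(n))
    values[tr, ] <- as.vector(t(epochs$data[tr, , ]))
  prov <- data.frame(
    channel = rep(seq_len(epochs$n_channels), each = epochs$n_samples),
    map = NA_integer_,
    position = rep(seq_len(epochs$n_samples), epochs$n_channels))
  feature_matrix(values, prov, "raw")
}

#' Serialize / restore a convolutional spec (including kernels) as JSON
#'
#' Weights are written in full so a run can be replayed exactly.
#'
#' @param spec a [convnet_spec].
#' @param path file path.
#' @export
write_convnet_spec <- function(spec, path) {
  stopifnot(inherits(spec, "convnet_spec"))
  x <- unclass(spec)
  if (!is.null(x$weights)) x$weights <- as.data.frame(x$weights)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_convnet_spec
#' @export
read_convnet_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- if (!is.null(x$weights)) as.matrix(x$weights) else NULL
  if (!is.null(w)) dimnames(w) <- NULL
  convnet_spec(x$n_maps, x$filter_len, x$pool_width, x$activation,
               x$pooling, x$init_sd, x$seed, weights = w,
               biases = if (is.null(x$biases)) NULL else as.numeric(x$biases))
}
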