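#' Labelled multichannel EEG epochs
#'
#' Container for a set of fixed-length EEG trials. Voltages are stored as a
#' 3-D array indexed `[trial, channel, sample]` in microvolts, together with
#' an integer class label and an image identifier per trial and the sampling
#' rate in Hz. All trials share the same channel and sample geometry.
#'
#' @param data 3-D numeric array `[trial, channel, sample]`, or a list of
#'   `channel x sample` matrices (one per trial) with identical dimensions.
#' @param labels integer class label per trial, values in `1..K`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param image_ids optional identifier per trial linking repeated
#'   presentations of the same stimulus; defaults to one id per trial.
#' @param channel_names optional character vector of channel labels.
#'
#' @return An object of class `epoch_set` with elements `data`, `labels`,
#'   `image_ids`, `fs`, `channel_names`, `n_trials`, `n_channels`,
#'   `n_samples`.
#' @export
#' @examples
#' es <- epoch_set(array(rnorm(4 * 2 * 10), c(4, 2, 10)),
#'                 labels = c(1, 1, 2, 2), fs = 10)
#' es
epoch_set <- function(data, labels, fs, image_ids = NULL,
                      channel_names = NULL) {
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L)
      stop("epoch_set: all trial matrices must share the same dimensions")
    arr <- array(0, c(length(data), dims[[1]][1], dims[[1]][2]))
    for (i in seq_along(data)) arr[i, , ] <- data[[i]]
    data <- arr
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("epoch_set: 'data' must be a trial x channel x sample array")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("epoch_set: 'fs' must be a positive scalar")
  n <- dim(data)[1]
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("epoch_set: 'labels' must have one entry per trial")
  if (any(is.na(labels)) || any(labels < 1L))
    stop("epoch_set: 'labels' must be positive integers in 1..K")
  if (is.null(image_ids)) image_ids <- seq_len(n)
  if (length(image_ids) != n)
    stop("epoch_set: 'image_ids' must have one entry per trial")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%03d", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2])
    stop("epoch_set: 'channel_names' length must equal the channel count")
  structure(list(
    data = data, labels = labels, image_ids = image_ids,
    fs = as.numeric(fs),
    channel_names = channel_names,
    n_trials = n, n_channels = dim(data)[2], n_samples = dim(data)[3]
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  k <- length(unique(x$labels))
  cat(sprintf(
    "EpochSet: %d trials x %d channels x %d samples @ %g Hz, %d class%s\n",
    x$n_trials, x$n_channels, x$n_samples, x$fs, k, if (k == 1) "" else "es"))
  tab <- table(x$labels)
  cat("  trials per class:", paste(sprintf("%s=%d", names(tab), tab),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Average repeated presentations of each image
#'
#' Collapses an epoch set to one trial per image by averaging, sample by
#' sample, all presentations sharing an `image_id`. The class label is
#' preserved (presentations of one image must agree on it). Every image must
#' have the same number of presentations.
#'
#' @param epochs an [epoch_set].
#' @return An [epoch_set] with one trial per distinct image id.
#' @export
average_presentations <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  ids <- epochs$image_ids
  counts <- table(ids)
  if (length(unique(as.integer(counts))) != 1L) {
    bad <- names(counts)[counts != as.integer(counts[1])]
    stop("average_presentations: unbalanced presentation counts for image ids: ",
         paste(bad, collapse = ", "))
  }
  # label consistency within image
  lab_by_id <- tapply(epochs$labels, ids, function(l) length(unique(l)))
  if (any(lab_by_id != 1L))
    stop("average_presentations: conflicting labels within an image id")
  uid <- unique(ids)
  flat <- matrix(epochs$data, nrow = epochs$n_trials)  # trial x (ch*sample)
  grp <- match(ids, uid)
  summed <- rowsum(flat, grp, reorder = TRUE)
  avg <- summed / as.integer(counts[1])
  out <- array(avg, c(length(uid), epochs$n_channels, epochs$n_samples))
  labels <- epochs$labels[match(uid, ids)]
  epoch_set(out, labels = labels, fs = epochs$fs, image_ids = uid,
            channel_names = epochs$channel_names)
}

#' Persist and restore epoch sets
#'
#' Epoch sets (and any other pipeline artifact) are stored in R's serialized
#' compressed array container via [saveRDS()]; the round-trip is lossless.
#'
#' @param epochs an [epoch_set].
#' @param path file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns the
#'   restored [epoch_set].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "epoch_set")) stop("read_epochs: not an epoch_set file")
  x
}

#' Trial-by-feature matrix with provenance
#'
#' Stores extracted features as a `trial x feature` numeric matrix alongside
#' per-feature provenance (which channel / map / position each column came
#' from) and a tag naming the extraction method.
#'
#' @param values numeric `trial x feature` matrix; all values must be finite.
#' @param provenance data frame with one row per feature.
#' @param method one of `"convnet"`, `"wavelet"`, `"raw"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, provenance, method = c("convnet", "wavelet", "raw")) {
  method <- match.arg(method)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("feature_matrix: non-finite feature values")
  if (nrow(provenance) != ncol(values))
    stop("feature_matrix: provenance must have one row per feature column")
  structure(list(values = values, provenance = provenance,
                 method_tag = method, n_features = ncol(values)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix [%s]: %d trials x %d features\n",
              x$method_tag, nrow(x$values), x$n_features))
  invisible(x)
}

#' Write a feature matrix (with provenance) to TSV
#'
#' The first columns carry the provenance, the remaining columns one trial
#' each (`trial_1 ... trial_n`, features as rows). `read_features_tsv`
#' restores the `feature_matrix` from that layout.
#'
#' @param fm a [feature_matrix].
#' @param path file path.
#' @export
write_features_tsv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  tab <- cbind(fm$provenance,
               as.data.frame(t(fm$values)))
  names(tab) <- c(names(fm$provenance),
                  sprintf("trial_%d", seq_len(nrow(fm$values))))
  utils::write.table(cbind(method = fm$method_tag, tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  method <- tab$method[1]
  trial_cols <- grep("^trial_", names(tab))
  prov <- tab[, setdiff(names(tab), c("method", names(tab)[trial_cols])),
              drop = FALSE]
  values <- t(as.matrix(tab[, trial_cols, drop = FALSE]))
  dimnames(values) <- NULL
  feature_matrix(values, prov, method)
}

# feature values as a plain matrix, accepting either representation
feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values
  else as.matrix(features)
}
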