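#' Specification of a synthetic evoked-response study
#'
#' Describes a balanced visual-category study to simulate: `n_classes`
#' stimulus categories, `images_per_class` distinct images each shown
#' `presentations_per_image` times, recorded over `n_channels` electrodes at
#' `fs` Hz in epochs of `epoch_len_s` seconds. Each class evokes a
#' Gaussian-windowed half-sine bump (an ERP-like monophasic deflection) on a
#' subset of channels, buried in a mixture of 1/f ("pink") and white noise.
#'
#' The defaults mirror a 5-category grayscale-image experiment: 52 images
#' per category presented twice, 1-s epochs at 250 Hz over 128 channels.
#'
#' @param n_classes number of stimulus categories (default 5).
#' @param images_per_class distinct images per category (default 52).
#' @param presentations_per_image repetitions of every image (default 2).
#' @param n_channels electrode count (default 128).
#' @param fs sampling rate in Hz (default 250).
#' @param epoch_len_s epoch duration in seconds (default 1); `fs *
#'   epoch_len_s` must be an integer.
#' @param evoked list with one entry per class, each a list with fields
#'   `amplitude` (peak, microvolts), `latency` (bump onset, seconds),
#'   `width` (bump duration, seconds) and `channels` (integer indices of
#'   affected channels). Defaults to [evoked_templates()].
#' @param noise_sd total noise standard deviation in microvolts (default 10).
#' @param pink_noise_fraction fraction of noise variance carried by the 1/f
#'   component, in `[0, 1]` (default 0.7).
#' @param seed integer seed; identical specs (including the seed) regenerate
#'   bit-identical data.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_epochs()]
#' @export
synthetic_spec <- function(n_classes = 5, images_per_class = 52,
                           presentations_per_image = 2, n_channels = 128,
                           fs = 250, epoch_len_s = 1,
                           evoked = NULL, noise_sd = 10,
                           pink_noise_fraction = 0.7, seed = 1) {
  for (fld in c("n_classes", "images_per_class", "presentations_per_image",
                "n_channels")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("synthetic_spec: '", fld, "' must be an integer >= 1")
  }
  if (!is.numeric(fs) || fs <= 0) stop("synthetic_spec: 'fs' must be > 0")
  n_samples <- fs * epoch_len_s
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("synthetic_spec: 'epoch_len_s' times 'fs' must be an integer")
  if (pink_noise_fraction < 0 || pink_noise_fraction > 1)
    stop("synthetic_spec: 'pink_noise_fraction' must lie in [0, 1]")
  if (noise_sd < 0) stop("synthetic_spec: 'noise_sd' must be >= 0")
  if (is.null(evoked))
    evoked <- evoked_templates(n_classes, n_channels)
  if (length(evoked) != n_classes)
    stop("synthetic_spec: 'evoked' must have one template per class")
  for (k in seq_along(evoked)) {
    tpl <- evoked[[k]]
    need <- c("amplitude", "latency", "width", "channels")
    if (!all(need %in% names(tpl)))
      stop("synthetic_spec: 'evoked' template ", k,
           " must have fields amplitude, latency, width, channels")
    if (any(tpl$channels < 1) || any(tpl$channels > n_channels))
      stop("synthetic_spec: 'evoked' template ", k,
           " has channel indices outside 1..n_channels")
  }
  structure(list(
    n_classes = as.integer(n_classes),
    images_per_class = as.integer(images_per_class),
    presentations_per_image = as.integer(presentations_per_image),
    n_channels = as.integer(n_channels), fs = as.numeric(fs),
    epoch_len_s = as.numeric(epoch_len_s),
    n_samples = as.integer(round(n_samples)),
    evoked = evoked, noise_sd = as.numeric(noise_sd),
    pink_noise_fraction = as.numeric(pink_noise_fraction),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Default class-dependent evoked templates
#'
#' One bump per class, identical shape but staggered latencies so that the
#' classes differ in their temporal activation pattern, on a shared
#' "posterior" channel block (one eighth of the montage).
#'
#' @param n_classes number of classes.
#' @param n_channels number of channels.
#' @param amplitude peak amplitude in microvolts (default 5).
#' @param latency0 latency of class 1's bump onset in seconds.
#' @param latency_step onset increment per class in seconds.
#' @param width bump duration in seconds.
#' @param channels affected channel indices; defaults to a contiguous block
#'   starting just past the middle of the montage.
#' @return List of per-class template descriptions.
#' @export
evoked_templates <- function(n_classes, n_channels, amplitude = 5,
                             latency0 = 0.1, latency_step = 0.05,
                             width = 0.08, channels = NULL) {
  if (is.null(channels)) {
    nb <- max(1L, round(n_channels / 8))
    start <- min(n_channels, floor(n_channels * 0.55) + 1L)
    channels <- seq(start, min(n_channels, start + nb - 1L))
  }
  lapply(seq_len(n_classes), function(k) {
    list(amplitude = amplitude,
         latency = latency0 + (k - 1) * latency_step,
         width = width, channels = as.integer(channels))
  })
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "SyntheticSpec: %d classes x %d images x %d presentations, %d ch @ %g Hz, %gs epochs\n",
    x$n_classes, x$images_per_class, x$presentations_per_image,
    x$n_channels, x$fs, x$epoch_len_s))
  cat(sprintf("  noise sd %g uV (pink fraction %g), seed %d\n",
              x$noise_sd, x$pink_noise_fraction, x$seed))
  invisible(x)
}

# Gaussian-windowed half-sine bump sampled on the epoch grid, peak-normalised
# so the maximum sample equals `amplitude` exactly.
evoked_waveform <- function(tpl, n_samples, fs) {
  t <- (seq_len(n_samples) - 1) / fs
  w <- numeric(n_samples)
  inside <- t >= tpl$latency & t <= tpl$latency + tpl$width
  if (!any(inside) || tpl$amplitude == 0) return(w)
  u <- (t[inside] - tpl$latency) / tpl$width          # in [0, 1]
  halfsine <- sin(pi * u)
  gauss <- exp(-0.5 * ((u - 0.5) / 0.25)^2)
  prof <- halfsine * gauss
  w[inside] <- tpl$amplitude * prof / max(prof)
  w
}

# 1/f-amplitude noise via spectral shaping: random phases, amplitude
# proportional to 1/sqrt(f), unit variance on output.
pink_noise <- function(n) {
  nf <- floor(n / 2)
  amp <- 1 / sqrt(seq_len(nf))
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(phase[nf]))  # Nyquist real
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

#' Generate labelled synthetic EEG epochs
#'
#' Simulates the study described by a [synthetic_spec]: for every class,
#' image and presentation, an epoch is built as the class's evoked bump on
#' its affected channels plus a per-channel mixture of 1/f and white noise.
#' Trials are ordered class-major (class 1 image 1 presentation 1, 2, image
#' 2, ..., class 2, ...), and image ids are assigned deterministically in
#' the same order. Output is bit-identical for identical specs.
#'
#' @param spec a [synthetic_spec].
#' @return An [epoch_set] with `n_classes * images_per_class *
#'   presentations_per_image` trials.
#' @export
#' @examples
#' es <- generate_epochs(synthetic_spec(n_classes = 2, images_per_class = 3,
#'                                      n_channels = 4, fs = 50, seed = 7))
#' es
generate_epochs <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop("generate_epochs: 'spec' must be a synthetic_spec")
  set.seed(spec$seed)
  K <- spec$n_classes; I <- spec$images_per_class
  P <- spec$presentations_per_image
  C <- spec$n_channels; S <- spec$n_samples
  n <- K * I * P
  waves <- lapply(spec$evoked, evoked_waveform, n_samples = S, fs = spec$fs)
  data <- array(0, c(n, C, S))
  labels <- integer(n); image_ids <- integer(n)
  pf <- spec$pink_noise_fraction
  tr <- 0L
  for (k in seq_len(K)) for (im in seq_len(I)) for (pr in seq_len(P)) {
    tr <- tr + 1L
    labels[tr] <- k
    image_ids[tr] <- (k - 1L) * I + im
    eps <- matrix(0, C, S)
    for (ch in seq_len(C)) {
      noise <- sqrt(1 - pf) * stats::rnorm(S)
      if (pf > 0) noise <- noise + sqrt(pf) * pink_noise(S)
      eps[ch, ] <- spec$noise_sd * noise
    }
    tpl <- spec$evoked[[k]]
    if (tpl$amplitude != 0)
      eps[tpl$channels, ] <- eps[tpl$channels, , drop = FALSE] +
        rep(waves[[k]], each = length(tpl$channels))
    data[tr, , ] <- eps
  }
  epoch_set(data, labels = labels, fs = spec$fs, image_ids = image_ids)
}

#' Serialize / restore a synthetic spec as JSON
#'
#' @param spec a [synthetic_spec].
#' @param path file path.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  evoked <- lapply(x$evoked, function(e)
    list(amplitude = e$amplitude, latency = e$latency, width = e$width,
         channels = as.integer(unlist(e$channels))))
  synthetic_spec(x$n_classes, x$images_per_class, x$presentations_per_image,
                 x$n_channels, x$fs, x$epoch_len_s, evoked, x$noise_sd,
                 x$pink_noise_fraction, x$seed)
}
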