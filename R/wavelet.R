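# Orthogonal discrete wavelet transform, implemented directly since the
# decomposition itself is a simple filter-bank cascade: analysis low/high
# pass filtering followed by dyadic decimation, repeated on the
# approximation. Supports zero-padding (default) and periodization
# boundary handling; both admit exact reconstruction and conserve energy
# for orthogonal filters.

# Daubechies analysis low-pass filters (orthonormal).
dwt_filters <- function(wavelet = c("db4", "db2", "haar")) {
  wavelet <- match.arg(wavelet)
  dec_lo <- switch(wavelet,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255126037, 0.2241438680420134,
            0.8365163037378079, 0.48296291314453416),
    db4 = c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965))
  L <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(L) - 1)   # quadrature mirror
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), len = L)
}

#' Maximum feasible decomposition depth
#'
#' @param n signal length.
#' @param wavelet wavelet name (`"db4"`, `"db2"`, `"haar"`).
#' @return Largest level such that the coarsest approximation still spans
#'   the filter, `floor(log2(n / (filter_len - 1)))`.
#' @export
dwt_max_level <- function(n, wavelet = "db4") {
  L <- dwt_filters(wavelet)$len
  if (n < L) return(0L)
  as.integer(floor(log2(n / (L - 1))))
}

# single analysis step: full convolution, then keep every second sample
# (offset 1 in 0-based full-convolution indices)
dwt_step <- function(x, filt, mode) {
  L <- length(filt$dec_lo)
  if (mode == "periodization") {
    if (length(x) %% 2 == 1) x <- c(x, x[length(x)])   # pad odd to even
    n <- length(x)
    ext <- c(x[(n - L + 1):n], x, x[1:L])              # periodic extension
    lo_full <- stats::convolve(ext, rev(filt$dec_lo), type = "open")
    hi_full <- stats::convolve(ext, rev(filt$dec_hi), type = "open")
    keep <- seq(L + 2, by = 2, length.out = n / 2)
    list(a = lo_full[keep], d = hi_full[keep])
  } else {                                             # zero padding
    lo_full <- stats::convolve(x, rev(filt$dec_lo), type = "open")
    hi_full <- stats::convolve(x, rev(filt$dec_hi), type = "open")
    keep <- seq(2, length(lo_full), by = 2)
    list(a = lo_full[keep], d = hi_full[keep])
  }
}

# single synthesis step inverting dwt_step; n = target length
idwt_step <- function(a, d, filt, mode, n) {
  L <- length(filt$rec_lo)
  up <- function(c) { u <- numeric(2 * length(c)); u[seq(2, 2 * length(c), 2)] <- c; u }
  if (mode == "periodization") {
    m <- 2 * length(a)
    ua <- up(a); ud <- up(d)
    ext <- function(u) c(u[(m - L + 1):m], u, u[1:L])
    y <- stats::convolve(ext(ua), rev(filt$rec_lo), type = "open") +
         stats::convolve(ext(ud), rev(filt$rec_hi), type = "open")
    # alignment mirrors the analysis offset
    out <- y[(2 * L):(2 * L + m - 1)]
    out[seq_len(n)]
  } else {
    ua <- up(a); ud <- up(d)
    y <- stats::convolve(ua, rev(filt$rec_lo), type = "open") +
         stats::convolve(ud, rev(filt$rec_hi), type = "open")
    out <- y[L:(length(y))]
    out[seq_len(n)]
  }
}

#' Multilevel discrete wavelet decomposition of a vector
#'
#' @param x numeric vector.
#' @param wavelet `"db4"` (default), `"db2"`, or `"haar"`.
#' @param n_levels decomposition depth; default the maximum feasible.
#' @param mode boundary handling, `"zero"` (default) or `"periodization"`.
#' @return List with `coeffs` (list: coarsest approximation first, then
#'   detail vectors coarse to fine), `lengths`, `wavelet`, `mode`, `n`
#'   (original length).
#' @export
wavedec <- function(x, wavelet = "db4", n_levels = NULL,
                    mode = c("zero", "periodization")) {
  mode <- match.arg(mode)
  filt <- dwt_filters(wavelet)
  maxlev <- dwt_max_level(length(x), wavelet)
  if (is.null(n_levels)) n_levels <- maxlev
  if (n_levels < 1 || n_levels > maxlev)
    stop("wavedec: infeasible decomposition depth ", n_levels,
         " for length ", length(x), " (maximum level is ", maxlev, ")")
  details <- vector("list", n_levels)
  lens <- integer(n_levels + 1)
  a <- x
  for (lev in seq_len(n_levels)) {
    lens[n_levels + 2 - lev] <- length(a)
    st <- dwt_step(a, filt, mode)
    a <- st$a
    details[[n_levels + 1 - lev]] <- st$d
  }
  lens[1] <- length(x)
  list(coeffs = c(list(a), details), wavelet = wavelet, mode = mode,
       n = length(x), level_input_lengths = lens)
}

#' Invert a multilevel wavelet decomposition
#'
#' @param dec output of [wavedec()].
#' @return The reconstructed signal (exact to floating point for the
#'   supported orthogonal wavelets).
#' @export
waverec <- function(dec) {
  filt <- dwt_filters(dec$wavelet)
  n_levels <- length(dec$coeffs) - 1L
  a <- dec$coeffs[[1]]
  for (lev in seq_len(n_levels)) {
    d <- dec$coeffs[[lev + 1]]
    target <- dec$level_input_lengths[lev + 1]
    if (length(a) > length(d)) a <- a[seq_along(d)]   # odd-length pad trim
    a <- idwt_step(a, d, filt, dec$mode, target)
  }
  a
}

#' Wavelet-coefficient features for every trial
#'
#' Baseline feature extractor: each channel row is decomposed with a
#' multilevel DWT and the full coefficient vector (coarsest approximation
#' followed by all detail levels, coarse to fine) is taken as features,
#' concatenated across channels. Provenance records channel, level (0 for
#' the approximation, then 1 = coarsest detail upward) and position.
#'
#' @param epochs an [epoch_set].
#' @param wavelet wavelet name (default `"db4"`).
#' @param n_levels decomposition depth; default the maximum feasible for
#'   the epoch length.
#' @param mode boundary handling (default `"zero"`).
#' @return A [feature_matrix] with method tag `"wavelet"`.
#' @export
extract_wavelet_features <- function(epochs, wavelet = "db4",
                                     n_levels = NULL, mode = "zero") {
  stopifnot(inherits(epochs, "epoch_set"))
  probe <- wavedec(epochs$data[1, 1, ], wavelet, n_levels, mode)
  lens <- lengths(probe$coeffs)
  per_row <- sum(lens)
  nlev <- length(probe$coeffs) - 1L
  values <- matrix(0, epochs$n_trials, epochs$n_channels * per_row)
  for (tr in seq_len(epochs$n_trials))
    for (ch in seq_len(epochs$n_channels)) {
      dec <- wavedec(epochs$data[tr, ch, ], wavelet, nlev, mode)
      values[tr, ((ch - 1) * per_row + 1):(ch * per_row)] <-
        unlist(dec$coeffs, use.names = FALSE)
    }
  prov <- data.frame(
    channel = rep(seq_len(epochs$n_channels), each = per_row),
    level = rep(rep(seq_along(lens) - 1L, lens), epochs$n_channels),
    position = rep(unlist(lapply(lens, seq_len)), epochs$n_channels))
  fm <- feature_matrix(values, prov, "wavelet")
  fm$wavelet <- wavelet
  fm$n_levels <- nlev
  fm
}
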