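# Independent brute-force oracles used to pin down the fast implementations.

# sliding-window dot products, explicit double loop (no matrix algebra)
conv_oracle <- function(row, weights, biases, act = identity) {
  M <- nrow(weights); fl <- ncol(weights)
  l_out <- length(row) - fl + 1
  out <- matrix(0, M, l_out)
  for (m in seq_len(M))
    for (p in seq_len(l_out)) {
      s <- 0
      for (j in seq_len(fl)) s <- s + weights[m, j] * row[p + j - 1]
      out[m, p] <- act(s + biases[m])
    }
  out
}

# sum over features of log mean-of-Gaussian-kernels, explicit loops
kde_score_oracle <- function(x, train, h) {
  total <- 0
  for (j in seq_along(x)) {
    dens <- 0
    for (k in seq_len(nrow(train)))
      dens <- dens + stats::dnorm(x[j], train[k, j], h[j])
    total <- total + log(max(dens / nrow(train), 1e-300))
  }
  total
}

# one analysis level of the Haar transform with zero extension, by hand
haar_cascade_step <- function(x) {
  h <- c(1, 1) / sqrt(2)
  g <- c(1, -1) / sqrt(2)
  xx <- c(x, 0)                 # zero extension for the trailing window
  n_out <- floor((length(x) + 1) / 2)
  a <- numeric(n_out); d <- numeric(n_out)
  for (i in seq_len(n_out)) {
    # windows (2i-1, 2i) in 1-based samples
    s1 <- xx[2 * i - 1]; s2 <- if (2 * i <= length(x)) xx[2 * i] else 0
    a[i] <- h[1] * s2 + h[2] * s1
    d[i] <- g[1] * s2 + g[2] * s1
  }
  list(a = a, d = d)
}

# Welch statistic straight from the textbook formula
welch_oracle <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  va <- stats::var(xa); vb <- stats::var(xb)
  se2 <- va / na + vb / nb
  t <- (mean(xa) - mean(xb)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# tiny epoch set with given per-trial channel x sample matrices
epochs_from_list <- function(mats, labels, fs = 10, image_ids = NULL) {
  epoch_set(mats, labels = labels, fs = fs, image_ids = image_ids)
}

# deterministic gaussian feature matrix with one shifted column
shifted_features <- function(n_per_class, n_feat, effect, sd = 1,
                             shift_col = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(2 * n_per_class * n_feat, sd = sd),
              2 * n_per_class, n_feat)
  y <- rep(1:2, each = n_per_class)
  X[y == 2, shift_col] <- X[y == 2, shift_col] + effect
  list(X = X, y = y)
}
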