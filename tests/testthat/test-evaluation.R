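test_that("confusion statistics compute the standard percentages", {
  perfect <- confusion_stats(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(perfect, list(accuracy = 100, sensitivity = 100,
                             specificity = 100))
  coin <- confusion_stats(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(coin, list(accuracy = 50, sensitivity = 50,
                          specificity = 50))
  mixed <- confusion_stats(matrix(c(8, 2, 4, 6), 2, byrow = TRUE))
  expect_equal(mixed, list(accuracy = 70, sensitivity = 80,
                           specificity = 60))
  multi <- confusion_stats(diag(3) * 4)
  expect_equal(multi$accuracy, 100)
  expect_null(multi$sensitivity)
  expect_error(confusion_stats(matrix(0, 2, 2)), "empty")
})

test_that("Monte-Carlo CV runs the protocol reproducibly", {
  d <- shifted_features(15, 10, effect = 10, seed = 61)
  cv <- monte_carlo_cv(d$X, d$y, n_features = 3, n_reps = 100, seed = 5)
  expect_length(cv$confusions[[1]], 100)
  expect_true(all(vapply(cv$confusions[[1]], sum, 0) ==
                    length(cv$test_indices[[1]])))
  expect_equal(cv$mean_accuracy, 100)      # a 10-sd effect is separable
  cv2 <- monte_carlo_cv(d$X, d$y, n_features = 3, n_reps = 100, seed = 5)
  expect_identical(cv, cv2)
  cv3 <- monte_carlo_cv(d$X, d$y, n_features = 3, n_reps = 10, seed = 6)
  expect_false(identical(cv$test_indices[1:10], cv3$test_indices))
  expect_error(monte_carlo_cv(d$X, d$y, test_fraction = 1.2), "test_fraction")
  expect_error(monte_carlo_cv(d$X, c(d$y[-1], 99)), "at least 2")
})

test_that("splits are stratified and pure functions of the seed", {
  y <- rep(1:2, each = 20)
  set.seed(eegdecode:::derive_seed(3, "mc-splits"))
  s1 <- eegdecode:::stratified_split(y, 0.1)
  expect_length(s1, 4)
  expect_equal(as.integer(table(y[s1])), c(2, 2))
  set.seed(eegdecode:::derive_seed(3, "mc-splits"))
  expect_identical(eegdecode:::stratified_split(y, 0.1), s1)
})

test_that("feature selection and densities never read the test fold", {
  d <- shifted_features(15, 30, effect = 1, seed = 62)
  cv <- monte_carlo_cv(d$X, d$y, n_features = 5, n_reps = 3, seed = 9)
  # corrupt the first repetition's test rows only
  X2 <- d$X
  X2[cv$test_indices[[1]], ] <- 1e6
  cv_mut <- monte_carlo_cv(X2, d$y, n_features = 5, n_reps = 3, seed = 9)
  expect_identical(cv_mut$selected_first_size[[1]],
                   cv$selected_first_size[[1]])
})

test_that("the pairwise sweep enumerates K(K-1)/2 class pairs with curves", {
  set.seed(63)
  X <- matrix(stats::rnorm(30 * 8), 30)
  y <- rep(1:5, each = 6)
  sw <- pairwise_sweep(X, y, sizes = c(2, 4), n_reps = 3, seed = 2)
  expect_length(sw$reports, 10)
  expect_equal(nrow(sw$summary), 10)
  expect_equal(length(sw$reports[[1]]$accuracy_by_size), 2)
  sw2 <- pairwise_sweep(X[y <= 2, ], y[y <= 2], sizes = 2, n_reps = 3,
                        seed = 2)
  expect_length(sw2$reports, 1)
})

test_that("chance thresholds: analytic binomial, empirical and asymptotics", {
  ch <- permutation_chance(100, 2, 0.05, 1000, seed = 1)
  expect_equal(ch$analytic, 58)
  expect_lte(abs(ch$empirical - ch$analytic), 1)
  expect_gte(ch$empirical, 50)
  # analytic threshold matches exhaustive pmf enumeration for small n
  for (n in c(7, 12, 20))
    for (K in c(2, 4)) {
      cdf <- cumsum(stats::dbinom(0:n, n, 1 / K))
      m <- min(which(cdf >= 0.95)) - 1
      expect_equal(permutation_chance(n, K, n_permutations = 10,
                                      seed = 2)$analytic, 100 * m / n)
    }
  # large n: threshold approaches pure chance
  expect_lt(abs(permutation_chance(1e5, 2, n_permutations = 10,
                                   seed = 3)$analytic - 50), 0.5)
  # refit hook drives the null with a caller-supplied functional
  ch_refit <- permutation_chance(10, 2, n_permutations = 50, seed = 4,
                                 refit = function(perm) 100 * mean(perm == 1),
                                 labels = rep(1:2, 5))
  expect_length(ch_refit$null_accuracies, 50)
})

test_that("method comparison reproduces paired t and ANOVA from first principles", {
  set.seed(64)
  base <- 70 + stats::rnorm(10, sd = 2)
  acc <- cbind(proposed = base + 5 + stats::rnorm(10, sd = 0.3),
               wavelet = base,
               raw = base - 3 + stats::rnorm(10, sd = 0.5))
  out <- compare_methods(acc, reference = "proposed")
  expect_true(all(out$paired$p < 0.05))
  # self comparison
  self <- compare_methods(cbind(a = base, b = base))
  expect_equal(self$paired$t, 0)
  expect_equal(self$paired$p, 1)
  # oracle: paired t from the difference vector
  d <- acc[, "proposed"] - acc[, "wavelet"]
  t_hand <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_hand), length(d) - 1)
  expect_lt(abs(out$paired$t[out$paired$method == "wavelet"] - t_hand), 1e-8)
  expect_lt(abs(out$paired$p[out$paired$method == "wavelet"] - p_hand), 1e-8)
  # oracle: one-way ANOVA from sums of squares
  gm <- mean(acc); k <- ncol(acc); n <- nrow(acc)
  ssb <- n * sum((colMeans(acc) - gm)^2)
  ssw <- sum(sweep(acc, 2, colMeans(acc))^2)
  f <- (ssb / (k - 1)) / (ssw / (k * n - k))
  p_anova <- stats::pf(f, k - 1, k * n - k, lower.tail = FALSE)
  expect_lt(abs(out$anova_p - p_anova), 1e-8)
  expect_error(compare_methods(cbind(a = c(base, NA), b = c(base, 1))),
               "misaligned")
})

test_that("the SVM baseline shares the split stream and behaves sanely", {
  d <- shifted_features(15, 10, effect = 4, seed = 65)
  sv <- svm_baseline(d$X, d$y, n_features = 3, n_reps = 20, seed = 7)
  lr <- monte_carlo_cv(d$X, d$y, n_features = 3, n_reps = 20, seed = 7)
  expect_identical(sv$test_indices, lr$test_indices)
  expect_gte(sv$mean_accuracy, 95)
  set.seed(66)
  Xn <- matrix(stats::rnorm(40 * 10), 40)
  yn <- rep(1:2, each = 20)
  svn <- svm_baseline(Xn, yn, n_features = 3, n_reps = 50, seed = 8)
  expect_lt(abs(svn$mean_accuracy - 50), 3 * svn$cluster_se_accuracy)
})

test_that("CV reports serialize to JSON and TSV", {
  d <- shifted_features(10, 6, effect = 3, seed = 67)
  cv <- monte_carlo_cv(d$X, d$y, n_features = 2, n_reps = 5, seed = 3)
  pj <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv, pj)
  parsed <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(parsed$mean_accuracy, cv$mean_accuracy)
  sw <- pairwise_sweep(d$X, d$y, sizes = 2, n_reps = 5, seed = 3)
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_cv_report(sw, pj, pt)
  tab <- utils::read.table(pt, header = TRUE, sep = "\t")
  expect_equal(names(tab)[1:4],
               c("pair", "accuracy", "sensitivity", "specificity"))
})
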