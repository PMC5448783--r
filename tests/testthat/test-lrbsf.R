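test_that("KDE fitting follows Silverman's rule and normalises", {
  set.seed(41)
  v <- stats::rnorm(50)
  k <- fit_kde(v)
  expect_equal(k$h,
               0.9 * min(stats::sd(v), stats::IQR(v) / 1.34) * 50^(-1 / 5))
  big <- fit_kde(stats::rnorm(2000))
  expect_lt(abs(kde_density(big, 0) - stats::dnorm(0)), 0.05)
  integral <- stats::integrate(function(x) kde_density(k, x), -10, 10)
  expect_lt(abs(integral$value - 1), 1e-3)
  expect_error(fit_kde(1), "at least 2")
})

test_that("degenerate training samples fall back to a proper density", {
  k <- fit_kde(rep(0, 10))
  expect_gt(k$h, 0)
  expect_gt(kde_density(k, 0), kde_density(k, 1))
  expect_true(is.finite(log(kde_density(k, 100))))
})

test_that("log likelihood ratios match a brute-force kernel-sum oracle", {
  set.seed(42)
  x <- rbind(matrix(stats::rnorm(6), 3, 2),
             matrix(stats::rnorm(6, 2), 3, 2))
  y <- rep(0:1, each = 3)
  fit <- lrbsf(x, y)
  # hand-set bandwidths to decouple from the bandwidth rule
  fit$models[[1]]$h <- c(0.5, 0.8)
  fit$models[[2]]$h <- c(0.6, 1.1)
  for (i in 1:5) {
    xt <- stats::rnorm(2, 1)
    got <- loglr(xt, fit$models[[2]], fit$models[[1]])
    want <- kde_score_oracle(xt, fit$models[[2]]$train,
                             fit$models[[2]]$h) -
            kde_score_oracle(xt, fit$models[[1]]$train,
                             fit$models[[1]]$h)
    expect_lt(abs(got - want), 1e-10)
  }
  # identical models give zero; swapping flips the sign exactly
  expect_equal(loglr(c(0, 0), fit$models[[1]], fit$models[[1]]), 0)
  expect_equal(loglr(c(0.3, -1), fit$models[[1]], fit$models[[2]]),
               -loglr(c(0.3, -1), fit$models[[2]], fit$models[[1]]))
})

test_that("multiclass scores match the oracle and reduce to the pairwise LR", {
  set.seed(43)
  x <- matrix(stats::rnorm(15), 15, 1)
  y <- rep(1:3, each = 5)
  fit <- lrbsf(x, y)
  xt <- matrix(c(0.2, -1), 2, 1)
  s <- class_scores(xt, fit$models)
  expect_equal(dim(s), c(2, 3))
  for (k in 1:3)
    for (i in 1:2)
      expect_lt(abs(s[i, k] -
                      kde_score_oracle(xt[i, ], fit$models[[k]]$train,
                                       fit$models[[k]]$h)), 1e-10)
  # K = 2: S1 - S0 is exactly the log likelihood ratio
  fit2 <- lrbsf(x[1:10, , drop = FALSE], y[1:10])
  s2 <- class_scores(xt, fit2$models)
  expect_equal(s2[, 2] - s2[, 1],
               loglr(xt, fit2$models[[2]], fit2$models[[1]]))
  # all models fitted on identical data score identically
  same <- lrbsf(rbind(x[1:5, , drop = FALSE], x[1:5, , drop = FALSE]),
                rep(1:2, each = 5))
  ss <- class_scores(xt, same$models)
  expect_equal(ss[, 1], ss[, 2])
  expect_error(class_scores(matrix(0, 1, 3), fit$models), "mismatch")
})

test_that("decision rules honour the threshold and tie conventions", {
  rule <- decision_rule(eta = 1, m1 = "M1", m0 = "M0")
  expect_equal(decide_pairwise(0, rule), "M1")      # boundary goes to M1
  expect_equal(decide_pairwise(-0.1, rule), "M0")
  expect_equal(decide_pairwise(0.5, decision_rule(eta = exp(1),
                                                  m1 = "M1", m0 = "M0")),
               "M0")
  expect_equal(decide_multiclass(c(-3, -1, -2)), 2)
  expect_equal(decide_multiclass(c(0, 0, 0)), 1)    # tie -> smallest id
  # pairwise and argmax agree at eta = 1 away from ties
  s <- c(-2.3, -1.1)
  expect_equal(decide_multiclass(s),
               decide_pairwise(s[2] - s[1], decision_rule(1, m1 = 2, m0 = 1)))
  expect_error(decision_rule(eta = 0), "eta")
})

test_that("threshold tuning separates separable scores and stays neutral otherwise", {
  scores <- c(-3, -2, -1, 1, 2, 3)
  labels <- rep(c(0, 1), each = 3)
  eta <- select_eta(scores, labels, m1 = 1)
  expect_equal(mean((scores >= log(eta)) == (labels == 1)), 1)
  expect_equal(select_eta(rep(0.7, 5), c(0, 1, 0, 1, 0)), 1)
  # optimisation bias shows up in training, not held-out, accuracy
  set.seed(44)
  held <- numeric(100)
  for (s in 1:100) {
    tr <- stats::rnorm(40); ytr <- rep(0:1, 20)
    eta_s <- select_eta(tr, ytr, m1 = 1)
    te <- stats::rnorm(40); yte <- rep(0:1, 20)
    held[s] <- mean((te >= log(eta_s)) == (yte == 1))
  }
  expect_lt(abs(mean(held) - 0.5), 3 * stats::sd(held) / 10)
})

test_that("a strongly informative feature yields near-perfect held-out decoding", {
  d <- shifted_features(100, 10, effect = 5, seed = 45)
  train <- c(1:50, 101:150); test <- c(51:100, 151:200)
  fit <- lrbsf(d$X[train, ], d$y[train])
  acc <- mean(predict(fit, d$X[test, ]) == d$y[test])
  expect_gte(acc, 0.95)
})

test_that("exchangeable classes decode at chance", {
  set.seed(46)
  accs <- numeric(100)
  for (s in 1:100) {
    X <- matrix(stats::rnorm(40 * 5), 40)
    y <- rep(1:2, each = 20)
    fit <- lrbsf(X[c(1:15, 21:35), ], y[c(1:15, 21:35)])
    accs[s] <- mean(predict(fit, X[c(16:20, 36:40), ]) ==
                      y[c(16:20, 36:40)])
  }
  expect_lt(abs(mean(accs) - 0.5), 3 * stats::sd(accs) / 10)
})

test_that("likelihood grows toward the alternative's training mass where the null is flat", {
  fit <- lrbsf(matrix(c(1, 1.1, 0.9, 30, 31, 32), 6, 1), rep(c(1, 0), each = 3))
  grid <- seq(-3, 1, 0.25)   # class-0 density is floored/flat out here
  lr <- vapply(grid, function(g)
    loglr(g, fit$models[["1"]], fit$models[["0"]]), 0)
  expect_true(all(diff(lr) >= 0))
})

test_that("fitted models replay exactly through JSON", {
  d <- shifted_features(10, 4, effect = 2, seed = 47)
  fit <- lrbsf(d$X, d$y, eta = 1.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_lrbsf(fit, path)
  fit2 <- read_lrbsf(path)
  xt <- matrix(stats::rnorm(12), 3, 4)
  expect_equal(predict(fit2, xt, type = "scores"),
               predict(fit, xt, type = "scores"), tolerance = 1e-12)
  expect_equal(fit2$eta, fit$eta)
})
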