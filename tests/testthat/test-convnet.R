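test_that("kernel initialisation is shaped and seeded as specified", {
  spec <- init_filters(convnet_spec(n_maps = 100, filter_len = 130,
                                    seed = 4))
  expect_equal(dim(spec$weights), c(100, 130))
  expect_equal(spec$biases, numeric(100))
  expect_identical(spec$weights,
                   init_filters(convnet_spec(n_maps = 100, filter_len = 130,
                                             seed = 4))$weights)
  zero <- init_filters(convnet_spec(n_maps = 3, filter_len = 5,
                                    init_sd = 0, seed = 1))
  out <- conv_forward(stats::rnorm(20), zero)
  expect_true(all(out == 0.5))  # g(0) everywhere
})

test_that("activations match their closed forms and ranges", {
  expect_equal(activate(0, "sigmoid"), 0.5)
  expect_lt(abs(activate(20, "sigmoid") - 1), 1e-8)
  expect_equal(activate(log(3), "sigmoid"), 0.75)
  x <- seq(-5, 5, 0.5)
  expect_true(all(activate(x, "sigmoid") > 0 & activate(x, "sigmoid") < 1))
  expect_true(all(abs(activate(x, "tanh")) < 1))
  expect_identical(activate(x, "identity"), x)
})

test_that("valid convolution matches the sliding-window oracle", {
  set.seed(21)
  for (case in 1:5) {
    row <- stats::rnorm(20)
    spec <- init_filters(convnet_spec(n_maps = 3, filter_len = 5,
                                      activation = "identity",
                                      seed = 100 + case))
    expect_lt(max(abs(conv_forward(row, spec) -
                        conv_oracle(row, spec$weights, spec$biases))),
              1e-12)
    sigm <- spec; sigm$activation <- "sigmoid"
    expect_lt(max(abs(conv_forward(row, sigm) -
                        conv_oracle(row, spec$weights, spec$biases,
                                    act = function(v) 1 / (1 + exp(-v))))),
              1e-12)
  }
  # output length and the delta-filter identity
  spec <- convnet_spec(n_maps = 1, filter_len = 130,
                       activation = "identity",
                       weights = matrix(c(1, rep(0, 129)), 1), biases = 0)
  row <- stats::rnorm(250)
  out <- conv_forward(row, spec)
  expect_equal(ncol(out), 121)
  expect_equal(as.vector(out), row[1:121])
  expect_error(conv_forward(stats::rnorm(100), spec), "shorter")
})

test_that("pooling averages or maximises non-overlapping blocks", {
  expect_equal(as.vector(pool_maps(c(1, 2, 3, 4), 2, "mean")), c(1.5, 3.5))
  expect_equal(as.vector(pool_maps(c(1, 2, 3, 4), 2, "max")), c(2, 4))
  m <- matrix(stats::rnorm(2 * 121), 2)
  expect_equal(ncol(pool_maps(m, 11)), 11)
  # trailing remainder discarded
  expect_equal(as.vector(pool_maps(1:10, 3, "mean")), c(2, 5, 8))
  expect_error(pool_maps(1:4, 7), "exceeds")
})

test_that("per-trial feature extraction has the documented geometry", {
  es <- generate_epochs(synthetic_spec(n_classes = 2, images_per_class = 2,
                                       presentations_per_image = 1,
                                       n_channels = 3, fs = 250, seed = 8))
  fm <- extract_convnet_features(es, convnet_spec(seed = 2))
  expect_equal(fm$n_features, 3 * 1100)
  expect_equal(nrow(fm$provenance), fm$n_features)
  expect_equal(max(fm$provenance$map), 100)
  expect_equal(max(fm$provenance$position), 11)
  expect_true(all(fm$values > 0 & fm$values < 1))  # sigmoid range

  # feature count formula over random geometries
  set.seed(31)
  for (g in 1:10) {
    ns <- sample(30:80, 1)
    fl <- sample(5:(ns - 5), 1)
    l_out <- ns - fl + 1
    pw <- sample(2:min(8, l_out), 1)
    M <- sample(1:4, 1)
    ch <- sample(1:3, 1)
    es_g <- epoch_set(array(stats::rnorm(2 * ch * ns), c(2, ch, ns)),
                      labels = c(1, 2), fs = ns)
    fm_g <- extract_convnet_features(
      es_g, convnet_spec(n_maps = M, filter_len = fl, pool_width = pw,
                         seed = g))
    expect_equal(fm_g$n_features, ch * M * (l_out %/% pw))
  }
  expect_error(
    extract_convnet_features(es, convnet_spec(filter_len = 260)),
    "geometry")
})

test_that("map-major flattening composes conv and pooling as documented", {
  # delta filter + identity activation + full-width mean pool = mean of the
  # first L_out samples
  ns <- 30; fl <- 11; l_out <- ns - fl + 1
  spec <- convnet_spec(n_maps = 1, filter_len = fl, pool_width = l_out,
                       activation = "identity",
                       weights = matrix(c(1, rep(0, fl - 1)), 1), biases = 0)
  row <- stats::rnorm(ns)
  es <- epoch_set(array(rep(row, each = 2), c(2, 1, ns)),
                  labels = c(1, 2), fs = ns)
  fm <- extract_convnet_features(es, spec)
  expect_equal(fm$n_features, 1)
  expect_equal(fm$values[1, 1], mean(row[1:l_out]))
})

test_that("trials are processed independently (row permutation property)", {
  es <- generate_epochs(synthetic_spec(n_classes = 2, images_per_class = 3,
                                       presentations_per_image = 1,
                                       n_channels = 2, fs = 50, seed = 12))
  spec <- convnet_spec(n_maps = 2, filter_len = 10, pool_width = 5,
                       seed = 3)
  fm <- extract_convnet_features(es, spec)
  perm <- c(4, 1, 6, 2, 3, 5)
  es_p <- epoch_set(es$data[perm, , , drop = FALSE], es$labels[perm],
                    es$fs, es$image_ids[perm])
  fm_p <- extract_convnet_features(es_p, spec)
  expect_equal(fm_p$values, fm$values[perm, ])
})

test_that("tanh mode stays in (-1,1) and specs replay from JSON", {
  es <- generate_epochs(synthetic_spec(n_classes = 2, images_per_class = 2,
                                       presentations_per_image = 1,
                                       n_channels = 1, fs = 50, seed = 5))
  spec <- init_filters(convnet_spec(n_maps = 2, filter_len = 10,
                                    pool_width = 5, activation = "tanh",
                                    seed = 6))
  fm <- extract_convnet_features(es, spec)
  expect_true(all(abs(fm$values) < 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_convnet_spec(spec, path)
  spec2 <- read_convnet_spec(path)
  expect_equal(spec2$weights, spec$weights, tolerance = 1e-12)
  expect_equal(extract_convnet_features(es, spec2)$values, fm$values)
})
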