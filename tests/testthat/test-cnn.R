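test_that("convolution feature maps have length num - m + 1", {
  X <- matrix(rnorm(5 * 3), 5, 3)
  k3 <- conv_kernel(matrix(rnorm(9), 3, 3))
  expect_length(conv_feature(X, k3), 3)
  k1 <- conv_kernel(matrix(rnorm(3), 1, 3))
  expect_length(conv_feature(X, k1), 5)
  expect_error(conv_feature(X[1:2, ], k3), "too short")
})

test_that("convolution matches a hand-computed oracle", {
  # 4x1 matrix [1,2,3,4], kernel [1,1], b = 0, identity: sliding sums
  X <- matrix(1:4, 4, 1)
  expect_equal(conv_feature(X, conv_kernel(matrix(1, 2, 1)), "identity"),
               c(3, 5, 7))
  # zero input with zero bias stays zero under ReLU
  Z <- matrix(0, 6, 2)
  kz <- conv_kernel(matrix(rnorm(4), 2, 2), bias = 0)
  expect_equal(conv_feature(Z, kz, "relu"), numeric(5))
  # bias and ReLU clipping
  kb <- conv_kernel(matrix(0, 2, 1), bias = -1)
  expect_equal(conv_feature(X, kb, "relu"), numeric(3))
  expect_equal(conv_feature(X, kb, "identity"), rep(-1, 3))
})

test_that("1-max pooling returns the maximum and rejects empty maps", {
  expect_identical(max_pool(c(3, 5, 7)), 7)
  expect_identical(max_pool(c(-1, -2)), -1)
  expect_identical(max_pool(rep(2.5, 4)), 2.5)
  expect_error(max_pool(numeric(0)), "empty")
})

test_that("forward pass is a calibrated probability", {
  model <- cnn_model(3, windows = c(2, 3), seed = 1)
  X <- matrix(rnorm(18), 6, 3)
  # all-zero fc weights: softmax of equal scores is exactly 1/2
  model0 <- model
  model0$fc_W[] <- 0
  model0$fc_b[] <- 0
  expect_identical(cnn_forward(X, model0), 0.5)
  # evaluation mode is deterministic
  expect_identical(cnn_forward(X, model), cnn_forward(X, model))
  eta <- cnn_forward(X, model)
  expect_gte(eta, 0)
  expect_lte(eta, 1)
  expect_error(cnn_forward(matrix(0, 6, 2), model), "columns")
})

test_that("pooled feature length equals kernel count for any document length", {
  model <- cnn_model(4, windows = c(2, 3), kernels_per_window = 2, seed = 5)
  for (num in c(3, 7, 20)) {
    X <- matrix(rnorm(num * 4), num, 4)
    cache <- nsclcstager:::cnn_forward_cache(X, model)
    expect_length(cache$z, 4)   # 2 windows x 2 kernels each
  }
})

test_that("the classifier is sensitive to token order", {
  model <- cnn_model(3, windows = c(2, 3), seed = 2)
  set.seed(42)
  X <- matrix(rnorm(24), 8, 3)
  etas <- vapply(1:5, function(i) {
    cnn_forward(X[sample(nrow(X)), ], model)
  }, numeric(1))
  expect_gt(diff(range(c(cnn_forward(X, model), etas))), 0)
})

test_that("backpropagated gradients match finite differences", {
  model <- cnn_model(4, windows = c(2, 3), dropout_rate = 0, seed = 2)
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4)
  for (y in c(0L, 1L)) {
    g <- nsclcstager:::cnn_gradients(X, y, model)
    loss_of <- function(m) {
      eta <- cnn_forward(X, m)
      -log(if (y == 1) eta else 1 - eta)
    }
    check <- function(get, set, analytic, eps = 1e-6) {
      m1 <- set(model, get(model) + eps)
      m2 <- set(model, get(model) - eps)
      numeric_grad <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      expect_lt(abs(numeric_grad - analytic) /
                  max(abs(numeric_grad), 1e-8), 1e-4)
    }
    check(function(m) m$kernels[[1]]$W[1, 2],
          function(m, v) { m$kernels[[1]]$W[1, 2] <- v; m },
          g$kernels[[1]]$dW[1, 2])
    check(function(m) m$kernels[[2]]$b,
          function(m, v) { m$kernels[[2]]$b <- v; m },
          g$kernels[[2]]$db)
    check(function(m) m$fc_W[2, 1],
          function(m, v) { m$fc_W[2, 1] <- v; m },
          g$fc_W[2, 1])
    check(function(m) m$fc_b[1],
          function(m, v) { m$fc_b[1] <- v; m },
          g$fc_b[1])
  }
})

test_that("training reduces loss, separates a separable set, and is seeded", {
  ds <- make_separable_docs(seed = 1)
  model <- cnn_model(4, windows = c(2, 3), lr = 0.2, batch_size = 4,
                     dropout_rate = 0.2, seed = 3)
  expect_identical(cnn_train(model, ds, epochs = 0), model)  # 0 epochs: identity
  expect_error(cnn_train(model, list(), epochs = 1), "empty")
  initial_loss <- cnn_loss(model, ds)
  trained <- cnn_train(model, ds, epochs = 120, seed = 4)
  expect_lt(cnn_loss(trained, ds), initial_loss)
  eta <- cnn_predict(trained, lapply(ds, `[[`, "x"))
  truth <- vapply(ds, `[[`, integer(1), "y")
  expect_equal(mean((eta >= 0.5) == truth), 1.0)
  expect_identical(trained, cnn_train(model, ds, epochs = 120, seed = 4))
})

test_that("tanh activation is selectable and trains", {
  ds <- make_separable_docs(seed = 2)
  model <- cnn_model(4, windows = c(2, 3), activation = "tanh", lr = 0.2,
                     batch_size = 4, dropout_rate = 0, seed = 6)
  trained <- cnn_train(model, ds, epochs = 40, seed = 6)
  expect_lt(cnn_loss(trained, ds), cnn_loss(model, ds))
  expect_error(cnn_model(4, activation = "swish"), "unknown activation")
})

test_that("checkpoints round-trip through the JSON archive", {
  ds <- make_separable_docs(seed = 3)
  model <- cnn_train(cnn_model(4, windows = c(2, 3), seed = 8), ds,
                     epochs = 5, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_cnn_checkpoint(model, path)
  back <- read_cnn_checkpoint(path)
  xs <- lapply(ds, `[[`, "x")
  expect_equal(cnn_predict(back, xs), cnn_predict(model, xs),
               tolerance = 1e-12)
  expect_identical(back$activation, model$activation)
  expect_equal(back$fc_W, model$fc_W, tolerance = 1e-12)
})
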