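test_that("transfer functions match their definitions", {
  expect_equal(transfer("tansig", 0), 0)
  expect_equal(transfer("tansig", 1.2), tanh(1.2))
  expect_equal(transfer("purelin", 3.7), 3.7)
  expect_equal(transfer("satlins", c(2.5, -0.3, -4)), c(1, -0.3, -1))
  expect_equal(transfer("logsig", 0), 0.5)
  expect_equal(transfer("hardlims", c(-0.01, 0, 0.01)), c(-1, 1, 1))
  expect_identical(sort(transfer_names()),
                   sort(c("hardlims", "satlins", "purelin", "logsig", "tansig")))
  expect_error(transfer("relu", 1), class = "registry_error")
})

test_that("forward pass equals an independent naive-loop implementation", {
  set.seed(9)
  for (rep in 1:5) {
    p <- sample(2:6, 1); h <- sample(2:5, 1); q <- sample(1:3, 1)
    x <- matrix(runif(12 * p), 12, p)
    y <- matrix(runif(12 * q), 12, q)
    hfn <- sample(c("tansig", "satlins", "purelin", "logsig"), 1)
    ofn <- sample(c("tansig", "purelin"), 1)
    m <- et_mlp(x, y, hidden = h, hidden_fn = hfn, output_fn = ofn,
                epochs = 30, seed = rep)
    pred <- predict(m, x)
    for (i in c(1, 5, 12))
      expect_equal(unname(pred[i, ]), unname(naive_forward(m, x[i, ])),
                   tolerance = 1e-12)
  }
})

test_that("a hand-set 2-2-1 tansig network reproduces the pencil computation", {
  x <- matrix(c(0, 1, -1, 0.5), 2, 2)
  y <- matrix(c(0.3, 0.7), 2, 1)
  m <- et_mlp(x, y, hidden = 2, hidden_fn = "tansig", output_fn = "purelin",
              epochs = 1, seed = 1)
  m$weights <- list(W1 = matrix(c(0.5, -0.25, 1, 0.75), 2, 2),
                    b1 = c(0.1, -0.2),
                    W2 = matrix(c(1.5, -0.5), 1, 2), b2 = 0.25)
  xin <- c(0.4, -0.3)
  xs <- (xin - m$input_scaling$center) / m$input_scaling$half
  h1 <- tanh(0.5 * xs[1] + 1.0 * xs[2] + 0.1)
  h2 <- tanh(-0.25 * xs[1] + 0.75 * xs[2] - 0.2)
  z <- 1.5 * h1 - 0.5 * h2 + 0.25
  expected <- z * m$target_scaling$half + m$target_scaling$center
  expect_equal(unname(predict(m, matrix(xin, 1))[1, 1]), unname(expected),
               tolerance = 1e-12)
})

test_that("training is deterministic and never worsens the initial loss", {
  m1 <- et_mlp(toy_linear$X, toy_linear$Y, hidden = 4, epochs = 200, seed = 3)
  m2 <- et_mlp(toy_linear$X, toy_linear$Y, hidden = 4, epochs = 200, seed = 3)
  expect_identical(m1$weights, m2$weights)
  expect_lte(m1$final_loss, m1$initial_loss)
  # hardlims has zero subgradient: weights stay at init, loss not worsened
  mh <- et_mlp(toy_linear$X, toy_linear$Y, hidden = 4, hidden_fn = "hardlims",
               epochs = 50, seed = 3)
  expect_lte(mh$final_loss, mh$initial_loss)
})

test_that("a linear network fits noiseless linear data to the least-squares oracle", {
  m <- et_mlp(toy_linear$X, toy_linear$Y, hidden = 4, hidden_fn = "purelin",
              output_fn = "purelin", epochs = 2000, seed = 1)
  expect_lt(nrmse(toy_linear$Y, fitted(m)), 1e-3)
  # oracle: exact ordinary least squares reaches (numerically) zero residual
  ls <- lm.fit(cbind(1, toy_linear$X), toy_linear$Y)
  expect_lt(max(abs(ls$residuals)), 1e-10)
})

test_that("bounded output heads never leave the inverse-scaled activation box", {
  m <- et_mlp(toy_linear$X, toy_linear$Y, hidden = 3, hidden_fn = "tansig",
              output_fn = "tansig", epochs = 100, seed = 2)
  far <- matrix(runif(300 * 6, -50, 50), 300, 6)
  pred <- predict(m, far)
  hi <- m$target_scaling$center + m$target_scaling$half
  lo <- m$target_scaling$center - m$target_scaling$half
  for (j in 1:3) expect_true(all(pred[, j] >= lo[j] & pred[, j] <= hi[j]))
})

test_that("zero-variance features are mapped to zero, not NaN", {
  x <- cbind(toy_linear$X, 5)
  m <- et_mlp(x, toy_linear$Y, hidden = 3, epochs = 50, seed = 1,
              input_scaling = "per-feature")
  expect_true(all(is.finite(predict(m, x))))
  expect_error(et_mlp(cbind(toy_linear$X, NA), toy_linear$Y),
               class = "data_error")
})

test_that("model JSON serialization round-trips predictions exactly", {
  m <- et_mlp(toy_linear$X, toy_linear$Y, hidden = 3, epochs = 100, seed = 5)
  path <- tempfile(fileext = ".json")
  et_mlp_write(m, path)
  m2 <- et_mlp_read(path)
  expect_equal(predict(m2, toy_linear$X), predict(m, toy_linear$X),
               tolerance = 1e-12)
})

test_that("restricted search grids behave and the default grid has 200 cells", {
  # single-cell grid returns that cell
  sr <- architecture_search(toy_linear$X, toy_linear$Y, hidden = 3,
                            hidden_fns = "tansig", output_fns = "purelin",
                            folds = 3, seed = 1, epochs = 50,
                            final_epochs = 100)
  expect_equal(sr$grid_size, 1L)
  expect_equal(sr$best$hidden_size, 3L)
  expect_error(architecture_search(toy_linear$X, toy_linear$Y,
                                   hidden = integer(0)),
               class = "configuration_error")
  # full default grid enumerates 8 x 5 x 5 combinations
  grid <- expand.grid(2:9, transfer_names(), transfer_names())
  expect_equal(nrow(grid), 200L)
})

test_that("a linear-output configuration wins on noiseless linear toy data", {
  sr <- architecture_search(toy_linear$X, toy_linear$Y, hidden = c(3, 5),
                            hidden_fns = c("purelin", "tansig"),
                            output_fns = c("purelin", "tansig"),
                            folds = 3, seed = 2, epochs = 300,
                            final_epochs = 300)
  expect_equal(sr$best$output_fn, "purelin")
  # winner attains the grid minimum, and best-so-far is non-increasing
  expect_equal(sr$best$cv_nrmse, min(sr$results$cv_nrmse))
  expect_true(all(diff(cummin(sr$results$cv_nrmse)) <= 0))
})

test_that("the pipeline inverts its own noiseless generative model (R^2 > 0.99)", {
  # zero simulator noise; the model chosen by the package's own selection
  # procedure (full 200-configuration search, CV on the 27 standards only)
  # must recover the held-out concentrations almost perfectly
  design <- default_run$design
  recs <- simulate_run(design, noise = NULL)
  X <- compress_records(recs)
  Y <- default_run$Y
  tr <- default_run$train
  sr <- architecture_search(X[tr, ], Y[tr, ], hidden = 2:9, folds = 3,
                            seed = 1, epochs = 300, final_epochs = 2000)
  expect_equal(sr$grid_size, 200L)
  pred <- predict(sr$model, X[!tr, ])
  for (j in 1:3) expect_gt(cor(pred[, j], Y[!tr, j])^2, 0.99)
})
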