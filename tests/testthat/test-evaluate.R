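test_that("nrmse matches hand arithmetic and its invariances", {
  expect_equal(nrmse(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(nrmse(c(10, 20, 30), c(11, 19, 31)), sqrt(3 / 1400))
  e <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(nrmse(e, 2 * e), 1)
  # scale invariance
  set.seed(1)
  o <- e + matrix(rnorm(4, 0, 0.1), 2)
  for (k in c(0.01, 1, 250)) expect_equal(nrmse(k * e, k * o), nrmse(e, o))
  expect_error(nrmse(c(0, 0), c(1, 1)), class = "undefined_normalization")
  expect_error(nrmse(1:3, 1:4), class = "shape_error")
  # range-normalized variant: rmse over the expected range
  expect_equal(nrmse(c(0, 10), c(1, 11), normalization = "range"), 0.1)
})

test_that("regression line recovers exact linear relations", {
  r <- regression_line(c(0, 15, 30), c(0, 15, 30))
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  r2 <- regression_line(c(0, 15, 30), c(1, 16, 31))
  expect_equal(r2$slope, 1); expect_equal(r2$intercept, 1)
  expect_equal(r2$r_squared, 1)
  expect_error(regression_line(c(1, 2), c(1, 2)), class = "degenerate_fit")
  expect_error(regression_line(c(2, 2, 2), c(1, 2, 3)), class = "degenerate_fit")
})

test_that("regression line minimises squared error (brute-force cross-check)", {
  set.seed(7)
  x <- runif(8, 0, 30); y <- 0.9 * x + 2 + rnorm(8)
  fit <- regression_line(x, y)
  sse <- function(a, b) sum((y - a - b * x)^2)
  best <- sse(fit$intercept, fit$slope)
  for (a in seq(fit$intercept - 1, fit$intercept + 1, length.out = 21))
    for (b in seq(fit$slope - 0.2, fit$slope + 0.2, length.out = 21))
      expect_gte(sse(a, b), best - 1e-8)
})

test_that("evaluate_model emits six per-analyte rows plus two combined rows", {
  tr <- default_run$train
  m <- et_mlp(default_run$X[tr, ], default_run$Y[tr, ], epochs = 300, seed = 1)
  res <- evaluate_model(m, default_run$X[tr, ], default_run$Y[tr, ],
                        default_run$X[!tr, ], default_run$Y[!tr, ])
  expect_equal(nrow(res), 8L)
  expect_equal(sum(res$analyte == "combined"), 2L)
  expect_setequal(unique(res$subset), c("train", "test"))
  # combined NRMSE pools analytes into one ratio, not a mean of per-analyte values
  comb_train <- res$nrmse[res$analyte == "combined" & res$subset == "train"]
  pred <- predict(m, default_run$X[tr, ])
  expect_equal(comb_train, nrmse(default_run$Y[tr, ], pred))
  expect_true(all(res$combined_nrmse[res$subset == "train"] == comb_train))
})

test_that("evaluate_model rejects overlapping subsets and a perfect model scores perfectly", {
  tr <- default_run$train
  m <- et_mlp(default_run$X[tr, ], default_run$Y[tr, ], epochs = 100, seed = 1)
  expect_error(evaluate_model(m, default_run$X[tr, ], default_run$Y[tr, ],
                              default_run$X[tr, ], default_run$Y[tr, ]),
               class = "protocol_error")
  perfect <- structure(list(Y = default_run$Y), class = "oracle_model")
  # a predict method that returns the truth gives NRMSE 0 and R^2 1
  assign("predict.oracle_model",
         function(object, newdata, ...) object$Y[rownames(newdata), ],
         envir = globalenv())
  on.exit(rm("predict.oracle_model", envir = globalenv()))
  res <- evaluate_model(perfect, default_run$X[tr, ], default_run$Y[tr, ],
                        default_run$X[!tr, ], default_run$Y[!tr, ])
  expect_true(all(res$nrmse < 1e-12))
  expect_true(all(abs(res$r_squared - 1) < 1e-12))
})

test_that("training error does not exceed test error in the typical run", {
  # overfitting direction: across seeds, train <= test combined NRMSE mostly
  worse <- vapply(1:10, function(s) {
    res <- run_pipeline(run_config(seed = s), out_dir = tempfile(),
                        quiet = TRUE)
    comb <- res$results[res$results$analyte == "combined", ]
    comb$nrmse[comb$subset == "train"] <= comb$nrmse[comb$subset == "test"]
  }, logical(1))
  expect_gte(mean(worse), 0.9)
})
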