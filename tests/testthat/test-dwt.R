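test_that("a 752-point voltammogram compresses to 24 approximation coefficients", {
  x <- sin(seq(0, 10, length.out = 752))
  expect_length(dwt_approx(x), 24L)
})

test_that("depth-5 db3 coefficients match an independent reference transform", {
  # reference values computed with PyWavelets (db3, mode="periodization",
  # level 5) for sin(2*pi*t/752) + 0.25*cos(2*pi*7*t/752), t = 0..751
  t <- 0:751
  sig <- sin(2 * pi * t / 752) + 0.25 * cos(2 * pi * 7 * t / 752)
  cA <- dwt_approx(sig)
  expect_equal(cA[1:6],
               c(-1.926018178723421, 1.137713051750356, 1.064930492835075,
                 1.465738955650633, 4.856333243904410, 5.519241833258439),
               tolerance = 1e-12)
  expect_equal(cA[23:24], c(-3.577481705518444, -3.481185999124038),
               tolerance = 1e-12)
})

test_that("constant signals give the closed-form coefficient c * 2^(L/2)", {
  for (L in 1:6) {
    cfg <- wavelet_config(depth = L)
    cA <- dwt_approx(rep(2.5, 256), cfg)
    expect_equal(cA, rep(2.5 * 2^(L / 2), 256 / 2^L), tolerance = 1e-12)
  }
  # holds on the odd-halving 752-point grid too
  expect_equal(dwt_approx(rep(1.75, 752)), rep(1.75 * 2^2.5, 24),
               tolerance = 1e-12)
})

test_that("coefficient count equals ceiling(n / 2^depth) across lengths and depths", {
  for (depth in 1:6) {
    cfg <- wavelet_config(depth = depth)
    for (n in unique(c(2^depth, 2^depth + 1, seq(64, 2048, by = 97), 752, 2048))) {
      if (n < 2^depth) next
      expect_length(dwt_approx(seq_len(n) * 0.1, cfg), ceiling(n / 2^depth))
    }
  }
})

test_that("keeping all branches reconstructs the signal exactly", {
  set.seed(3)
  for (n in c(64, 97, 752)) {
    x <- rnorm(n)
    for (fam in c("db1", "db2", "db3")) {
      dec <- dwt_decompose(x, wavelet_config(family = fam, depth = 5))
      expect_lt(max(abs(dwt_reconstruct(dec) - x)) / max(abs(x)), 1e-10)
    }
  }
})

test_that("approximation energy does not exceed signal energy (orthonormality)", {
  set.seed(4)
  for (depth in 1:5) {
    n <- 32 * 2^depth  # multiple of 2^depth: no odd-length padding
    x <- rnorm(n)
    cA <- dwt_approx(x, wavelet_config(depth = depth))
    expect_lte(sum(cA^2), sum(x^2) * (1 + 1e-12))
  }
})

test_that("the transform is linear", {
  x <- sin(seq_len(752) / 40)
  expect_equal(dwt_approx(2 * x), 2 * dwt_approx(x), tolerance = 1e-12)
  expect_equal(dwt_approx(numeric(752)), numeric(24))
})

test_that("too-short signals and unknown families are rejected", {
  expect_error(dwt_approx(rnorm(16), wavelet_config(depth = 5)),
               class = "decomposition_error")
  expect_error(wavelet_config(depth = 0), class = "invalid_wavelet")
  expect_error(wavelet_config(family = "sym4"), class = "invalid_wavelet")
})

test_that("sample compression yields the 144-vector in fixed sensor order", {
  rec <- default_run$records[[1]]
  fv <- compress_sample(rec)
  expect_length(fv, 144L)
  expect_identical(names(fv)[c(1, 144)], c("f001", "f144"))
  # block k equals the transform of sensor k's trace
  for (k in seq_along(et_sensors())) {
    blk <- fv[((k - 1) * 24 + 1):(k * 24)]
    expect_equal(unname(blk),
                 dwt_approx(rec$voltammograms[[k]]$currents))
  }
  X <- default_run$X
  expect_equal(dim(X), c(36L, 144L))
})

test_that("compression percentage arithmetic", {
  expect_equal(compression_percent(4512, 144), 100 * (1 - 144 / 4512))
  expect_gte(compression_percent(4512, 144), 96.7)
  expect_equal(compression_percent(100, 100), 0)
  expect_equal(compression_percent(4512, 2256), 50)
  expect_error(compression_percent(100, 101), class = "domain_error")
  expect_error(compression_percent(0, 0), class = "domain_error")
})
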