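test_that("potential grid is a triangular sweep with the stated geometry", {
  g <- et_grid()
  expect_equal(g$n_points, 752L)
  expect_length(g$potentials, 752L)
  expect_equal(g$potentials[1], -1.5)
  expect_equal(g$potentials[752], -1.5)
  expect_equal(max(g$potentials), 1.5)
  up <- g$potentials[1:376]; down <- g$potentials[377:752]
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))
  # implied potential step ~8 mV for the default geometry
  expect_equal(1000 * diff(up)[1], 3000 / 375, tolerance = 1e-12)

  g4 <- et_grid(-1, 1, 4)
  expect_equal(g4$potentials, c(-1, 1, 1, -1))

  expect_error(et_grid(-1, 1, 5), class = "invalid_grid")
  expect_error(et_grid(-1, 1, 2), class = "invalid_grid")
  expect_error(et_grid(1, -1, 8), class = "invalid_grid")
})

test_that("peak current follows the saturating response law", {
  expect_equal(peak_current(0, 3, 10), 0)
  expect_equal(peak_current(10, 1, 50), 10 / 1.2)
  # bounded by S*K in the high-concentration limit, monotone before it
  cs <- seq(0, 5000, by = 50)
  v <- peak_current(cs, 2, 25)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v < 2 * 25))
  expect_gt(peak_current(1e6, 2, 25), 0.99 * 2 * 25)
  expect_error(peak_current(-1, 1, 1), class = "domain_error")
})

test_that("blank voltammogram is the pure direction-dependent baseline", {
  s <- et_default_bank()$GEC
  g <- et_grid()
  v <- simulate_voltammogram(s, c(0, 0, 0), g, noise = NULL)
  expect_equal(v$currents, s$b0 * g$direction + s$b1 * g$potentials)
})

test_that("simulation is deterministic given the seed", {
  s <- et_default_bank()$CuO
  n <- noise_model(0.05, 0.01, 7L)
  v1 <- simulate_voltammogram(s, c(5, 10, 2), noise = n)
  v2 <- simulate_voltammogram(s, c(5, 10, 2), noise = n)
  expect_identical(v1$currents, v2$currents)
  r1 <- simulate_sample(c(5, 10, 2), noise = n, sample_id = "a")
  r2 <- simulate_sample(c(5, 10, 2), noise = n, sample_id = "a")
  expect_identical(r1, r2)
  # different sample ids draw different noise
  r3 <- simulate_sample(c(5, 10, 2), noise = n, sample_id = "b")
  expect_false(identical(r1$voltammograms$GEC$currents,
                         r3$voltammograms$GEC$currents))
})

test_that("peak response saturates: doubling concentration less than doubles it", {
  s <- et_default_bank()$GEC
  g <- et_grid()
  base <- simulate_voltammogram(s, c(0, 0, 0), g, NULL)$currents
  lo <- simulate_voltammogram(s, c(12.5, 0, 0), g, NULL)$currents
  hi <- simulate_voltammogram(s, c(25, 0, 0), g, NULL)$currents
  exc_lo <- max(lo - base); exc_hi <- max(hi - base)
  expect_gt(exc_hi, exc_lo)
  expect_lt(exc_hi, 2 * exc_lo)
})

test_that("a sample record carries 6 voltammograms and 4512 raw currents", {
  rec <- simulate_sample(c(10, 20, 5), noise = NULL)
  expect_length(rec$voltammograms, 6L)
  expect_identical(names(rec$voltammograms), et_sensors())
  expect_equal(sum(vapply(rec$voltammograms, function(v) length(v$currents),
                          integer(1))), 4512L)
})

test_that("sensor bank must have six distinct sensors", {
  bank <- et_default_bank()
  expect_error(simulate_sample(c(1, 1, 1), bank[1:5]),
               class = "configuration_error")
  bank2 <- bank
  bank2$CuO$sensor_id <- "GEC"
  expect_error(simulate_sample(c(1, 1, 1), bank2),
               class = "configuration_error")
  expect_error(simulate_voltammogram(bank$GEC, c(1, 1), et_grid()),
               class = "shape_error")
})

test_that("single-analyte responses are non-collinear across analytes", {
  recA <- simulate_sample(c(25, 0, 0), noise = NULL, sample_id = "A")
  recB <- simulate_sample(c(0, 25, 0), noise = NULL, sample_id = "B")
  for (s in et_sensors()) {
    a <- recA$voltammograms[[s]]$currents
    b <- recB$voltammograms[[s]]$currents
    expect_lt(abs(cor(a, b)), 0.999)
  }
})

test_that("low-concentration mixtures superpose when interactions are off", {
  s <- et_default_bank()$GEC
  s$G[] <- 0
  g <- et_grid()
  base <- simulate_voltammogram(s, c(0, 0, 0), g, NULL)$currents
  mix <- simulate_voltammogram(s, c(0.1, 0.1, 0.1), g, NULL)$currents - base
  singles <- Reduce(`+`, lapply(1:3, function(a) {
    conc <- numeric(3); conc[a] <- 0.1
    simulate_voltammogram(s, conc, g, NULL)$currents - base
  }))
  expect_lt(max(abs(mix - singles)) / max(abs(singles)), 0.01)
})

test_that("empirical noise SD matches the configured level", {
  s <- et_default_bank()$Pt
  g <- et_grid(-1, 1, 32)
  blank0 <- simulate_voltammogram(s, c(0, 0, 0), g, NULL)$currents
  sd_cfg <- 0.2 + 0.01 * max(abs(blank0))
  reps <- vapply(seq_len(1000), function(i)
    simulate_voltammogram(s, c(0, 0, 0), g,
                          noise_model(0.2, 0.01, i))$currents,
    numeric(32))
  sd_emp <- apply(reps, 1, sd)
  expect_true(all(abs(sd_emp - sd_cfg) / sd_cfg < 0.10))
})

test_that("default bank sensitivity matrix has full column rank", {
  expect_equal(qr(sensitivity_matrix())$rank, 3L)
})
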