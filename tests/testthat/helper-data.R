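# Shared small objects, built once per test run.

conc_cols <- paste0("c_", et_analytes(), "_ppm")

# canonical low-noise run at seed 1: design, features, concentration matrix
default_run <- local({
  cfg <- run_config(seed = 1)
  design <- build_design(cfg$design)
  noise <- noise_model(0, cfg$sigma_rel, 101L)
  records <- simulate_run(design, cfg$bank, cfg$grid, noise)
  X <- compress_records(records, cfg$wavelet)
  Y <- as.matrix(design[, conc_cols])
  colnames(Y) <- et_analytes()
  rownames(Y) <- design$sample_id
  list(cfg = cfg, design = design, records = records, X = X, Y = Y,
       train = design$subset == "train")
})

# tiny linearly generated calibration problem (exact linear feature->target map)
toy_linear <- local({
  set.seed(42)
  X <- matrix(runif(20 * 6, -1, 1), 20, 6)
  B <- matrix(c(2, -1, 0.5, 1, 0.25, -0.75,
                -0.5, 1.5, 1, -0.25, 0.75, 0.5,
                1, 0.5, -1, 0.5, 1.25, -0.25), 6, 3)
  list(X = X, Y = X %*% B + 15)
})

# reference forward pass written as plain loops, independent of the package's
# vectorised implementation
naive_forward <- function(model, xrow) {
  a <- model$architecture
  xs <- (xrow - model$input_scaling$center) / model$input_scaling$half
  h <- numeric(a$n_hidden)
  for (i in seq_len(a$n_hidden)) {
    z <- model$weights$b1[i]
    for (j in seq_len(a$n_input)) z <- z + model$weights$W1[i, j] * xs[j]
    h[i] <- transfer(a$hidden_fn, z)
  }
  out <- numeric(a$n_output)
  for (k in seq_len(a$n_output)) {
    z <- model$weights$b2[k]
    for (i in seq_len(a$n_hidden)) z <- z + model$weights$W2[k, i] * h[i]
    out[k] <- transfer(a$output_fn, z)
  }
  out * model$target_scaling$half + model$target_scaling$center
}
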