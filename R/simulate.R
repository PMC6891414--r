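#' Measurement-noise model
#'
#' Additive Gaussian noise with standard deviation
#' `sigma_abs + sigma_rel * full_scale`, where `full_scale` is the largest
#' absolute noise-free current of the trace being perturbed. The default
#' `sigma_rel = 0.005` (0.5% of full scale) is the package's canonical
#' measurement-noise level.
#'
#' @param sigma_abs Absolute noise floor (uA), `>= 0`.
#' @param sigma_rel Relative noise as a fraction of full-scale current, `>= 0`.
#' @param seed Integer master seed; every stochastic draw in the simulator is
#'   derived deterministically from it.
#' @return An object of class `et_noise`.
#' @export
noise_model <- function(sigma_abs = 0, sigma_rel = 0.005, seed = 1L) {
  if (sigma_abs < 0 || sigma_rel < 0)
    stop_et("noise magnitudes must be nonnegative", class = "invalid_noise")
  structure(list(sigma_abs = sigma_abs, sigma_rel = sigma_rel,
                 seed = as.integer(seed)),
            class = "et_noise")
}

#' Saturating faradaic peak current
#'
#' Peak amplitude of one analyte at one sensor:
#' `S * c / (1 + c / K + suppression)`. Linear in `c` at low concentration
#' (slope `S` when `suppression = 0`), monotone nondecreasing, and bounded by
#' `S * K` as `c` grows — the saturation that motivates a nonlinear
#' calibration model. `suppression` is the competitive-interference term
#' contributed by the other analytes present.
#'
#' @param c Concentration (ppm), nonnegative; vectorized.
#' @param S Sensitivity (uA/ppm).
#' @param K Saturation constant (ppm).
#' @param suppression Dimensionless nonnegative interference term.
#' @return Peak current (uA).
#' @examples
#' peak_current(10, 1, 50)  # 10 / 1.2 = 8.333...
#' @export
peak_current <- function(c, S, K, suppression = 0) {
  if (any(c < 0)) stop_et("concentration must be nonnegative", class = "domain_error")
  if (any(suppression < 0)) stop_et("suppression must be nonnegative", class = "domain_error")
  S * c / (1 + c / K + suppression)
}

#' Simulate one sensor's cyclic voltammogram
#'
#' Current at potential `E` is a direction-dependent capacitive baseline
#' `b0 * direction + b1 * E` plus, on the cathodic (descending) half-cycle,
#' a sum of Gaussian reduction peaks — one per analyte, amplitude from
#' [peak_current()] with cross-suppression `sum_b G[a, b] * c_b` — and on the
#' anodic (ascending) half the same peaks scaled by `anodic_fraction`
#' (quasi-reversible mirror signal). Gaussian noise per [noise_model()] is
#' added last; the draw is fully determined by `noise$seed`.
#'
#' @param params An [et_sensor()].
#' @param concentrations Length-3 numeric vector (ppm), canonical analyte order.
#' @param grid An [et_grid()].
#' @param noise An [noise_model()]; `NULL` for noise-free currents.
#' @return Object of class `et_voltammogram`: list with `sensor_id`, `grid`,
#'   `currents` (uA, length `grid$n_points`).
#' @export
simulate_voltammogram <- function(params, concentrations, grid = et_grid(),
                                  noise = NULL) {
  stopifnot(inherits(params, "et_sensor"), is_et_grid(grid))
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != 3L)
    stop_et("expected 3 concentrations, got %d", length(concentrations),
            class = "shape_error")
  if (any(concentrations < 0))
    stop_et("concentrations must be nonnegative", class = "domain_error")

  E <- grid$potentials
  dir <- grid$direction
  suppression <- as.numeric(params$G %*% concentrations)
  amp <- peak_current(concentrations, params$S, params$K, suppression)
  peaks <- numeric(grid$n_points)
  for (a in 1:3) {
    if (amp[a] == 0) next
    peaks <- peaks + amp[a] * exp(-0.5 * ((E - params$E0[a]) / params$w[a])^2)
  }
  scale <- ifelse(dir < 0, 1, params$anodic_fraction)  # full cathodic, scaled anodic
  i <- params$b0 * dir + params$b1 * E + scale * peaks

  if (!is.null(noise) && (noise$sigma_abs > 0 || noise$sigma_rel > 0)) {
    sd <- noise$sigma_abs + noise$sigma_rel * max(abs(i))
    i <- i + with_seed(noise$seed, stats::rnorm(grid$n_points, 0, sd))
  }
  structure(list(sensor_id = params$sensor_id, grid = grid, currents = i),
            class = "et_voltammogram")
}

#' Simulate a full sample record (six voltammograms)
#'
#' Runs [simulate_voltammogram()] for every sensor of the bank with
#' per-sensor noise streams derived from `(noise$seed, sample_id, sensor
#' index)` by stable hashing, so records are reproducible individually and
#' independent across sensors.
#'
#' @param concentrations Length-3 ppm vector (design row).
#' @param bank List of six [et_sensor()] objects with distinct ids.
#' @param grid An [et_grid()].
#' @param noise An [noise_model()] or `NULL`.
#' @param sample_id Label stamped on the record and hashed into noise streams.
#' @return Object of class `et_sample`: `sample_id`, named `concentrations`,
#'   and `voltammograms` (named list, canonical sensor order). Six sensors at
#'   752 points carry the 4512-current raw fingerprint.
#' @export
simulate_sample <- function(concentrations, bank = et_default_bank(),
                            grid = et_grid(), noise = noise_model(),
                            sample_id = "S1") {
  if (length(bank) != 6L)
    stop_et("sensor bank must have 6 entries, got %d", length(bank),
            class = "configuration_error")
  ids <- vapply(bank, function(s) s$sensor_id, character(1))
  if (anyDuplicated(ids))
    stop_et("duplicate sensor_id in bank: %s", ids[duplicated(ids)][1],
            class = "configuration_error")
  vgs <- vector("list", 6L)
  for (k in seq_along(bank)) {
    nk <- if (is.null(noise)) NULL else
      noise_model(noise$sigma_abs, noise$sigma_rel,
                  derive_seed(noise$seed, sample_id, k))
    vgs[[k]] <- simulate_voltammogram(bank[[k]], concentrations, grid, nk)
  }
  names(vgs) <- ids
  structure(list(sample_id = as.character(sample_id),
                 concentrations = stats::setNames(as.numeric(concentrations), ET_ANALYTES),
                 voltammograms = vgs),
            class = "et_sample")
}

#' Simulate every sample of a design table
#'
#' @param design A design `data.frame` from [build_design()] (or the same
#'   schema read back from CSV).
#' @inheritParams simulate_sample
#' @return List of `et_sample` records, one per design row, named by sample id.
#' @export
simulate_run <- function(design, bank = et_default_bank(), grid = et_grid(),
                         noise = noise_model()) {
  conc_cols <- paste0("c_", ET_ANALYTES, "_ppm")
  stopifnot(all(c("sample_id", conc_cols) %in% names(design)))
  recs <- lapply(seq_len(nrow(design)), function(i)
    simulate_sample(as.numeric(design[i, conc_cols]), bank, grid, noise,
                    sample_id = design$sample_id[i]))
  names(recs) <- design$sample_id
  recs
}

#' @export
print.et_sample <- function(x, ...) {
  cat(sprintf("Sample %s: [%s] ppm, %d voltammograms x %d points\n",
              x$sample_id, paste(signif(x$concentrations, 4), collapse = ", "),
              length(x$voltammograms),
              length(x$voltammograms[[1]]$currents)))
  invisible(x)
}

# total raw current values carried by a record (6 x 752 = 4512 at defaults)
n_raw_values <- function(rec) {
  sum(vapply(rec$voltammograms, function(v) length(v$currents), integer(1)))
}
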