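#' Write / read a sensor bank as YAML
#'
#' Flat per-sensor mapping mirroring the [et_sensor()] fields, so custom
#' arrays can be version-controlled and shared.
#'
#' @param bank Named list of [et_sensor()] objects.
#' @param path YAML file path.
#' @return `bank_write` returns `path` invisibly; `bank_read` the bank.
#' @export
bank_write <- function(bank, path) {
  payload <- lapply(bank, function(s)
    list(sensor_id = s$sensor_id, S = as.numeric(s$S), K = as.numeric(s$K),
         E0 = as.numeric(s$E0), w = as.numeric(s$w),
         anodic_fraction = s$anodic_fraction, b1 = s$b1, b0 = s$b0,
         G = as.numeric(s$G[upper.tri(s$G)])))
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname bank_write
#' @export
bank_read <- function(path) {
  payload <- yaml::read_yaml(path)
  lapply(payload, function(p) {
    G <- matrix(0, 3, 3)
    G[upper.tri(G)] <- as.numeric(p$G)
    G <- G + t(G)
    et_sensor(p$sensor_id, p$S, p$K, p$E0, p$w, p$anodic_fraction,
              p$b1, p$b0, G)
  })
}

#' Write / read a pipeline configuration as YAML
#'
#' The full [run_config()] round-trips losslessly (the sensor bank
#' included), giving a single human-editable file that pins a run.
#'
#' @param config An [run_config()].
#' @param path YAML file path.
#' @return `et_config_write` returns `path` invisibly; `et_config_read` the
#'   configuration.
#' @export
et_config_write <- function(config, path) {
  stopifnot(inherits(config, "et_config"))
  payload <- list(
    seed = config$seed,
    design = unclass(config$design),
    grid = list(e_min = config$grid$e_min, e_max = config$grid$e_max,
                n_points = config$grid$n_points),
    noise = list(sigma_abs = config$sigma_abs, sigma_rel = config$sigma_rel),
    wavelet = unclass(config$wavelet),
    network = list(hidden = config$hidden, hidden_fn = config$hidden_fn,
                   output_fn = config$output_fn, epochs = config$epochs),
    search = list(do_search = config$do_search,
                  hidden = config$search_hidden,
                  folds = config$search_folds,
                  epochs = config$search_epochs),
    bank = lapply(config$bank, function(s)
      list(sensor_id = s$sensor_id, S = as.numeric(s$S), K = as.numeric(s$K),
           E0 = as.numeric(s$E0), w = as.numeric(s$w),
           anodic_fraction = s$anodic_fraction, b1 = s$b1, b0 = s$b0,
           G = as.numeric(s$G[upper.tri(s$G)]))))
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname et_config_write
#' @export
et_config_read <- function(path) {
  p <- yaml::read_yaml(path)
  bank <- lapply(p$bank, function(s) {
    G <- matrix(0, 3, 3); G[upper.tri(G)] <- as.numeric(s$G); G <- G + t(G)
    et_sensor(s$sensor_id, s$S, s$K, s$E0, s$w, s$anodic_fraction,
              s$b1, s$b0, G)
  })
  names(bank) <- vapply(bank, function(s) s$sensor_id, character(1))
  cfg <- run_config(
    seed = p$seed,
    design = design_spec(p$design$levels, p$design$factors,
                         p$design$domain_lo, p$design$domain_hi,
                         p$design$tilt_deg, p$design$n_test, p$design$seed),
    bank = bank,
    grid = et_grid(p$grid$e_min, p$grid$e_max, p$grid$n_points),
    sigma_abs = p$noise$sigma_abs, sigma_rel = p$noise$sigma_rel,
    wavelet = wavelet_config(p$wavelet$family, p$wavelet$depth,
                             p$wavelet$boundary),
    hidden = p$network$hidden, hidden_fn = p$network$hidden_fn,
    output_fn = p$network$output_fn, epochs = p$network$epochs,
    do_search = p$search$do_search, search_hidden = p$search$hidden,
    search_folds = p$search$folds, search_epochs = p$search$epochs)
  # preserve the exact stored design seed rather than re-deriving it
  cfg$design$seed <- as.integer(p$design$seed)
  cfg
}
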