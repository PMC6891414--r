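.conc_cols <- function() paste0("c_", ET_ANALYTES, "_ppm")

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the voltammogram CSV schema
#'
#' Long format, one row per current sample: columns `sample_id`, `sensor_id`,
#' `point_index` (1-based within the cycle), `potential_V`, `current_uA`.
#'
#' @param records List of `et_sample` records.
#' @param path CSV path.
#' @return `write_voltammograms` returns `path` invisibly.
#' @export
write_voltammograms <- function(records, path) {
  parts <- lapply(records, function(rec) {
    do.call(rbind, lapply(rec$voltammograms, function(v)
      data.frame(sample_id = rec$sample_id, sensor_id = v$sensor_id,
                 point_index = seq_along(v$currents),
                 potential_V = v$grid$potentials, current_uA = v$currents,
                 stringsAsFactors = FALSE)))
  })
  write_csv_plain(do.call(rbind, parts), path)
}

#' Write the sample (design) table CSV
#'
#' Columns `sample_id`, `c_diazepam_ppm`, `c_flunitrazepam_ppm`,
#' `c_lorazepam_ppm`, `subset`.
#'
#' @param design Design `data.frame` from [build_design()].
#' @param path CSV path.
#' @export
write_sample_table <- function(design, path) write_csv_plain(design, path)

#' Write a feature matrix CSV (`sample_id`, `f001`...)
#'
#' @param x Feature matrix with sample-id rownames.
#' @param path CSV path.
#' @export
write_features <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_csv_plain(df, path)
}

#' Ingest externally acquired voltammograms
#'
#' Reads the voltammogram and sample-table CSV schemas back into validated
#' `et_sample` records, so instrument exports can replace the simulator.
#' Every record must carry all six sensors in the canonical order with the
#' expected number of points and a triangular potential program; schema
#' violations name the offending file and sample.
#'
#' @param voltammogram_csv Path to the long-format voltammogram CSV.
#' @param sample_csv Path to the sample table CSV.
#' @param grid Expected [et_grid()]; point counts are checked against it.
#' @return Named list of `et_sample` records in sample-table order.
#' @export
ingest_external <- function(voltammogram_csv, sample_csv, grid = et_grid()) {
  volt <- utils::read.csv(voltammogram_csv, stringsAsFactors = FALSE)
  samp <- utils::read.csv(sample_csv, stringsAsFactors = FALSE)
  need <- c("sample_id", "sensor_id", "point_index", "potential_V", "current_uA")
  if (!all(need %in% names(volt)))
    stop_et("%s: missing columns %s", voltammogram_csv,
            paste(setdiff(need, names(volt)), collapse = ", "),
            class = "schema_error")
  if (!all(c("sample_id", .conc_cols()) %in% names(samp)))
    stop_et("%s: bad sample-table schema", sample_csv, class = "schema_error")
  half <- grid$n_points %/% 2L
  recs <- lapply(seq_len(nrow(samp)), function(i) {
    sid <- samp$sample_id[i]
    sv <- volt[volt$sample_id == sid, ]
    if (nrow(sv) == 0L)
      stop_et("%s: no voltammograms for sample %s", voltammogram_csv, sid,
              class = "schema_error")
    missing <- setdiff(ET_SENSORS, unique(sv$sensor_id))
    if (length(missing))
      stop_et("%s: sample %s missing sensor(s) %s", voltammogram_csv, sid,
              paste(missing, collapse = ", "), class = "schema_error")
    vgs <- lapply(ET_SENSORS, function(sn) {
      tr <- sv[sv$sensor_id == sn, ]
      tr <- tr[order(tr$point_index), ]
      if (nrow(tr) != grid$n_points)
        stop_et("%s: sample %s sensor %s has %d points, expected %d",
                voltammogram_csv, sid, sn, nrow(tr), grid$n_points,
                class = "schema_error")
      up <- tr$potential_V[seq_len(half)]
      down <- tr$potential_V[(half + 1L):grid$n_points]
      if (any(diff(up) <= 0) || any(diff(down) >= 0))
        stop_et("%s: sample %s sensor %s potential halves not monotone",
                voltammogram_csv, sid, sn, class = "schema_error")
      structure(list(sensor_id = sn, grid = grid, currents = tr$current_uA),
                class = "et_voltammogram")
    })
    names(vgs) <- ET_SENSORS
    structure(list(sample_id = sid,
                   concentrations = stats::setNames(
                     as.numeric(samp[i, .conc_cols()]), ET_ANALYTES),
                   voltammograms = vgs),
              class = "et_sample")
  })
  names(recs) <- samp$sample_id
  recs
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters with one master seed. Defaults are the
#' canonical study conditions: 27 tilted factorial standards plus 9 random
#' test mixtures over 0-30 ppm, the shipped six-sensor bank, 0.5% relative
#' noise, db3/depth-5 compression and the 144-5-3 satlins/tansig network.
#'
#' @param seed Master seed; the design, every noise stream and every
#'   training run derive from it.
#' @param design An [design_spec()] (its seed is re-derived from `seed`).
#' @param bank Sensor bank.
#' @param grid An [et_grid()].
#' @param sigma_abs,sigma_rel Noise magnitudes, see [noise_model()].
#' @param wavelet An [wavelet_config()].
#' @param hidden,hidden_fn,output_fn Network architecture used when
#'   `do_search = FALSE`.
#' @param epochs Training epochs.
#' @param do_search Run the full [architecture_search()] instead of training
#'   the fixed architecture directly.
#' @param search_hidden,search_folds,search_epochs Search-stage settings.
#' @return Object of class `et_config`.
#' @export
run_config <- function(seed = 1L, design = design_spec(),
                       bank = et_default_bank(), grid = et_grid(),
                       sigma_abs = 0, sigma_rel = 0.005,
                       wavelet = wavelet_config(),
                       hidden = 5L, hidden_fn = "satlins",
                       output_fn = "tansig", epochs = 2000L,
                       do_search = FALSE, search_hidden = 2:9,
                       search_folds = 3L, search_epochs = 600L) {
  design$seed <- derive_seed(seed, "design")
  structure(list(seed = as.integer(seed), design = design, bank = bank,
                 grid = grid, sigma_abs = sigma_abs, sigma_rel = sigma_rel,
                 wavelet = wavelet, hidden = as.integer(hidden),
                 hidden_fn = hidden_fn, output_fn = output_fn,
                 epochs = as.integer(epochs), do_search = isTRUE(do_search),
                 search_hidden = as.integer(search_hidden),
                 search_folds = as.integer(search_folds),
                 search_epochs = as.integer(search_epochs)),
            class = "et_config")
}

config_hash <- function(config) {
  flat <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  fnv1a_hex(as.character(flat))
}

#' Run the full electronic-tongue pipeline
#'
#' Design, simulation, wavelet compression, network training (or
#' architecture search) and evaluation, writing every stage artifact to
#' `out_dir`: `samples.csv`, `voltammograms.csv`, `features.csv`,
#' `search_report.csv`, `model.json`, `results.csv` and `run.log`. A rerun
#' with the same configuration and seed reproduces every numeric output
#' bit-identically.
#'
#' @param config An [run_config()].
#' @param out_dir Output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @param quiet Suppress stage messages.
#' @return (Invisibly) list with `design`, `features`, `model`, `search`
#'   (`NULL` unless `do_search`), `results`, `paths`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, overwrite = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "et_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite)
    stop_et("output directory %s is not empty (use overwrite = TRUE)",
            out_dir, class = "output_exists")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- lapply(stats::setNames(nm = c("samples", "voltammograms", "features",
                                         "search_report", "model", "results",
                                         "log")),
                  function(nm) file.path(out_dir, paste0(
                    nm, if (nm == "model") ".json" else if (nm == "log") ".txt"
                    else ".csv")))
  logf <- file(paths$log, "w")
  on.exit(close(logf), add = TRUE)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, logf)
    if (!quiet) message(msg)
  }
  say("run: seed=%d config=%s", config$seed, config_hash(config))

  stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e)
      stop_et("stage %s failed: %s", name, conditionMessage(e),
              class = "stage_error"))
  }

  design <- stage("A:design", build_design(config$design))
  noise <- noise_model(config$sigma_abs, config$sigma_rel,
                       derive_seed(config$seed, "noise"))
  records <- stage("B:simulate", simulate_run(design, config$bank,
                                              config$grid, noise))
  write_sample_table(design, paths$samples)
  write_voltammograms(records, paths$voltammograms)

  X <- stage("C:compress", compress_records(records, config$wavelet))
  write_features(X, paths$features)

  tr <- design$subset == "train"
  Y <- as.matrix(design[, .conc_cols()])
  colnames(Y) <- ET_ANALYTES
  rownames(Y) <- design$sample_id

  search <- NULL
  if (config$do_search) {
    search <- stage("D:search", architecture_search(
      X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
      hidden = config$search_hidden, folds = config$search_folds,
      seed = derive_seed(config$seed, "search"),
      epochs = config$search_epochs, final_epochs = config$epochs))
    model <- search$model
    write_csv_plain(search$results, paths$search_report)
    say("winner: %d hidden, %s/%s, cv_nrmse=%.5g", search$best$hidden_size,
        search$best$hidden_fn, search$best$output_fn, search$best$cv_nrmse)
  } else {
    model <- stage("D:train", et_mlp(
      X[tr, , drop = FALSE], Y[tr, , drop = FALSE], hidden = config$hidden,
      hidden_fn = config$hidden_fn, output_fn = config$output_fn,
      epochs = config$epochs, seed = derive_seed(config$seed, "train")))
    write_csv_plain(data.frame(hidden_size = config$hidden,
                               hidden_fn = config$hidden_fn,
                               output_fn = config$output_fn,
                               cv_nrmse = NA_real_,
                               train_loss = model$final_loss),
                    paths$search_report)
  }
  et_mlp_write(model, paths$model)

  results <- stage("E:evaluate", evaluate_model(
    model, X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
    X[!tr, , drop = FALSE], Y[!tr, , drop = FALSE]))
  write_csv_plain(results, paths$results)
  comb <- results[results$analyte == "combined", ]
  say("combined NRMSE: train=%.5g test=%.5g",
      comb$nrmse[comb$subset == "train"], comb$nrmse[comb$subset == "test"])

  invisible(list(design = design, features = X, model = model,
                 search = search, results = results, paths = paths,
                 config = config))
}
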