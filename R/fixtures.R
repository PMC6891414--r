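# Registered fixture generators. Each writes plain-text pipeline CSVs into a
# directory and returns the file names; the wrapper stamps a manifest with
# content hashes so regeneration can be verified bit-for-bit.
.FIXTURES <- list(
  default_run_noiseless = function(dir, seed)
    .fixture_run(dir, seed, sigma_rel = 0),
  default_run_lownoise = function(dir, seed)
    .fixture_run(dir, seed, sigma_rel = 0.005),
  default_run_noisy = function(dir, seed)
    .fixture_run(dir, seed, sigma_rel = 0.02),
  toy_linear_calibration = function(dir, seed) {
    # 20 samples whose concentrations are an exact linear map of 5 features
    B <- matrix(c(2, -1, 0.5, 1, 0.25,
                  -0.5, 1.5, 1, -0.25, 0.75,
                  1, 0.5, -1, 0.5, 1.25), 5, 3)
    X <- with_seed(derive_seed(seed, "toy_linear"),
                   matrix(stats::runif(100, -1, 1), 20, 5))
    Y <- X %*% B + 15
    df <- data.frame(sample_id = sprintf("toy%02d", 1:20), X1 = X[, 1],
                     X2 = X[, 2], X3 = X[, 3], X4 = X[, 4], X5 = X[, 5],
                     c_diazepam_ppm = Y[, 1], c_flunitrazepam_ppm = Y[, 2],
                     c_lorazepam_ppm = Y[, 3])
    write_csv_plain(df, file.path(dir, "toy_linear.csv"))
    "toy_linear.csv"
  },
  toy_signals = function(dir, seed) {
    # small deterministic waveforms exercising the wavelet stage
    t <- seq_len(752) - 1L
    df <- data.frame(point_index = t + 1L,
                     sine = sin(2 * pi * t / 752),
                     chirp = sin(2 * pi * t^2 / 752^2 * 8),
                     constant = rep(2.5, 752))
    write_csv_plain(df, file.path(dir, "toy_signals.csv"))
    "toy_signals.csv"
  }
)

.fixture_run <- function(dir, seed, sigma_rel) {
  cfg <- run_config(seed = seed, sigma_rel = sigma_rel)
  design <- build_design(cfg$design)
  noise <- noise_model(0, sigma_rel, derive_seed(seed, "noise"))
  records <- simulate_run(design, cfg$bank, cfg$grid, noise)
  write_sample_table(design, file.path(dir, "samples.csv"))
  write_voltammograms(records, file.path(dir, "voltammograms.csv"))
  write_features(compress_records(records, cfg$wavelet),
                 file.path(dir, "features.csv"))
  c("samples.csv", "voltammograms.csv", "features.csv")
}

#' Deterministic canonical fixtures
#'
#' Generates one of the registered fixture sets under `dir` and writes a
#' `manifest.json` recording the generator name, seed and a content hash per
#' file. Regeneration with the same name and seed reproduces every hash.
#' The three `default_run_*` fixtures are the 36-sample canonical run at
#' noise levels 0, 0.5% and 2% of full scale.
#'
#' @param name Registered fixture name, see [fixture_names()].
#' @param seed Integer seed.
#' @param dir Target directory (created if needed).
#' @return (Invisibly) the manifest as a list.
#' @export
make_fixture <- function(name, seed = 1L, dir = tempfile("fixture")) {
  gen <- .FIXTURES[[name]]
  if (is.null(gen))
    stop_et("unknown fixture '%s' (available: %s)", name,
            paste(names(.FIXTURES), collapse = ", "), class = "registry_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- gen(dir, seed)
  hashes <- vapply(files, function(f)
    fnv1a_hex(paste(readLines(file.path(dir, f)), collapse = "\n")),
    character(1))
  manifest <- list(name = name, seed = as.integer(seed), dir = dir,
                   files = as.list(hashes))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname make_fixture
#' @export
fixture_names <- function() names(.FIXTURES)
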