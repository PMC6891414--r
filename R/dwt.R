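# Orthonormal Daubechies scaling filters (decomposition low-pass). db1 is the
# Haar pair; db3 (6 taps) is the package default. Standard published values.
.DB_FILTERS <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.8365163037378079, 0.48296291314469025),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.8068915093110925, 0.33267055295008263)
)

.wavelet_filters <- function(family) {
  h <- .DB_FILTERS[[family]]
  if (is.null(h))
    stop_et("unknown wavelet family '%s' (available: %s)", family,
            paste(names(.DB_FILTERS), collapse = ", "), class = "invalid_wavelet")
  L <- length(h)
  g <- rev(h) * (-1)^seq_len(L)   # quadrature mirror high-pass
  list(lo = h, hi = g, L = L)
}

#' Wavelet compression settings
#'
#' @param family Wavelet family; `"db3"` (Daubechies-3, 6 filter taps) is the
#'   default used throughout.
#' @param depth Decomposition depth; 5 halvings take a 752-point voltammogram
#'   to 24 approximation coefficients (`ceiling(752 / 2^5)`).
#' @param boundary Boundary handling; only `"periodization"` is provided
#'   (circular extension, `ceiling(n/2)` coefficients per level — the mode
#'   that makes the 4512-to-144 compression exact).
#' @return Object of class `et_wavelet`.
#' @export
wavelet_config <- function(family = "db3", depth = 5L,
                           boundary = "periodization") {
  depth <- as.integer(depth)
  if (depth < 1L) stop_et("depth must be >= 1", class = "invalid_wavelet")
  boundary <- match.arg(boundary, "periodization")
  .wavelet_filters(family)  # validates family
  structure(list(family = family, depth = depth, boundary = boundary),
            class = "et_wavelet")
}

# one periodized analysis level; odd-length input is extended by repeating the
# final sample (circular convolution phase matches the usual periodized DWT)
.dwt_step <- function(x, flt) {
  n0 <- length(x)
  if (n0 %% 2L == 1L) x <- c(x, x[n0])
  n <- length(x)
  half <- n %/% 2L
  cA <- numeric(half); cD <- numeric(half)
  k <- seq_len(half) - 1L
  for (m in seq_len(flt$L)) {
    idx <- (2L * k + 3L - (m - 1L)) %% n + 1L
    cA <- cA + flt$lo[m] * x[idx]
    cD <- cD + flt$hi[m] * x[idx]
  }
  list(cA = cA, cD = cD, n = n0)
}

# transpose/synthesis of .dwt_step; exact inverse (after truncation to n)
.idwt_step <- function(cA, cD, n_orig, flt) {
  n <- 2L * length(cA)
  x <- numeric(n)
  k <- seq_along(cA) - 1L
  for (m in seq_len(flt$L)) {
    # stride-2 indices are pairwise distinct modulo the even n, so plain
    # indexed accumulation is safe
    idx <- (2L * k + 3L - (m - 1L)) %% n + 1L
    x[idx] <- x[idx] + flt$lo[m] * cA + flt$hi[m] * cD
  }
  x[seq_len(n_orig)]
}

#' Multi-level periodized wavelet decomposition
#'
#' Full analysis keeping approximation and detail branches plus the length
#' bookkeeping needed for exact reconstruction via [dwt_reconstruct()].
#'
#' @param signal Numeric vector, length at least `2^depth`.
#' @param config An [wavelet_config()].
#' @return Object of class `et_dwt`: `approx` (deepest-level coefficients),
#'   `details` (list, level 1 first), `lengths` (input length per level),
#'   `config`.
#' @export
dwt_decompose <- function(signal, config = wavelet_config()) {
  stopifnot(inherits(config, "et_wavelet"))
  x <- as.numeric(signal)
  if (any(!is.finite(x))) stop_et("signal must be finite", class = "data_error")
  if (length(x) < 2^config$depth)
    stop_et("signal length %d too short for depth %d (needs >= %d)",
            length(x), config$depth, 2^config$depth,
            class = "decomposition_error")
  flt <- .wavelet_filters(config$family)
  details <- vector("list", config$depth)
  lengths <- integer(config$depth)
  for (lev in seq_len(config$depth)) {
    lengths[lev] <- length(x)
    st <- .dwt_step(x, flt)
    details[[lev]] <- st$cD
    x <- st$cA
  }
  structure(list(approx = x, details = details, lengths = lengths,
                 config = config),
            class = "et_dwt")
}

#' Inverse of [dwt_decompose()]
#'
#' @param dec An `et_dwt` object.
#' @return Reconstructed signal (numeric vector, original length).
#' @export
dwt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "et_dwt"))
  flt <- .wavelet_filters(dec$config$family)
  x <- dec$approx
  for (lev in rev(seq_len(dec$config$depth)))
    x <- .idwt_step(x, dec$details[[lev]], dec$lengths[lev], flt)
  x
}

#' Approximation coefficients of a signal
#'
#' The compressed fingerprint: the low-frequency branch of the depth-level
#' periodized transform. Output length is `ceiling(n / 2^depth)` — 24 for a
#' 752-point voltammogram at the default depth 5.
#'
#' @inheritParams dwt_decompose
#' @return Numeric vector of approximation coefficients.
#' @examples
#' length(dwt_approx(sin(seq(0, 6, length.out = 752))))  # 24
#' @export
dwt_approx <- function(signal, config = wavelet_config()) {
  dwt_decompose(signal, config)$approx
}

#' Compress a sample record to its feature vector
#'
#' Applies [dwt_approx()] to each of the six voltammograms and concatenates
#' the per-sensor blocks in canonical sensor order: 6 x 24 = 144 coefficients
#' at the defaults.
#'
#' @param rec An `et_sample` from [simulate_sample()] or [ingest_external()].
#' @param config An [wavelet_config()].
#' @return Named numeric vector (`f001`...`f144`) with attribute `sample_id`.
#' @export
compress_sample <- function(rec, config = wavelet_config()) {
  stopifnot(inherits(rec, "et_sample"))
  blocks <- lapply(rec$voltammograms, function(v) dwt_approx(v$currents, config))
  v <- unlist(blocks, use.names = FALSE)
  names(v) <- sprintf("f%03d", seq_along(v))
  attr(v, "sample_id") <- rec$sample_id
  v
}

#' Feature matrix for a list of sample records
#'
#' @param records List of `et_sample` records.
#' @inheritParams compress_sample
#' @return samples x features numeric matrix, rownames = sample ids.
#' @export
compress_records <- function(records, config = wavelet_config()) {
  rows <- lapply(records, compress_sample, config = config)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(records, function(r) r$sample_id, character(1))
  m
}

#' Compression percentage
#'
#' `100 * (1 - n_out / n_in)`; 4512 raw currents to 144 coefficients is a
#' 96.81% compression.
#'
#' @param n_in,n_out Input and output value counts, `n_out <= n_in`.
#' @return Percentage in `[0, 100]`.
#' @export
compression_percent <- function(n_in, n_out) {
  if (n_in <= 0) stop_et("n_in must be positive", class = "domain_error")
  if (n_out > n_in) stop_et("n_out (%s) exceeds n_in (%s)", n_out, n_in,
                            class = "domain_error")
  100 * (1 - n_out / n_in)
}
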