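#' Full factorial concentration grid
#'
#' Cartesian product of `levels` equally spaced levels per factor spanning
#' `[lo, hi]`; the 3-level, 3-factor default gives the 27 calibration
#' standards. A single level returns the domain midpoint.
#'
#' @param levels Levels per factor (>= 1).
#' @param factors Number of factors (>= 1).
#' @param lo,hi Domain bounds (ppm), `lo < hi`.
#' @return `levels^factors` x `factors` numeric matrix.
#' @examples
#' nrow(full_factorial(3, 3, 0, 30))  # 27
#' @export
full_factorial <- function(levels = 3L, factors = 3L, lo = 0, hi = 30) {
  if (lo >= hi) stop_et("lo (%s) must be below hi (%s)", lo, hi, class = "domain_error")
  levels <- as.integer(levels); factors <- as.integer(factors)
  if (levels < 1L || factors < 1L)
    stop_et("levels and factors must be positive", class = "domain_error")
  axis <- if (levels == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = levels)
  as.matrix(expand.grid(rep(list(axis), factors), KEEP.OUT.ATTRS = FALSE))
}

.rot3 <- function(theta) {
  c3 <- cos(theta); s3 <- sin(theta)
  Rx <- matrix(c(1, 0, 0, 0, c3, -s3, 0, s3, c3), 3, byrow = TRUE)
  Ry <- matrix(c(c3, 0, s3, 0, 1, 0, -s3, 0, c3), 3, byrow = TRUE)
  Rz <- matrix(c(c3, -s3, 0, s3, c3, 0, 0, 0, 1), 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

#' Tilt a 3-D design about its centroid
#'
#' Rotates the point cloud by `Rx(theta) %*% Ry(theta) %*% Rz(theta)` about
#' its centroid, then applies one uniform isotropic rescale plus translation
#' so the rotated bounding box sits centered inside `[lo, hi]^3`. Rotation
#' plus isotropic scaling is a similarity map, so all pairwise distance
#' ratios are preserved. A zero tilt returns the input unchanged.
#'
#' @param points n x 3 matrix (ppm).
#' @param tilt_deg Rotation angle applied about each axis (degrees).
#' @param lo,hi Domain bounds the tilted cloud must fit in.
#' @return n x 3 matrix of tilted points, all inside `[lo, hi]^3`.
#' @export
tilt_points <- function(points, tilt_deg = 45, lo = 0, hi = 30) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop_et("tilt_points expects 3-D points, got %d columns", ncol(points),
            class = "shape_error")
  if (tilt_deg == 0) return(points)
  R <- .rot3(tilt_deg * pi / 180)
  ctr <- colMeans(points)
  rot <- sweep(points, 2, ctr) %*% t(R)
  rot <- sweep(rot, 2, ctr, `+`)
  # uniform fit: one scale factor (largest extent governs), then center per axis
  rng <- apply(rot, 2, range)
  ext <- rng[2, ] - rng[1, ]
  s <- (hi - lo) / max(ext)
  mid <- (rng[1, ] + rng[2, ]) / 2
  out <- sweep(rot, 2, mid) * s
  out <- sweep(out, 2, rep((lo + hi) / 2, 3), `+`)
  if (anyDuplicated(round(out, 9)))
    stop_et("tilt produced coincident design points", class = "degenerate_design")
  out
}

#' Random external test set
#'
#' `n` mixtures with each concentration drawn independently and uniformly on
#' `[lo, hi]`; deterministic given `seed`.
#'
#' @param n Number of test samples.
#' @param lo,hi Domain bounds (ppm).
#' @param seed Integer seed.
#' @return n x 3 matrix (ppm).
#' @export
random_test_set <- function(n = 9L, lo = 0, hi = 30, seed = 1L) {
  if (lo >= hi) stop_et("lo must be below hi", class = "domain_error")
  if (n < 1L) stop_et("n must be >= 1", class = "domain_error")
  with_seed(seed, matrix(stats::runif(3 * n, lo, hi), ncol = 3L, byrow = TRUE))
}

#' Calibration design specification
#'
#' Defaults reproduce the canonical plan: a 3-level/3-factor full factorial
#' (27 standards) tilted 45 degrees about each axis inside the 0-30 ppm
#' domain, plus 9 random external test mixtures — a 75%/25% train/test split.
#'
#' @param levels,factors Factorial shape.
#' @param domain_lo,domain_hi Concentration domain (ppm).
#' @param tilt_deg Tilt angle (degrees), in `[0, 90)`.
#' @param n_test External test samples.
#' @param seed Seed for the random test set.
#' @return An object of class `et_design_spec`.
#' @export
design_spec <- function(levels = 3L, factors = 3L, domain_lo = 0,
                        domain_hi = 30, tilt_deg = 45, n_test = 9L,
                        seed = 1L) {
  if (levels < 2L) stop_et("levels must be >= 2", class = "invalid_spec")
  if (factors < 1L) stop_et("factors must be >= 1", class = "invalid_spec")
  if (domain_lo >= domain_hi) stop_et("empty domain", class = "invalid_spec")
  if (tilt_deg < 0 || tilt_deg >= 90)
    stop_et("tilt_deg must lie in [0, 90)", class = "invalid_spec")
  structure(list(levels = as.integer(levels), factors = as.integer(factors),
                 domain_lo = domain_lo, domain_hi = domain_hi,
                 tilt_deg = tilt_deg, n_test = as.integer(n_test),
                 seed = as.integer(seed)),
            class = "et_design_spec")
}

#' Build the concentration design table
#'
#' Tilted factorial training standards labelled `cal01..` plus the random
#' external test rows labelled `ext01..`; at defaults, 27 + 9 rows and a
#' training fraction of exactly 75%.
#'
#' @param spec An [design_spec()].
#' @return `data.frame` with columns `sample_id`, `c_diazepam_ppm`,
#'   `c_flunitrazepam_ppm`, `c_lorazepam_ppm`, `subset` (`train` / `test`).
#' @examples
#' d <- build_design(design_spec())
#' table(d$subset)  # 27 train, 9 test
#' @export
build_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "et_design_spec"))
  train <- full_factorial(spec$levels, spec$factors, spec$domain_lo, spec$domain_hi)
  if (spec$factors == 3L)
    train <- tilt_points(train, spec$tilt_deg, spec$domain_lo, spec$domain_hi)
  if (anyDuplicated(round(train, 9)))
    stop_et("training design has coincident points", class = "degenerate_design")
  rows <- list(data.frame(
    sample_id = sprintf("cal%02d", seq_len(nrow(train))),
    c1 = train[, 1], c2 = train[, 2], c3 = train[, 3],
    subset = "train", stringsAsFactors = FALSE))
  if (spec$n_test > 0L) {
    test <- random_test_set(spec$n_test, spec$domain_lo, spec$domain_hi, spec$seed)
    rows <- c(rows, list(data.frame(
      sample_id = sprintf("ext%02d", seq_len(nrow(test))),
      c1 = test[, 1], c2 = test[, 2], c3 = test[, 3],
      subset = "test", stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  names(out)[2:4] <- paste0("c_", ET_ANALYTES, "_ppm")
  rownames(out) <- NULL
  out
}
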