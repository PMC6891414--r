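#' Triangular cyclic-voltammetry potential grid
#'
#' Builds the potential program of one stabilized cyclic-voltammetry cycle:
#' a triangular sweep from `e_min` up to `e_max` and back, sampled at
#' `n_points` equally spaced potentials (`n_points / 2` on each half-cycle).
#' The default window of -1.5 V to +1.5 V (vs. Ag/AgCl) with 752 points per
#' cycle matches the acquisition convention of the rest of the package: six
#' sensors times 752 currents give the 4512-value raw fingerprint per sample.
#'
#' @param e_min Lower vertex potential (V). Must be `< e_max`.
#' @param e_max Upper vertex potential (V).
#' @param n_points Total points per cycle; even, at least 4.
#'
#' @return An object of class `et_grid`: a list with `e_min`, `e_max`,
#'   `n_points`, `potentials` (length `n_points`) and `direction`
#'   (+1 on the anodic/ascending half, -1 on the cathodic/descending half).
#' @examples
#' g <- et_grid()
#' length(g$potentials)  # 752
#' range(g$potentials)   # -1.5 1.5
#' @export
et_grid <- function(e_min = -1.5, e_max = 1.5, n_points = 752L) {
  if (!is.numeric(e_min) || !is.numeric(e_max) || e_min >= e_max)
    stop_et("e_min (%s) must be strictly below e_max (%s)", e_min, e_max,
            class = "invalid_grid")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 4L || n_points %% 2L != 0L)
    stop_et("n_points must be an even integer >= 4, got %s", n_points,
            class = "invalid_grid")
  half <- n_points %/% 2L
  up <- seq(e_min, e_max, length.out = half)
  down <- seq(e_max, e_min, length.out = half)
  structure(
    list(e_min = e_min, e_max = e_max, n_points = n_points,
         potentials = c(up, down),
         direction = rep(c(1, -1), each = half)),
    class = "et_grid")
}

#' @export
print.et_grid <- function(x, ...) {
  cat(sprintf("Cyclic potential grid: %g -> %g -> %g V, %d points (%.1f mV step)\n",
              x$e_min, x$e_max, x$e_min, x$n_points,
              1000 * (x$e_max - x$e_min) / (x$n_points / 2 - 1)))
  invisible(x)
}

is_et_grid <- function(x) inherits(x, "et_grid")
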