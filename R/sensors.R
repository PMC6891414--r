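#' Phenomenological sensor parameters
#'
#' A sensor is described by its response to each of the three analytes
#' (diazepam, flunitrazepam, lorazepam): a low-concentration sensitivity `S`
#' (uA/ppm), a saturation constant `K` (ppm) giving a Michaelis-type bounded
#' response, a cathodic peak potential `E0` (V) with Gaussian width `w` (V),
#' plus an `anodic_fraction` scaling the mirror peak seen on the ascending
#' half-cycle, a linear baseline slope `b1` (uA/V), a capacitive offset `b0`
#' (uA) that changes sign with sweep direction, and a symmetric, zero-diagonal
#' cross-suppression matrix `G` (1/ppm) modelling competitive interference
#' between analytes at the electrode surface.
#'
#' @param sensor_id Label, one of [et_sensors()] for the shipped bank (any
#'   label is accepted for custom arrays).
#' @param S,K,E0,w Numeric length-3 vectors (one entry per analyte, canonical
#'   order).
#' @param anodic_fraction Scalar in `[0, 1]`.
#' @param b1 Baseline slope (uA/V).
#' @param b0 Capacitive offset (uA).
#' @param G 3x3 symmetric nonnegative matrix with zero diagonal (1/ppm).
#'
#' @return An object of class `et_sensor`.
#' @export
et_sensor <- function(sensor_id, S, K, E0, w, anodic_fraction = 0.3,
                      b1 = 1, b0 = 2, G = matrix(0, 3, 3)) {
  S <- as.numeric(S); K <- as.numeric(K); E0 <- as.numeric(E0); w <- as.numeric(w)
  G <- as.matrix(G)
  if (length(S) != 3L || length(K) != 3L || length(E0) != 3L || length(w) != 3L)
    stop_et("S, K, E0 and w must each have one entry per analyte (3)",
            class = "invalid_sensor")
  if (any(S < 0)) stop_et("sensitivities S must be nonnegative", class = "invalid_sensor")
  if (any(K <= 0)) stop_et("saturation constants K must be positive", class = "invalid_sensor")
  if (any(w <= 0)) stop_et("peak widths w must be positive", class = "invalid_sensor")
  if (anodic_fraction < 0 || anodic_fraction > 1)
    stop_et("anodic_fraction must lie in [0, 1]", class = "invalid_sensor")
  if (!all(dim(G) == c(3L, 3L)) || any(abs(G - t(G)) > 1e-12) ||
      any(diag(G) != 0) || any(G < 0))
    stop_et("G must be a 3x3 symmetric nonnegative matrix with zero diagonal",
            class = "invalid_sensor")
  structure(
    list(sensor_id = as.character(sensor_id),
         S = stats::setNames(S, ET_ANALYTES), K = stats::setNames(K, ET_ANALYTES),
         E0 = stats::setNames(E0, ET_ANALYTES), w = stats::setNames(w, ET_ANALYTES),
         anodic_fraction = anodic_fraction, b1 = b1, b0 = b0,
         G = structure(G, dimnames = list(ET_ANALYTES, ET_ANALYTES))),
    class = "et_sensor")
}

# Mild, shared cross-suppression: analyte pairs compete for electrode surface.
.default_G <- function(g12, g13, g23) {
  G <- matrix(0, 3, 3)
  G[1, 2] <- G[2, 1] <- g12
  G[1, 3] <- G[3, 1] <- g13
  G[2, 3] <- G[3, 2] <- g23
  G
}

#' Default six-sensor bank
#'
#' Package constants describing six electrodes with complementary,
#' non-collinear response profiles for the three benzodiazepines: distinct
#' sensitivity patterns (the 6x3 sensitivity matrix has full column rank) and
#' staggered cathodic peak potentials around the azomethine reduction region.
#' Amplitudes and peak positions are documented package defaults chosen to
#' emulate the qualitative diversity of a real modified-graphite array; they
#' are not measurements.
#'
#' @return Named list of six [et_sensor()] objects in canonical order.
#' @examples
#' bank <- et_default_bank()
#' sapply(bank, function(s) s$S)  # 3 x 6 sensitivity profile
#' @export
et_default_bank <- function() {
  mk <- function(id, S, E0shift, K, w, af, b1, b0, G)
    et_sensor(id, S = S, K = K,
              E0 = c(-0.95, -1.10, -0.80) + E0shift, w = w,
              anodic_fraction = af, b1 = b1, b0 = b0, G = G)
  list(
    GEC  = mk("GEC",  c(1.00, 0.60, 0.80), c( 0.00,  0.00,  0.00),
              c(40, 45, 50), c(0.12, 0.14, 0.11), 0.30, 1.2, 2.0,
              .default_G(0.004, 0.006, 0.003)),
    CuO  = mk("CuO",  c(1.40, 0.90, 0.40), c( 0.05, -0.03,  0.04),
              c(35, 50, 45), c(0.10, 0.13, 0.15), 0.25, 1.8, 3.0,
              .default_G(0.006, 0.003, 0.005)),
    Cu   = mk("Cu",   c(0.70, 1.20, 0.60), c(-0.04,  0.05, -0.05),
              c(55, 38, 48), c(0.14, 0.11, 0.13), 0.35, 0.8, 1.5,
              .default_G(0.003, 0.005, 0.006)),
    PtNP = mk("PtNP", c(1.10, 0.50, 1.30), c( 0.03, -0.06,  0.06),
              c(45, 60, 36), c(0.11, 0.15, 0.10), 0.40, 1.5, 2.5,
              .default_G(0.005, 0.004, 0.004)),
    WO3  = mk("WO3",  c(0.50, 1.00, 1.10), c(-0.06,  0.04, -0.03),
              c(60, 42, 40), c(0.15, 0.10, 0.14), 0.20, 1.0, 3.5,
              .default_G(0.004, 0.005, 0.003)),
    Pt   = mk("Pt",   c(0.90, 0.80, 0.30), c( 0.06, -0.05,  0.05),
              c(48, 44, 58), c(0.13, 0.12, 0.12), 0.30, 0.6, 1.0,
              .default_G(0.003, 0.004, 0.005))
  )
}

#' Low-concentration sensitivity matrix of a bank
#'
#' @param bank List of [et_sensor()] objects.
#' @return Sensors x analytes matrix of `S` values (uA/ppm). Full column rank
#'   for the default bank, the prerequisite for resolving the ternary mixture.
#' @export
sensitivity_matrix <- function(bank = et_default_bank()) {
  m <- t(vapply(bank, function(s) s$S, numeric(3)))
  dimnames(m) <- list(vapply(bank, function(s) s$sensor_id, character(1)), ET_ANALYTES)
  m
}
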