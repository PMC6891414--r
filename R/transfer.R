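# Classical MATLAB-style neuron transfer functions. Each entry supplies the
# forward map `f` and the (sub)derivative `d` expressed in terms of the input
# x and the activation y = f(x). hardlims has zero subgradient everywhere, so
# networks using it do not learn — it stays in the registry for completeness
# of the historical five-function search grid.
.TRANSFER <- list(
  purelin  = list(f = function(x) x,
                  d = function(x, y) rep(1, length(x))),
  tansig   = list(f = function(x) tanh(x),
                  d = function(x, y) 1 - y^2),
  logsig   = list(f = function(x) 1 / (1 + exp(-x)),
                  d = function(x, y) y * (1 - y)),
  satlins  = list(f = function(x) pmin(pmax(x, -1), 1),
                  d = function(x, y) as.numeric(x > -1 & x < 1)),
  hardlims = list(f = function(x) ifelse(x >= 0, 1, -1),
                  d = function(x, y) rep(0, length(x)))
)

#' Neuron transfer functions
#'
#' Applies one of the five classical transfer functions elementwise:
#' `purelin` (identity), `tansig` (hyperbolic tangent, range (-1,1)),
#' `logsig` (logistic, range (0,1)), `satlins` (symmetric saturating linear,
#' clamp to \[-1,1\]) and `hardlims` (symmetric hard limit, sign to
#' \{-1,+1\}).
#'
#' @param name One of `"purelin"`, `"tansig"`, `"logsig"`, `"satlins"`,
#'   `"hardlims"`.
#' @param x Numeric input (vector or matrix).
#' @return Transformed values, same shape as `x`.
#' @examples
#' transfer("satlins", c(-2.5, -0.3, 0.4, 2.5))
#' @export
transfer <- function(name, x) {
  fn <- .TRANSFER[[name]]
  if (is.null(fn))
    stop_et("unknown transfer function '%s' (available: %s)", name,
            paste(names(.TRANSFER), collapse = ", "), class = "registry_error")
  y <- fn$f(x)
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}

#' @rdname transfer
#' @return `transfer_names()` returns the registry names.
#' @export
transfer_names <- function() names(.TRANSFER)

transfer_deriv <- function(name, x, y) {
  d <- .TRANSFER[[name]]$d(x, y)
  if (is.matrix(x)) dim(d) <- dim(x)
  d
}

# whether the activation is bounded (prediction box guarantee for the head)
transfer_bounded <- function(name) name %in% c("tansig", "logsig", "satlins", "hardlims")
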