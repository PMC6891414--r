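# affine map onto [-span, span] from training min/max. `global = TRUE` uses
# one affine for every column (appropriate when columns share units, as the
# wavelet coefficients do — per-feature scaling would blow up baseline-only
# coefficients whose across-sample variation is pure noise). Zero-variance
# columns get half = 1 so they map to the constant 0.
.fit_scaling <- function(m, global = FALSE, span = 1) {
  if (global) {
    mn <- rep(min(m), ncol(m)); mx <- rep(max(m), ncol(m))
  } else {
    mn <- apply(m, 2, min); mx <- apply(m, 2, max)
  }
  center <- (mx + mn) / 2
  half <- (mx - mn) / 2 / span
  center[half == 0] <- mx[half == 0]
  half[half == 0] <- 1
  list(center = center, half = half)
}
.apply_scaling <- function(m, sc) sweep(sweep(m, 2, sc$center), 2, sc$half, "/")
.invert_scaling <- function(m, sc) sweep(sweep(m, 2, sc$half, "*"), 2, sc$center, "+")

.init_weights <- function(n_in, n_hidden, n_out, seed) {
  with_seed(seed, {
    list(W1 = matrix(stats::runif(n_hidden * n_in, -0.5, 0.5) / sqrt(n_in),
                     n_hidden, n_in),
         b1 = stats::runif(n_hidden, -0.5, 0.5) / sqrt(n_in),
         W2 = matrix(stats::runif(n_out * n_hidden, -0.5, 0.5) / sqrt(n_hidden),
                     n_out, n_hidden),
         b2 = stats::runif(n_out, -0.5, 0.5) / sqrt(n_hidden))
  })
}

# scaled-space forward pass; Xs is n x p, returns q x n activations
.mlp_forward_scaled <- function(w, Xs, hidden_fn, output_fn) {
  Z1 <- w$W1 %*% t(Xs) + w$b1
  A1 <- transfer(hidden_fn, Z1)
  Z2 <- w$W2 %*% A1 + w$b2
  A2 <- transfer(output_fn, Z2)
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2)
}

#' Single-hidden-layer perceptron calibration model
#'
#' Fits a fully connected feed-forward network with one hidden layer by
#' deterministic full-batch quasi-Newton training (L-BFGS-B with analytic
#' backpropagated gradients), minimising the mean squared error on scaled
#' targets. The canonical calibration architecture is 144 inputs (24 wavelet
#' coefficients per sensor), 5 hidden `satlins` neurons and 3 `tansig`
#' output neurons, one per analyte.
#'
#' Scaling: inputs are mapped affinely to \[-1, 1\] from the training
#' minima/maxima — by default with a single global map, because the wavelet
#' coefficients share units (uA) and per-feature scaling would amplify
#' baseline-only coefficients whose across-sample variation is mostly
#' measurement noise. Targets are mapped per analyte to
#' \[-`target_span`, `target_span`\]; the default 0.8 keeps the design
#' extremes out of the asymptotic region of saturating output neurons
#' (`tansig`/`logsig`), where fitting would push weights toward infinity.
#' New data are always scaled with the training parameters.
#'
#' Training is seeded and fully deterministic: the same data, architecture
#' and seed reproduce identical weights. The minimiser's line search only
#' accepts descent steps, so the final training loss never exceeds the
#' initial one (for `hardlims`, whose subgradient is zero everywhere, the
#' weights simply stay at their initial values).
#'
#' @param x Numeric feature matrix, samples x features.
#' @param y Numeric target matrix (samples x analytes, ppm) or vector.
#' @param hidden Hidden-layer size.
#' @param hidden_fn,output_fn Transfer-function names, see [transfer()].
#' @param epochs Maximum quasi-Newton iterations.
#' @param seed Integer seed for weight initialisation.
#' @param input_scaling `"global"` (one affine map for all features, the
#'   default) or `"per-feature"`.
#' @param target_span Half-width of the scaled-target interval, in (0, 1].
#' @param tol Relative loss-improvement tolerance for early stopping
#'   (`factr`-style convergence control).
#' @return Object of class `et_mlp` with weights, scalings and architecture.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(60), 20, 3)
#' y <- x %*% c(2, -1, 0.5)
#' fit <- et_mlp(x, y, hidden = 3, hidden_fn = "purelin", output_fn = "purelin",
#'               epochs = 500, seed = 1)
#' max(abs(predict(fit, x) - y))
#' @export
et_mlp <- function(x, y, hidden = 5L, hidden_fn = "satlins",
                   output_fn = "tansig", epochs = 2000L, seed = 1L,
                   input_scaling = c("global", "per-feature"),
                   target_span = 0.8, tol = 1e-10) {
  x <- as.matrix(x); y <- as.matrix(y)
  input_scaling <- match.arg(input_scaling)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_et("training data must be finite", class = "data_error")
  if (nrow(x) != nrow(y))
    stop_et("x and y row counts differ (%d vs %d)", nrow(x), nrow(y),
            class = "shape_error")
  hidden <- as.integer(hidden)
  if (nrow(x) < hidden)
    stop_et("need at least as many training rows (%d) as hidden units (%d)",
            nrow(x), hidden, class = "data_error")
  stopifnot(hidden_fn %in% transfer_names(), output_fn %in% transfer_names())
  if (target_span <= 0 || target_span > 1)
    stop_et("target_span must lie in (0, 1]", class = "data_error")

  in_sc <- .fit_scaling(x, global = input_scaling == "global")
  out_sc <- .fit_scaling(y, span = target_span)
  Xs <- .apply_scaling(x, in_sc)
  Ys <- t(.apply_scaling(y, out_sc))          # q x n
  n <- nrow(x); p <- ncol(x); q <- ncol(y)

  w0 <- .init_weights(p, hidden, q, seed)
  shapes <- lapply(w0, function(m) dim(m) %||% length(m))
  pack <- function(w) unlist(w, use.names = FALSE)
  unpack <- function(v) {
    out <- list(); i <- 0L
    for (nm in names(w0)) {
      len <- prod(shapes[[nm]])
      piece <- v[(i + 1L):(i + len)]
      out[[nm]] <- if (length(shapes[[nm]]) == 2L)
        matrix(piece, shapes[[nm]][1], shapes[[nm]][2]) else piece
      i <- i + len
    }
    out
  }

  loss_fn <- function(v) {
    fw <- .mlp_forward_scaled(unpack(v), Xs, hidden_fn, output_fn)
    mean((fw$A2 - Ys)^2)
  }
  grad_fn <- function(v) {
    w <- unpack(v)
    fw <- .mlp_forward_scaled(w, Xs, hidden_fn, output_fn)
    dZ2 <- (2 / (n * q)) * (fw$A2 - Ys) * transfer_deriv(output_fn, fw$Z2, fw$A2)
    dZ1 <- (t(w$W2) %*% dZ2) * transfer_deriv(hidden_fn, fw$Z1, fw$A1)
    pack(list(W1 = dZ1 %*% Xs, b1 = rowSums(dZ1),
              W2 = dZ2 %*% t(fw$A1), b2 = rowSums(dZ2)))
  }

  theta0 <- pack(w0)
  loss0 <- loss_fn(theta0)
  opt <- stats::optim(theta0, loss_fn, grad_fn, method = "L-BFGS-B",
                      control = list(maxit = as.integer(epochs),
                                     factr = tol / .Machine$double.eps))
  # keep the better of initial and optimised weights (descent guarantee)
  if (opt$value <= loss0) {
    theta <- opt$par; loss <- opt$value
  } else {
    theta <- theta0; loss <- loss0
  }

  structure(
    list(weights = unpack(theta),
         architecture = list(n_input = p, n_hidden = hidden, n_output = q,
                             hidden_fn = hidden_fn, output_fn = output_fn),
         input_scaling = in_sc, target_scaling = out_sc,
         scaling_mode = input_scaling, target_span = target_span,
         seed = as.integer(seed),
         epochs_run = unname(opt$counts["function"]),
         initial_loss = loss0, final_loss = loss,
         feature_names = colnames(x),
         analytes = colnames(y) %||% ET_ANALYTES[seq_len(q)],
         x = x, y = y,
         call = match.call()),
    class = "et_mlp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.et_mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == 1L && object$architecture$n_input > 1L)
    newdata <- t(newdata)
  if (ncol(newdata) != object$architecture$n_input)
    stop_et("feature length %d does not match network input size %d",
            ncol(newdata), object$architecture$n_input, class = "shape_error")
  Xs <- .apply_scaling(newdata, object$input_scaling)
  A2 <- .mlp_forward_scaled(object$weights, Xs,
                            object$architecture$hidden_fn,
                            object$architecture$output_fn)$A2
  out <- .invert_scaling(t(A2), object$target_scaling)
  colnames(out) <- object$analytes
  rownames(out) <- rownames(newdata)
  out
}

#' @export
coef.et_mlp <- function(object, ...) object$weights

#' @export
fitted.et_mlp <- function(object, ...) {
  if (is.null(object$x)) stop_et("model was restored without training data",
                                 class = "data_error")
  predict(object, object$x)
}

#' @export
residuals.et_mlp <- function(object, ...) object$y - fitted(object)

#' Obtained-versus-expected diagnostic plot
#'
#' One panel per analyte, predicted concentration against the reference
#' value for the training data (and optionally an external set), with the
#' identity line and the fitted regression line.
#'
#' @param x An `et_mlp`.
#' @param newdata,newy Optional external feature matrix and reference
#'   concentrations, drawn as open points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.et_mlp <- function(x, newdata = NULL, newy = NULL, ...) {
  obt <- fitted(x); exp_ <- x$y
  q <- ncol(exp_)
  op <- graphics::par(mfrow = c(1, q), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  has_ext <- !is.null(newdata) && !is.null(newy)
  if (has_ext) pext <- predict(x, newdata)
  for (j in seq_len(q)) {
    rngx <- range(exp_[, j], if (has_ext) newy[, j])
    rngy <- range(obt[, j], if (has_ext) pext[, j])
    graphics::plot(exp_[, j], obt[, j], pch = 16,
                   xlim = rngx, ylim = rngy,
                   xlab = "expected (ppm)", ylab = "obtained (ppm)",
                   main = x$analytes[j], ...)
    if (has_ext) graphics::points(newy[, j], pext[, j], pch = 1)
    graphics::abline(0, 1, lty = 2)
    graphics::abline(stats::lm(obt[, j] ~ exp_[, j]), col = 2)
  }
  invisible(x)
}

#' @export
print.et_mlp <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("Feed-forward calibration network %d-%d-%d (%s / %s)\n",
              a$n_input, a$n_hidden, a$n_output, a$hidden_fn, a$output_fn))
  cat(sprintf("  trained %d epochs, final scaled MSE %.3g, seed %d\n",
              x$epochs_run, x$final_loss, x$seed))
  invisible(x)
}

#' @export
summary.et_mlp <- function(object, ...) {
  out <- list(architecture = object$architecture,
              n_weights = length(unlist(object$weights)),
              epochs_run = object$epochs_run,
              final_loss = object$final_loss)
  class(out) <- "summary.et_mlp"
  out
}

#' @export
print.summary.et_mlp <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("Architecture : %d-%d-%d\n", a$n_input, a$n_hidden, a$n_output))
  cat(sprintf("Transfer fns : hidden %s, output %s\n", a$hidden_fn, a$output_fn))
  cat(sprintf("Parameters   : %d weights/biases\n", x$n_weights))
  cat(sprintf("Training     : %d epochs, final scaled MSE %.4g\n",
              x$epochs_run, x$final_loss))
  invisible(x)
}

#' Serialize / restore a fitted network as flat JSON
#'
#' @param model An `et_mlp`.
#' @param path Output (input) file path.
#' @return `et_mlp_write` returns `path` invisibly; `et_mlp_read` the model.
#' @export
et_mlp_write <- function(model, path) {
  stopifnot(inherits(model, "et_mlp"))
  payload <- list(
    architecture = model$architecture,
    weights = lapply(model$weights, function(m) as.numeric(t(m))),  # row-major
    input_scaling = model$input_scaling, target_scaling = model$target_scaling,
    scaling_mode = model$scaling_mode, target_span = model$target_span,
    seed = model$seed, analytes = model$analytes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname et_mlp_write
#' @export
et_mlp_read <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- p$architecture
  w <- list(
    W1 = matrix(p$weights$W1, a$n_hidden, a$n_input, byrow = TRUE),
    b1 = as.numeric(p$weights$b1),
    W2 = matrix(p$weights$W2, a$n_output, a$n_hidden, byrow = TRUE),
    b2 = as.numeric(p$weights$b2))
  structure(list(weights = w, architecture = a,
                 input_scaling = lapply(p$input_scaling, as.numeric),
                 target_scaling = lapply(p$target_scaling, as.numeric),
                 scaling_mode = p$scaling_mode, target_span = p$target_span,
                 seed = p$seed, epochs_run = NA_integer_,
                 initial_loss = NA_real_, final_loss = NA_real_,
                 feature_names = NULL, analytes = p$analytes,
                 call = NULL),
            class = "et_mlp")
}
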