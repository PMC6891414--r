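#' Normalized root mean squared error
#'
#' `sqrt(sum((obtained - expected)^2) / sum(expected^2))` over all entries —
#' residual norm relative to the norm of the reference concentrations. The
#' alternative range normalization
#' `rmse / (max(expected) - min(expected))` is available for comparison with
#' literature using that convention.
#'
#' NRMSE is invariant to a common rescaling of both matrices.
#'
#' @param expected,obtained Equal-shape numeric matrices or vectors (ppm).
#' @param normalization `"norm"` (default) or `"range"`.
#' @return Dimensionless nonnegative scalar.
#' @examples
#' nrmse(c(10, 20, 30), c(11, 19, 31))  # sqrt(3/1400) = 0.0463
#' @export
nrmse <- function(expected, obtained, normalization = c("norm", "range")) {
  normalization <- match.arg(normalization)
  expected <- as.matrix(expected); obtained <- as.matrix(obtained)
  if (!all(dim(expected) == dim(obtained)))
    stop_et("expected and obtained shapes differ", class = "shape_error")
  if (length(expected) == 0L) stop_et("empty input", class = "shape_error")
  rss <- sum((obtained - expected)^2)
  if (normalization == "norm") {
    denom <- sum(expected^2)
    if (denom == 0)
      stop_et("all expected values are zero; normalization undefined",
              class = "undefined_normalization")
    sqrt(rss / denom)
  } else {
    rng <- diff(range(expected))
    if (rng == 0)
      stop_et("expected values have zero range; normalization undefined",
              class = "undefined_normalization")
    sqrt(rss / length(expected)) / rng
  }
}

#' Obtained-versus-expected regression line
#'
#' Ordinary least squares of obtained on expected concentrations; ideal
#' calibration gives slope 1, intercept 0, correlation 1. Both the
#' correlation coefficient `r` and its square are reported.
#'
#' @param expected,obtained Numeric vectors (ppm), at least 3 points,
#'   `expected` with nonzero variance.
#' @return List with `slope`, `intercept`, `r`, `r_squared`, `n`.
#' @export
regression_line <- function(expected, obtained) {
  expected <- as.numeric(expected); obtained <- as.numeric(obtained)
  if (length(expected) != length(obtained))
    stop_et("length mismatch", class = "shape_error")
  if (length(expected) < 3L)
    stop_et("need at least 3 points, got %d", length(expected),
            class = "degenerate_fit")
  if (stats::var(expected) == 0)
    stop_et("expected values have zero variance", class = "degenerate_fit")
  fit <- stats::lm(obtained ~ expected)
  r <- stats::cor(expected, obtained)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = r^2, n = length(expected))
}

#' Evaluate a calibration model on train and test subsets
#'
#' Computes, per analyte and subset, the obtained-versus-expected regression
#' line and NRMSE, plus a combined row per subset that pools the three
#' analytes into one NRMSE ratio (not the mean of per-analyte values) and
#' one pooled regression — eight rows at the canonical three-analyte setup.
#'
#' @param model A fitted `et_mlp` (or any object with a `predict` method
#'   returning a samples x analytes matrix).
#' @param x_train,y_train,x_test,y_test Feature and concentration matrices;
#'   rownames (sample ids) are used to verify the subsets are disjoint.
#' @return `data.frame` with columns `subset`, `analyte`, `slope`,
#'   `intercept_ppm`, `r`, `r_squared`, `nrmse`, `combined_nrmse`.
#' @export
evaluate_model <- function(model, x_train, y_train, x_test, y_test) {
  if (!is.null(rownames(x_train)) && !is.null(rownames(x_test))) {
    overlap <- intersect(rownames(x_train), rownames(x_test))
    if (length(overlap))
      stop_et("train and test subsets overlap (e.g. %s)", overlap[1],
              class = "protocol_error")
  }
  one_subset <- function(xx, yy, tag) {
    yy <- as.matrix(yy)
    pred <- predict(model, xx)
    comb <- nrmse(yy, pred)
    rows <- lapply(seq_len(ncol(yy)), function(j) {
      rl <- regression_line(yy[, j], pred[, j])
      data.frame(subset = tag, analyte = colnames(yy)[j] %||% ET_ANALYTES[j],
                 slope = rl$slope, intercept_ppm = rl$intercept,
                 r = rl$r, r_squared = rl$r_squared,
                 nrmse = nrmse(yy[, j], pred[, j]), combined_nrmse = comb,
                 stringsAsFactors = FALSE)
    })
    pooled <- regression_line(as.numeric(yy), as.numeric(pred))
    rows <- c(rows, list(data.frame(
      subset = tag, analyte = "combined", slope = pooled$slope,
      intercept_ppm = pooled$intercept, r = pooled$r,
      r_squared = pooled$r_squared, nrmse = comb, combined_nrmse = comb,
      stringsAsFactors = FALSE)))
    do.call(rbind, rows)
  }
  out <- rbind(one_subset(x_train, y_train, "train"),
               one_subset(x_test, y_test, "test"))
  rownames(out) <- NULL
  out
}
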