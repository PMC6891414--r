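#' Exhaustive architecture search
#'
#' Trains every combination of hidden-layer size and hidden/output transfer
#' function on the training standards and scores each by k-fold
#' cross-validated combined NRMSE (predictions pooled over held-out folds,
#' in concentration units). The default grid — hidden sizes 2 to 9 crossed
#' with the five classical transfer functions in both layers — has
#' 8 x 5 x 5 = 200 configurations. The external test set plays no part in
#' selection. The winner (minimum CV NRMSE; first in scan order on ties) is
#' refitted on the full training set.
#'
#' @param x,y Training features and concentrations (matrices).
#' @param hidden Integer vector of hidden sizes to scan.
#' @param hidden_fns,output_fns Transfer-function names to scan.
#' @param folds Number of CV folds.
#' @param seed Master seed (fold assignment and every training run derive
#'   their streams from it).
#' @param epochs Training epochs per CV fit.
#' @param final_epochs Epochs for the winner's refit on all rows.
#' @return Object of class `et_search`: `results` (one row per configuration,
#'   scan order, with `hidden_size`, `hidden_fn`, `output_fn`, `cv_nrmse`),
#'   `best` (winning row), `model` (refitted `et_mlp`), `grid_size`, `folds`.
#' @export
architecture_search <- function(x, y, hidden = 2:9,
                                hidden_fns = transfer_names(),
                                output_fns = transfer_names(),
                                folds = 3L, seed = 1L, epochs = 600L,
                                final_epochs = 2000L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (length(hidden) == 0L || length(hidden_fns) == 0L || length(output_fns) == 0L)
    stop_et("empty search grid", class = "configuration_error")
  if (n < folds) stop_et("need at least as many rows as folds", class = "data_error")

  fold_id <- with_seed(derive_seed(seed, "folds"), sample(rep_len(seq_len(folds), n)))
  grid <- expand.grid(hidden_size = as.integer(hidden),
                      hidden_fn = hidden_fns, output_fn = output_fns,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- grid[i, ]
    pred <- matrix(NA_real_, n, ncol(y))
    ok <- TRUE
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (sum(tr) < cfg$hidden_size) { ok <- FALSE; break }
      fit <- et_mlp(x[tr, , drop = FALSE], y[tr, , drop = FALSE],
                    hidden = cfg$hidden_size, hidden_fn = cfg$hidden_fn,
                    output_fn = cfg$output_fn, epochs = epochs,
                    seed = derive_seed(seed, i, f))
      pred[!tr, ] <- predict(fit, x[!tr, , drop = FALSE])
    }
    scores[i] <- if (ok) nrmse(y, pred) else Inf
  }
  grid$cv_nrmse <- scores
  best_i <- which.min(scores)
  model <- et_mlp(x, y, hidden = grid$hidden_size[best_i],
                  hidden_fn = grid$hidden_fn[best_i],
                  output_fn = grid$output_fn[best_i],
                  epochs = final_epochs, seed = derive_seed(seed, "final"))
  structure(list(results = grid, best = grid[best_i, ], model = model,
                 grid_size = nrow(grid), folds = folds, seed = seed),
            class = "et_search")
}

#' @export
print.et_search <- function(x, ...) {
  cat(sprintf("Architecture search: %d configurations, %d-fold CV\n",
              x$grid_size, x$folds))
  cat(sprintf("Winner: %d hidden (%s / %s), CV NRMSE %.4g\n",
              x$best$hidden_size, x$best$hidden_fn, x$best$output_fn,
              x$best$cv_nrmse))
  invisible(x)
}
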