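#' Principal component analysis by SVD
#'
#' Column-mean centering followed by singular value decomposition, with the
#' deterministic sign convention that each loading vector's
#' largest-magnitude entry is positive. No autoscaling is applied: the
#' voltammetric variables share units (uA), so centering alone preserves the
#' relative current magnitudes.
#'
#' @param x Numeric matrix, samples x variables, at least 2 rows.
#' @param n_components Components to retain;
#'   at most `min(nrow(x) - 1, ncol(x))`.
#' @return Object of class `et_pca`: `scores` (samples x components),
#'   `loadings` (variables x components), `explained_variance_fraction`
#'   (per retained component, of the total variance), `center`, `sdev`.
#' @export
et_pca <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_et("need at least 2 rows", class = "rank_error")
  kmax <- min(nrow(x) - 1L, ncol(x))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > kmax)
    stop_et("n_components must lie in [1, %d], got %d", kmax, n_components,
            class = "rank_error")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(sv$v))) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) { sv$v[, k] <- -sv$v[, k]; sv$u[, k] <- -sv$u[, k] }
  }
  keep <- seq_len(n_components)
  var_total <- sum(sv$d^2)
  structure(
    list(scores = sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components),
         loadings = sv$v[, keep, drop = FALSE],
         explained_variance_fraction = sv$d[keep]^2 / var_total,
         singular_values = sv$d, center = ctr,
         n_components = n_components),
    class = "et_pca")
}

#' @export
print.et_pca <- function(x, ...) {
  cat(sprintf("PCA: %d components, explained variance %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = " + ")))
  invisible(x)
}

#' Sensor-array complementarity diagnostic
#'
#' Emulates the classical array-qualification experiment: `n_replicates`
#' single-analyte solutions of each compound at a fixed concentration are
#' measured with all six sensors; each (sensor, replicate) voltammogram is
#' one PCA row. The first two principal-component scores are summarised by
#' per-(sensor, compound) centroids and a mean silhouette width over
#' compound-wise groups — positive silhouette means the compounds separate
#' beyond the replicate scatter, the prerequisite for mixture resolution.
#'
#' @param bank Sensor bank (list of [et_sensor()]).
#' @param grid An [et_grid()].
#' @param noise An [noise_model()] or `NULL` for noise-free replicates.
#' @param n_replicates Replicates per compound.
#' @param concentration Single-analyte concentration (ppm).
#' @return Object of class `et_complementarity`: `scores` (data.frame
#'   `sensor_id`, `compound`, `replicate`, `pc1`, `pc2`), `centroids`,
#'   `mean_silhouette`, `pca`.
#' @export
complementarity_report <- function(bank = et_default_bank(), grid = et_grid(),
                                   noise = noise_model(), n_replicates = 5L,
                                   concentration = 25) {
  if (length(ET_ANALYTES) < 2L)
    stop_et("need at least 2 compounds", class = "diagnostic_error")
  rows <- list(); meta <- list(); idx <- 0L
  for (a in seq_along(ET_ANALYTES)) {
    conc <- numeric(3); conc[a] <- concentration
    for (r in seq_len(n_replicates)) {
      rec <- simulate_sample(conc, bank, grid, noise,
                             sample_id = sprintf("%s_rep%d", ET_ANALYTES[a], r))
      for (s in seq_along(rec$voltammograms)) {
        idx <- idx + 1L
        rows[[idx]] <- rec$voltammograms[[s]]$currents
        meta[[idx]] <- data.frame(sensor_id = rec$voltammograms[[s]]$sensor_id,
                                  compound = ET_ANALYTES[a], replicate = r,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  X <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  pca <- et_pca(X, 2L)
  scores <- cbind(meta, pc1 = pca$scores[, 1], pc2 = pca$scores[, 2])
  centroids <- stats::aggregate(scores[, c("pc1", "pc2")],
                                by = scores[c("sensor_id", "compound")], mean)
  if (all(abs(as.matrix(centroids[, c("pc1", "pc2")])) < 1e-12))
    stop_et("degenerate diagnostic: all score centroids at the origin",
            class = "diagnostic_error")
  sil <- cluster::silhouette(as.integer(factor(scores$compound)),
                             stats::dist(scores[, c("pc1", "pc2")]))
  structure(list(scores = scores, centroids = centroids,
                 mean_silhouette = mean(sil[, "sil_width"]), pca = pca),
            class = "et_complementarity")
}

#' @export
print.et_complementarity <- function(x, ...) {
  cat(sprintf("Complementarity diagnostic: %d score rows, mean silhouette %.3f\n",
              nrow(x$scores), x$mean_silhouette))
  cat(sprintf("PC1+PC2 explained variance: %.1f%%\n",
              100 * sum(x$pca$explained_variance_fraction)))
  invisible(x)
}

#' Score plot of the complementarity diagnostic
#'
#' @param x An `et_complementarity`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.et_complementarity <- function(x, ...) {
  comp <- factor(x$scores$compound)
  graphics::plot(x$scores$pc1, x$scores$pc2, col = as.integer(comp),
                 pch = as.integer(factor(x$scores$sensor_id)),
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$pca$explained_variance_fraction[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$pca$explained_variance_fraction[2]),
                 ...)
  graphics::legend("topright", legend = levels(comp),
                   col = seq_along(levels(comp)), pch = 16, cex = 0.8)
  invisible(x)
}
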