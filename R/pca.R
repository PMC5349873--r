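# Correlation-matrix PCA of feature tables. Markers live on wildly different
# scales (correlations in [-1,1] next to raw intensities), so columns are
# z-scored (population SD) before the eigendecomposition; zero-variance
# markers carry no information and are dropped with a warning.

#' Standardize marker columns to mean 0, SD 1
#'
#' Population-SD z-scoring; constant markers are dropped with a warning.
#'
#' @param table a [feature_table()].
#' @return a `feature_table` with standardized marker columns.
#' @export
standardize_features <- function(table) {
  mk <- marker_names(table)
  X <- marker_matrix(table)
  n <- nrow(X)
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sdev > 0
  if (!any(keep)) stop("all marker columns have zero variance")
  if (any(!keep))
    warning("dropping ", sum(!keep), " zero-variance marker(s): ",
            paste(utils::head(mk[!keep], 5), collapse = ", "))
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  feature_table(table$subject_id, table$grade,
                as.data.frame(Z, check.names = FALSE))
}

#' Project a standardized feature table onto principal components
#'
#' Eigendecomposition of the (population) covariance of the standardized
#' markers; components ordered by eigenvalue with a deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#'
#' @param table a standardized [feature_table()] (see
#'   [standardize_features()]).
#' @param n_components number of components to retain (default 2).
#' @return a `pca_projection`: `loadings` (markers x components, orthonormal),
#'   `explained` (variance fractions), `scores` (subjects x components),
#'   `grade`, `subject_id`.
#' @export
pca_project <- function(table, n_components = 2L) {
  mk <- marker_names(table)
  if (nrow(table) < 3L) stop("need at least 3 subjects")
  if (length(mk) < n_components)
    stop("fewer markers (", length(mk), ") than components requested")
  Z <- marker_matrix(table)
  Z <- sweep(Z, 2, colMeans(Z))          # tolerate not-quite-centered input
  C <- crossprod(Z) / nrow(Z)
  eig <- eigen(C, symmetric = TRUE)
  keep <- seq_len(n_components)
  load <- eig$vectors[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- mk
  colnames(load) <- paste0("PC", keep)
  scores <- Z %*% load
  structure(list(loadings = load,
                 explained = eig$values[keep] / sum(eig$values),
                 eigenvalues = eig$values,
                 scores = scores,
                 grade = table$grade,
                 subject_id = table$subject_id),
            class = "pca_projection")
}

#' Standardized between-class centroid separation in PC space
#'
#' Euclidean distance between the HG and LG score centroids divided by the
#' pooled within-class standard deviation (averaged over the retained
#' components). A quantitative surrogate for "the two grades separate in the
#' first two components".
#'
#' @param projection a `pca_projection`.
#' @return nonnegative scalar (distance in pooled-SD units).
#' @export
pca_separation <- function(projection) {
  stopifnot(inherits(projection, "pca_projection"))
  S <- projection$scores
  g <- projection$grade
  if (length(unique(g)) < 2L) stop("both grades required")
  c1 <- colMeans(S[g == 1L, , drop = FALSE])
  c0 <- colMeans(S[g == 0L, , drop = FALSE])
  n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  pooled_var <- vapply(seq_len(ncol(S)), function(j) {
    ((n1 - 1) * stats::var(S[g == 1L, j]) +
       (n0 - 1) * stats::var(S[g == 0L, j])) / (n1 + n0 - 2)
  }, numeric(1))
  sqrt(sum((c1 - c0)^2)) / sqrt(mean(pooled_var))
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("pca_projection: %d subjects, %d components (%s of variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " + ")))
  invisible(x)
}

#' Scatter plot of the first two PC scores colored by grade
#' @param x a `pca_projection`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pca_projection <- function(x, ...) {
  S <- x$scores
  graphics::plot(S[, 1], S[, 2],
                 col = ifelse(x$grade == 1L, "firebrick", "steelblue"),
                 pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  graphics::legend("topright", legend = c("HG", "LG"), pch = 19,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
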