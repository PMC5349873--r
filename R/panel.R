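# Maximum-likelihood logistic panels and the exhaustive AIC subset search.
#
# Fitting is iteratively reweighted least squares (Newton) on z-scored
# markers. With ~50 subjects and up to 15 candidate markers, perfect
# separation is common in subsets; a diverging fit is flagged and refit with
# a small L2 penalty on the non-intercept coefficients so the exhaustive
# search stays total. AIC always uses the unpenalized log-likelihood at the
# returned coefficients.

# |beta| beyond this on z-scored markers means (quasi-)separation: legitimate
# ML fits on standardized data live well below it, while separated fits march
# past it within a few Newton steps before the step size can stall.
.COEF_DIVERGED <- 15

# IRLS core on an already-centered/scaled design (no intercept column).
# Returns list(beta = c(intercept, slopes), ll, converged, separation).
.irls <- function(Z, y, ridge = 0, max_iter = 100L, tol = 1e-8) {
  n <- length(y)
  p <- ncol(Z)
  X <- cbind(1, Z)
  beta <- numeric(p + 1L)
  pen <- c(0, rep(ridge, p))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X, X * w)
    diag(A) <- diag(A) + n * pen
    bnew <- tryCatch(drop(solve(A, crossprod(X, w * z))),
                     error = function(e) NULL)
    if (is.null(bnew) || any(!is.finite(bnew)) ||
        max(abs(bnew)) > .COEF_DIVERGED) {
      # diverging (typically separation): report the last in-bounds iterate
      return(list(beta = beta, ll = .bernoulli_ll(X, beta, y),
                  converged = FALSE, separation = TRUE))
    }
    delta <- max(abs(bnew - beta))
    beta <- bnew
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta, ll = .bernoulli_ll(X, beta, y), converged = converged,
       separation = FALSE)
}

.bernoulli_ll <- function(X, beta, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' Fit a logistic regression panel by maximum likelihood
#'
#' Markers are z-scored with the training data's statistics before fitting
#' (numerical conditioning; predictions are invariant). On detected
#' separation the model is refit with an L2 penalty `ridge_fallback` on the
#' slopes and flagged.
#'
#' @param design numeric matrix of subjects x markers (may have 0 columns for
#'   the intercept-only model); column names become the panel marker names.
#' @param labels binary vector, 1 = positive class.
#' @param ridge_fallback L2 penalty used only when separation is detected.
#' @param max_iter,tol IRLS controls.
#' @return a `panel_model`: `marker_names`, `coefficients` (intercept first,
#'   on the z-scored marker scale), `centers`, `scales`, `log_likelihood`,
#'   `aic`, `converged`, `separation_flag`.
#' @export
fit_logistic_ml <- function(design, labels, ridge_fallback = 1e-4,
                            max_iter = 100L, tol = 1e-8) {
  design <- as.matrix(design)
  y <- as.integer(labels)
  stopifnot(nrow(design) == length(y) || ncol(design) == 0L)
  if (any(!y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n <- length(y)
  if (n <= ncol(design) + 1L)
    stop("need more subjects than coefficients")
  if (ncol(design) > 0L) {
    centers <- colMeans(design)
    scales <- apply(design, 2, stats::sd)
    if (any(scales == 0))
      stop("zero-variance marker column: ",
           colnames(design)[which(scales == 0)[1]])
    Z <- sweep(sweep(design, 2, centers), 2, scales, "/")
  } else {
    centers <- numeric(0); scales <- numeric(0)
    Z <- matrix(0, n, 0)
  }
  fit <- .irls(Z, y, ridge = 0, max_iter = max_iter, tol = tol)
  separation <- fit$separation
  if (separation) {
    fit <- .irls(Z, y, ridge = ridge_fallback, max_iter = max_iter, tol = tol)
    fit$separation <- TRUE
  }
  new_panel_model(colnames(design) %||% character(0), fit, centers, scales)
}

new_panel_model <- function(markers, fit, centers, scales) {
  k <- 1L + length(markers)
  structure(list(marker_names = markers,
                 coefficients = stats::setNames(
                   fit$beta, c("(Intercept)", markers)),
                 centers = centers, scales = scales,
                 log_likelihood = fit$ll,
                 aic = 2 * k - 2 * fit$ll,
                 converged = fit$converged,
                 separation_flag = fit$separation),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel_model: %d marker(s), logLik %.4f, AIC %.4f%s\n",
              length(x$marker_names), x$log_likelihood, x$aic,
              if (x$separation_flag) " [separation: ridge fallback]" else ""))
  invisible(x)
}

#' Akaike information criterion of a fitted panel
#'
#' `AIC = 2k - 2 logLik` with `k = 1 + number of markers`.
#'
#' @param model a `panel_model`.
#' @export
model_aic <- function(model) {
  stopifnot(inherits(model, "panel_model"))
  model$aic
}

#' Exhaustive AIC search over candidate-marker subsets
#'
#' Fits every non-empty subset of the candidates (hard cap 15 candidates,
#' i.e. at most 32767 fits) and returns the minimum-AIC model. Ties are
#' broken toward the smaller subset, then lexicographically by marker names.
#' Subsets whose fit fails are excluded and counted.
#'
#' @param table a [feature_table()].
#' @param candidates character vector of candidate marker names (1..15).
#' @return list with `best` (a `panel_model`), `ranking` (data.frame over all
#'   evaluated subsets, sorted by AIC) and `n_failed`.
#' @export
exhaustive_aic_search <- function(table, candidates) {
  candidates <- sort(unique(as.character(candidates)))
  m <- length(candidates)
  if (m < 1L || m > 15L)
    stop("candidate set must contain 1..15 markers, got ", m)
  y <- table$grade
  X <- marker_matrix(table, candidates)
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  if (any(scales == 0))
    stop("zero-variance candidate marker: ",
         candidates[which(scales == 0)[1]])
  Z <- sweep(sweep(X, 2, centers), 2, scales, "/")
  n_sub <- bitwShiftL(1L, m) - 1L
  aic <- rep(NA_real_, n_sub)
  ll <- rep(NA_real_, n_sub)
  kk <- integer(n_sub)
  sep <- logical(n_sub)
  fits <- vector("list", n_sub)
  n_failed <- 0L
  for (s in seq_len(n_sub)) {
    idx <- which(bitwAnd(s, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    kk[s] <- length(idx)
    fit <- tryCatch({
      f <- .irls(Z[, idx, drop = FALSE], y)
      if (f$separation) {
        f <- .irls(Z[, idx, drop = FALSE], y, ridge = 1e-4)
        f$separation <- TRUE
      }
      f
    }, error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    fits[[s]] <- fit
    ll[s] <- fit$ll
    sep[s] <- fit$separation
    aic[s] <- 2 * (1 + length(idx)) - 2 * fit$ll
  }
  if (all(is.na(aic))) stop("exhaustive search failed: no subset could be fit")
  subset_names <- vapply(seq_len(n_sub), function(s) {
    paste(candidates[bitwAnd(s, bitwShiftL(1L, seq_len(m) - 1L)) != 0L],
          collapse = "+")
  }, character(1))
  ranking <- data.frame(subset = subset_names, k = kk, log_likelihood = ll,
                        aic = aic, separation = sep,
                        stringsAsFactors = FALSE)
  ok <- which(!is.na(aic))
  best_s <- ok[order(aic[ok], kk[ok], subset_names[ok])][1]
  idx <- which(bitwAnd(best_s, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
  best <- new_panel_model(candidates[idx], fits[[best_s]],
                          centers[idx], scales[idx])
  ranking <- ranking[order(ranking$aic, ranking$k, ranking$subset), ]
  rownames(ranking) <- NULL
  list(best = best, ranking = ranking, n_failed = n_failed)
}

#' Panel risk scores for new subjects
#'
#' Applies the logistic inverse link to the linear predictor of a fitted
#' panel; the returned scores in (0, 1) can feed any of the ROC screening
#' operations.
#'
#' @param model a `panel_model`.
#' @param features data.frame or matrix containing all of the model's
#'   marker columns.
#' @return numeric vector of risk scores.
#' @export
panel_predict <- function(model, features) {
  stopifnot(inherits(model, "panel_model"))
  mk <- model$marker_names
  if (length(mk) == 0L) {
    n <- nrow(features) %||% length(features)
    return(rep(stats::plogis(model$coefficients[1]), n))
  }
  missing <- setdiff(mk, colnames(features))
  if (length(missing)) stop("missing marker in features: ", missing[1])
  X <- as.matrix(as.data.frame(features)[, mk, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$centers), 2, model$scales, "/")
  drop(stats::plogis(model$coefficients[1] +
                       Z %*% model$coefficients[-1]))
}

# Convenience: fit a fixed marker panel from a feature table.
#' Fit a panel of named markers from a feature table
#' @param table a [feature_table()].
#' @param markers marker names to include.
#' @export
fit_panel <- function(table, markers) {
  fit_logistic_ml(marker_matrix(table, markers), table$grade)
}
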