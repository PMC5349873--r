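# Leave-one-third-out cross-validation and refit-per-draw bootstrap for
# logistic panels. All splits and resamples are stratified by grade: with a
# 34/19 cohort an unstratified one-third test set is frequently single-class.
#
# Scheme 1 fixes the marker set and refits only the coefficients per split;
# scheme 2 re-runs the entire procedure (screening, candidate selection,
# exhaustive AIC search, fitting) inside each training split, so the test
# AUC is free of selection optimism.

new_cv_result <- function(scheme, per_repeat_auc, seed, n_failed = 0L) {
  ok <- per_repeat_auc[!is.na(per_repeat_auc)]
  structure(list(scheme = scheme,
                 repeats = length(per_repeat_auc),
                 per_repeat_auc = per_repeat_auc,
                 mean_auc = mean(ok),
                 sd_auc = stats::sd(ok),
                 n_failed = n_failed,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result (scheme %d): mean test AUC %.3f (sd %.3f) over %d repeats%s\n",
    x$scheme, x$mean_auc, x$sd_auc, x$repeats,
    if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

# Stratified 2/3-1/3 split; returns train indices.
.stratified_train_idx <- function(labels, frac = 2 / 3) {
  idx <- unlist(lapply(split(seq_along(labels), labels), function(ii) {
    n_tr <- round(frac * length(ii))
    n_tr <- min(max(n_tr, 1L), length(ii) - 1L)
    sample(ii, n_tr)
  }), use.names = FALSE)
  sort(idx)
}

#' Cross-validate a fixed marker panel (scheme 1)
#'
#' Repeatedly splits the cohort into stratified 2/3 training and 1/3 test
#' sets, refits the panel coefficients on the training set (marker set held
#' fixed), scores the test set and records its AUC. Reported as the mean and
#' SD of per-repeat test AUCs.
#'
#' @param table a [feature_table()].
#' @param markers fixed panel marker names.
#' @param repeats number of random splits (default 1000).
#' @param seed integer seed.
#' @return a `cv_result` (scheme 1).
#' @export
cv_fixed_panel <- function(table, markers, repeats = 1000L, seed = NULL) {
  y <- table$grade
  if (min(table(y)) < 3L) stop("need at least 3 subjects per class")
  X <- marker_matrix(table, markers)
  if (!is.null(seed)) set.seed(seed)
  aucs <- rep(NA_real_, repeats)
  n_failed <- 0L
  for (r in seq_len(repeats)) {
    tr <- .stratified_train_idx(y)
    te <- setdiff(seq_along(y), tr)
    fit <- tryCatch(fit_logistic_ml(X[tr, , drop = FALSE], y[tr]),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    scores <- panel_predict(fit, X[te, , drop = FALSE])
    aucs[r] <- auc_mannwhitney(scores, y[te])
  }
  new_cv_result(1L, aucs, seed, n_failed)
}

#' Cross-validate the whole selection procedure (scheme 2)
#'
#' Per repeat: stratified 2/3-1/3 split; marker screening, candidate
#' selection (top `k_auc` by AUC plus top `k_roc` by ROC(0.05)) and the
#' exhaustive AIC search are all run inside the training split; the selected
#' model's coefficients are frozen and applied to the test split, whose AUC
#' is recorded. Failed repeats are excluded from the mean and counted.
#'
#' @param table feature table of all markers.
#' @param repeats number of splits (default 10).
#' @param k_auc,k_roc candidate-selection sizes passed to [screen_markers()].
#' @param seed integer seed.
#' @return a `cv_result` (scheme 2) with `panels` attribute listing the
#'   per-repeat selected marker sets.
#' @export
cv_full_procedure <- function(table, repeats = 10L, k_auc = 10L, k_roc = 5L,
                              seed = NULL) {
  y <- table$grade
  if (min(table(y)) < 3L) stop("need at least 3 subjects per class")
  if (length(marker_names(table)) < k_auc)
    stop("need at least k_auc markers")
  if (!is.null(seed)) set.seed(seed)
  aucs <- rep(NA_real_, repeats)
  panels <- vector("list", repeats)
  n_failed <- 0L
  for (r in seq_len(repeats)) {
    tr <- .stratified_train_idx(y)
    te <- setdiff(seq_along(y), tr)
    res <- tryCatch({
      train <- table[tr, ]
      class(train) <- class(table)
      scr <- screen_markers(train, k_auc = k_auc, k_roc = k_roc)
      search <- exhaustive_aic_search(train, scr$candidates)
      scores <- panel_predict(search$best, table[te, ])
      list(auc = auc_mannwhitney(scores, y[te]),
           markers = search$best$marker_names)
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    aucs[r] <- res$auc
    panels[[r]] <- res$markers
  }
  out <- new_cv_result(2L, aucs, seed, n_failed)
  attr(out, "panels") <- panels
  out
}

#' Refit-per-draw bootstrap for a panel's AUC and Youden point
#'
#' Per draw: stratified resample of subjects with replacement, panel
#' coefficients refit on the resample, in-draw risk scores computed and
#' their AUC and maximum Youden index recorded. Refitting inside each draw
#' propagates coefficient variance into the interval. Percentile intervals;
#' fit failures are redrawn (counted).
#'
#' @param table a [feature_table()].
#' @param markers panel marker names.
#' @param draws bootstrap draws (default 1000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `auc` (`estimate`, `lower`, `upper`), `youden`
#'   (point estimate list plus `j_lower`, `j_upper`), `draws`, `n_redrawn`.
#' @export
bootstrap_panel_ci <- function(table, markers, draws = 1000L, level = 0.95,
                               seed = NULL) {
  stopifnot(draws >= 100L)
  y <- table$grade
  X <- marker_matrix(table, markers)
  if (!is.null(seed)) set.seed(seed)
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  full_fit <- fit_logistic_ml(X, y)
  full_scores <- panel_predict(full_fit, X)
  # ML logistic predictions are invariant to affine rescaling of the
  # columns, so z-score once and run the IRLS core directly per draw.
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, stats::sd), "/")
  auc_b <- numeric(draws)
  j_b <- numeric(draws)
  n_redrawn <- 0L
  b <- 1L
  while (b <= draws) {
    idx <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
    Zb <- Z[idx, , drop = FALSE]
    yb <- y[idx]
    fit <- tryCatch({
      f <- .irls(Zb, yb)
      if (f$separation) f <- .irls(Zb, yb, ridge = 1e-4)
      f
    }, error = function(e) NULL)
    if (is.null(fit)) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 10L * draws) stop("too many failed bootstrap draws")
      next
    }
    eta <- fit$beta[1] + drop(Zb %*% fit$beta[-1])
    auc_b[b] <- auc_mannwhitney(eta, yb)
    j_b[b] <- youden_max(roc_curve(eta, yb))$J
    b <- b + 1L
  }
  probs <- c((1 - level) / 2, (1 + level) / 2)
  auc_q <- stats::quantile(auc_b, probs, names = FALSE)
  j_q <- stats::quantile(j_b, probs, names = FALSE)
  list(auc = list(estimate = auc_mannwhitney(full_scores, y),
                  lower = auc_q[1], upper = auc_q[2]),
       youden = c(youden_max(roc_curve(full_scores, y)),
                  list(j_lower = j_q[1], j_upper = j_q[2])),
       level = level, draws = draws, n_redrawn = n_redrawn)
}
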