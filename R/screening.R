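# ROC-based marker screening. Scores are oriented so that larger values
# indicate the positive (high-grade) class; markers whose raw AUC falls below
# 0.5 are flipped before ranking and the flip is recorded. The ROC convention
# throughout is the empirical step function "score >= threshold => positive"
# with thresholds at observed values only, no interpolation.

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  labels
}

#' Mann-Whitney AUC
#'
#' Probability that a positive-class score exceeds a negative-class score,
#' with ties counted half: `AUC = (#(pos > neg) + 0.5 #(pos = neg)) / (n1 n0)`.
#'
#' @param scores numeric marker values.
#' @param labels binary labels, 1 = positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_mannwhitney <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)                      # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' One operating point per distinct observed score (rule: score >= threshold
#' is called positive), plus the (0,0) endpoint at threshold `Inf`. The last
#' point is always (1,1). Trapezoidal area equals [auc_mannwhitney()].
#'
#' @inheritParams auc_mannwhitney
#' @return a `roc_curve` object: `thresholds`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  idx <- match(scores, thr)
  tp <- cumsum(tabulate(idx[labels == 1L], nbins = length(thr)))
  fp <- cumsum(tabulate(idx[labels == 0L], nbins = length(thr)))
  structure(list(thresholds = c(Inf, thr),
                 fpr = c(0, fp / n0),
                 tpr = c(0, tp / n1)),
            class = "roc_curve")
}

#' Area under a ROC curve by the trapezoidal rule
#' @param roc a `roc_curve`.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  n <- length(roc$fpr)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

#' TPR at a capped FPR ("ROC(0.05)")
#'
#' Maximum TPR over operating points whose empirical FPR does not exceed the
#' cap; step-function convention, no interpolation.
#'
#' @param roc a `roc_curve`.
#' @param fpr_cap false-positive-rate cap in `[0, 1]` (default 0.05).
#' @export
tpr_at_fixed_fpr <- function(roc, fpr_cap = 0.05) {
  stopifnot(inherits(roc, "roc_curve"), fpr_cap >= 0, fpr_cap <= 1)
  max(roc$tpr[roc$fpr <= fpr_cap])
}

#' Maximum of the Youden index
#'
#' Maximizes `J = sensitivity + specificity - 1 = TPR - FPR` over observed
#' thresholds; ties are broken toward higher specificity (fewer false
#' positives), then toward the higher threshold.
#'
#' @param roc a `roc_curve`.
#' @return list with `J`, `sensitivity`, `specificity`, `threshold`.
#' @export
youden_max <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  J <- roc$tpr - roc$fpr
  best <- order(-J, roc$fpr, -roc$thresholds)[1]
  list(J = J[best], sensitivity = roc$tpr[best],
       specificity = 1 - roc$fpr[best], threshold = roc$thresholds[best])
}

#' Two-sided Mann-Whitney marker p-value
#'
#' Normal approximation to the Mann-Whitney U statistic with the usual tie
#' correction to its variance. Chosen over bootstrap-based inference because
#' screening p-values far below 1/draws must remain resolvable. All-tied
#' scores (zero variance) give p = 1.
#'
#' @inheritParams auc_mannwhitney
#' @export
marker_pvalue <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  N <- n1 + n0
  r <- rank(scores)
  U <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n0 / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(1)
  z <- (U - n1 * n0 / 2) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1,
#' returned in the input order.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  q <- pmin(1, rev(cummin(rev(p_values[ord] * m / seq_len(m)))))
  q[order(ord)]
}

#' Stratified bootstrap percentile interval for a score statistic
#'
#' Resamples subjects with replacement within each class (preserving the
#' class sizes) and returns the percentile interval of the statistic.
#'
#' @inheritParams auc_mannwhitney
#' @param statistic `function(scores, labels)` returning a scalar; default
#'   [auc_mannwhitney()].
#' @param draws number of bootstrap draws (>= 100).
#' @param level confidence level.
#' @param seed integer seed (required for reproducibility).
#' @return list with `lower`, `upper`, `level`, `draws`, `estimate`.
#' @export
bootstrap_ci <- function(scores, labels, statistic = auc_mannwhitney,
                         draws = 1000L, level = 0.95, seed = NULL) {
  labels <- check_binary_labels(labels)
  stopifnot(draws >= 100L, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  stat <- numeric(draws)
  for (b in seq_len(draws)) {
    idx <- c(sample(i1, length(i1), replace = TRUE),
             sample(i0, length(i0), replace = TRUE))
    stat[b] <- statistic(scores[idx], labels[idx])
  }
  qs <- stats::quantile(stat, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  list(lower = qs[1], upper = qs[2], level = level, draws = draws,
       estimate = statistic(scores, labels))
}

#' Screen markers by AUC and ROC(0.05) and select panel candidates
#'
#' Computes per-marker oriented statistics (flipping markers with raw
#' AUC < 0.5), ranks them, and returns the union of the top `k_auc` by AUC
#' and the top `k_roc` by TPR at 5\% FPR as the candidate set for panel
#' construction, tagging each candidate `AUC`, `ROC(0.05)` or `BOTH`.
#'
#' @param table a [feature_table()].
#' @param k_auc number of top-AUC candidates (default 10).
#' @param k_roc number of top-ROC(0.05) candidates (default 5).
#' @param fpr_cap FPR cap for the second criterion.
#' @param ci_draws bootstrap draws for per-marker AUC CIs (0 = skip, the
#'   default; screening inside cross-validation does not need intervals).
#' @param seed seed for the bootstrap CIs.
#' @return list with `stats` (data.frame of per-marker statistics, ranked by
#'   AUC) and `candidates` (character vector of selected marker names).
#' @export
screen_markers <- function(table, k_auc = 10L, k_roc = 5L, fpr_cap = 0.05,
                           ci_draws = 0L, seed = NULL) {
  mk <- marker_names(table)
  if (length(mk) < k_auc)
    stop("need at least k_auc = ", k_auc, " markers, have ", length(mk))
  y <- table$grade
  rows <- lapply(mk, function(name) {
    s <- table[[name]]
    raw_auc <- auc_mannwhitney(s, y)
    orientation <- if (raw_auc < 0.5) -1L else 1L
    s <- s * orientation
    roc <- roc_curve(s, y)
    yj <- youden_max(roc)
    data.frame(marker = name, auc = auc_mannwhitney(s, y),
               roc05 = tpr_at_fixed_fpr(roc, fpr_cap),
               p_value = marker_pvalue(s, y),
               youden_j = yj$J, sensitivity = yj$sensitivity,
               specificity = yj$specificity, threshold = yj$threshold,
               orientation = orientation, stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  stats$fdr_q <- bh_fdr(stats$p_value)
  if (ci_draws >= 100L) {
    cis <- lapply(seq_along(mk), function(i) {
      s <- table[[mk[i]]] * stats$orientation[i]
      bootstrap_ci(s, y, draws = ci_draws,
                   seed = if (is.null(seed)) NULL else seed + i)
    })
    stats$auc_lower <- vapply(cis, `[[`, numeric(1), "lower")
    stats$auc_upper <- vapply(cis, `[[`, numeric(1), "upper")
  }
  ord_auc <- order(-stats$auc, stats$marker)
  ord_roc <- order(-stats$roc05, -stats$auc, stats$marker)
  top_auc <- stats$marker[ord_auc][seq_len(min(k_auc, nrow(stats)))]
  top_roc <- stats$marker[ord_roc][seq_len(min(k_roc, nrow(stats)))]
  stats$criteria <- ifelse(
    stats$marker %in% top_auc & stats$marker %in% top_roc, "BOTH",
    ifelse(stats$marker %in% top_auc, "AUC",
           ifelse(stats$marker %in% top_roc, "ROC(0.05)", "")))
  stats <- stats[ord_auc, ]
  rownames(stats) <- NULL
  list(stats = stats, candidates = stats$marker[stats$criteria != ""])
}
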