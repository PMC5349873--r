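test_that("Mann-Whitney AUC counts wins and half-ties", {
  expect_equal(auc_mannwhitney(c(2, 3, 4, 1, 2, 3),
                               c(1, 1, 1, 0, 0, 0)), 7 / 9)
  expect_equal(auc_mannwhitney(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_mannwhitney(rep(2, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_mannwhitney(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC invariances: monotone transform and score negation", {
  set.seed(501)
  for (i in 1:20) {
    d <- random_scores()
    a <- auc_mannwhitney(d$scores, d$labels)
    expect_equal(auc_mannwhitney(exp(d$scores), d$labels), a)
    expect_equal(auc_mannwhitney(-d$scores, d$labels), 1 - a)
  }
})

test_that("ROC curve is a valid step function whose area equals the MW AUC", {
  r <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_true(any(r$fpr == 0 & r$tpr == 1))          # perfect separation
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)

  # single pos/neg, pos > neg -> {(0,0),(0,1),(1,1)}
  r2 <- roc_curve(c(5, 2), c(1, 0))
  expect_equal(r2$fpr, c(0, 0, 1))
  expect_equal(r2$tpr, c(0, 1, 1))

  set.seed(502)
  for (i in 1:100) {
    d <- random_scores(ties = i %% 2 == 0)
    r <- roc_curve(d$scores, d$labels)
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
    expect_equal(roc_auc(r), auc_mannwhitney(d$scores, d$labels),
                 tolerance = 1e-12)
  }
})

test_that("TPR at capped FPR uses the step-function convention", {
  perfect <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(tpr_at_fixed_fpr(perfect), 1.0)
  # TPR=0 at FPR=0, first nonzero FPR above the cap -> 0
  r <- roc_curve(c(1, 1, 2, 2), c(1, 1, 0, 0))
  expect_equal(tpr_at_fixed_fpr(r, 0.05), 0)
})

test_that("Youden maximum enumerates thresholds with spec'd tie-breaks", {
  y <- youden_max(roc_curve(c(2, 3, 4, 1, 2), c(1, 1, 1, 0, 0)))
  expect_equal(y$J, 2 / 3, tolerance = 1e-12)
  expect_equal(y$threshold, 3)
  expect_equal(y$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(y$specificity, 1)

  expect_equal(youden_max(roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0)))$J, 1.0)
  flat <- youden_max(roc_curve(rep(1, 6), c(1, 1, 1, 0, 0, 0)))
  expect_equal(flat$J, 0)

  set.seed(503)
  for (i in 1:30) {
    d <- random_scores()
    yj <- youden_max(roc_curve(d$scores, d$labels))
    expect_equal(yj$J, yj$sensitivity + yj$specificity - 1, tolerance = 1e-12)
    expect_gte(yj$J, 0); expect_lte(yj$J, 1)
  }
})

test_that("marker p-value: degenerate ties and perfect separation", {
  expect_equal(marker_pvalue(rep(3, 10), c(rep(1, 5), rep(0, 5))), 1)
  p <- marker_pvalue(c(rnorm(20) + 100, rnorm(20)),
                     c(rep(1, 20), rep(0, 20)))
  expect_lt(p, 1e-6)
})

test_that("BH adjustment matches the step-up formula and is monotone", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.5)),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(504)
  for (i in 1:20) {
    p <- runif(25)
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))    # sorted by p => sorted q
    expect_true(all(q <= 1))
  }
})

test_that("stratified bootstrap CI is deterministic and degenerate-safe", {
  lab <- c(rep(1L, 8), rep(0L, 6))
  sc <- c(rnorm(8) + 10, rnorm(6))                   # perfect marker
  ci <- bootstrap_ci(sc, lab, draws = 200, seed = 7)
  expect_equal(ci$lower, 1.0); expect_equal(ci$upper, 1.0)
  ci2 <- bootstrap_ci(sc, lab, draws = 200, seed = 7)
  expect_identical(ci, ci2)
})

test_that("screening orients markers, ranks, and unions the two top sets", {
  set.seed(505)
  # one marker designed strong but reversed in sign, the rest noise
  tab <- generate_feature_table(25, 25, specs = c(good = 0.95),
                                n_noise_markers = 14, seed = 506)
  tab$good <- -tab$good
  scr <- screen_markers(tab, k_auc = 3, k_roc = 2)
  expect_equal(scr$stats$marker[1], "good")
  expect_equal(scr$stats$orientation[scr$stats$marker == "good"], -1L)
  expect_true(all(scr$stats$auc >= 0.5))
  expect_true(all(scr$stats$fdr_q >= scr$stats$p_value))
  expect_lte(length(scr$candidates), 5)
  expect_true("good" %in% scr$candidates)
  expect_true(all(scr$stats$criteria[match(scr$candidates,
                                           scr$stats$marker)] != ""))
  expect_error(screen_markers(tab, k_auc = 99), "k_auc")
})

test_that("screening with bootstrap CIs brackets each marker AUC", {
  tab <- generate_feature_table(15, 12, specs = c(a = 0.85, b = 0.6),
                                n_noise_markers = 1, seed = 507)
  scr <- screen_markers(tab, k_auc = 3, k_roc = 1, ci_draws = 200, seed = 508)
  expect_true(all(scr$stats$auc_lower <= scr$stats$auc + 1e-12))
  expect_true(all(scr$stats$auc_upper >= scr$stats$auc - 1e-12))
})
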