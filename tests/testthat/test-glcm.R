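test_that("quantization bins masked voxels over their own range", {
  v <- as_vol(rbind(c(0, 10), c(0, 10)))
  q <- quantize_roi(v, full_mask(dim(v)), 2)
  expect_equal(sort(unique(as.vector(q))), c(0L, 1L))

  v <- as_vol(matrix(c(0, 1, 2, 3), 2))
  q <- quantize_roi(v, full_mask(dim(v)), 2)
  expect_equal(sort(as.vector(q)), c(0L, 0L, 1L, 1L))

  const <- as_vol(matrix(7, 4, 4))
  expect_true(all(quantize_roi(const, full_mask(dim(const)), 32) == 0L))

  expect_error(quantize_roi(const, array(FALSE, dim(const)), 32),
               "fewer than 2")
  expect_error(quantize_roi(const, full_mask(c(4, 4, 2)), 32), "shapes")
})

test_that("GLCM matches hand-enumerated 2x2 examples", {
  stripes <- array(c(0, 1, 0, 1), c(2, 2, 1))   # rows (0,0) and (1,1)
  q <- quantize_roi(stripes, full_mask(c(2, 2, 1)), 2)
  g <- compute_glcm(q, glcm_spec(c(0, 1, 0), levels = 2))
  expect_equal(g$p, matrix(c(0.5, 0, 0, 0.5), 2))
  expect_equal(glcm_correlation(g), 1.0)

  checker <- array(c(0, 1, 1, 0), c(2, 2, 1))
  g2 <- compute_glcm(quantize_roi(checker, full_mask(c(2, 2, 1)), 2),
                     glcm_spec(c(0, 1, 0), levels = 2))
  expect_equal(g2$p, matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(glcm_correlation(g2), -1.0)
  sec <- glcm_secondary_stats(g2)
  expect_equal(sec$contrast, 1.0)
  expect_equal(sec$entropy, 1.0)
  expect_equal(sec$energy, 0.5)

  # point-mass GLCM: constant ROI
  g3 <- compute_glcm(quantize_roi(array(5, c(2, 2, 1)),
                                  full_mask(c(2, 2, 1)), 32),
                     glcm_spec(c(1, 0, 0), levels = 32))
  sec3 <- glcm_secondary_stats(g3)
  expect_equal(sec3$energy, 1.0)
  expect_equal(sec3$entropy, 0.0)
  expect_equal(sec3$contrast, 0.0)
  expect_equal(glcm_correlation(g3), 1.0)   # degenerate-SD sentinel
})

test_that("GLCM invariants hold on random volumes", {
  set.seed(401)
  dirs <- glcm_directions("3D")
  for (rep in 1:25) {
    q <- random_quantized(levels = 5L)
    spec <- glcm_spec(dirs[sample.int(13, 1), ],
                      distance = sample(1:3, 1), levels = 5L)
    g <- compute_glcm(q, spec)
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_true(all(g$p >= 0))
    expect_equal(g$p, t(g$p))                        # symmetric mode
    corr <- glcm_correlation(g)
    expect_gte(corr, -1); expect_lte(corr, 1)
    # symmetric GLCM invariant under offset negation
    neg <- spec; neg$direction <- -spec$direction
    expect_equal(compute_glcm(q, neg)$p, g$p)
  }
})

test_that("monotone gray transforms preserving bins leave features unchanged", {
  set.seed(402)
  v <- array(runif(6 * 6 * 4), c(6, 6, 4))
  m <- full_mask(dim(v))
  spec <- glcm_spec(c(1, 0, 0), levels = 8L)
  f1 <- glcm_correlation(compute_glcm(quantize_roi(v, m, 8), spec))
  f2 <- glcm_correlation(compute_glcm(quantize_roi(exp(4 * v), m, 8), spec))
  q1 <- quantize_roi(v, m, 8)
  q2 <- quantize_roi(v^3, m, 8)                      # cube: not bin-preserving
  expect_equal(
    glcm_correlation(compute_glcm(q1, spec)),
    glcm_correlation(compute_glcm(
      quantize_roi(2 * v + 10, m, 8), spec)))        # affine: bin-preserving
  expect_true(is.numeric(f2))                        # exp need not preserve bins
})

test_that("no-pairs conditions raise the dedicated error", {
  q <- quantize_roi(as_vol(matrix(1:4, 2)), full_mask(c(2, 2, 1)), 2)
  expect_error(compute_glcm(q, glcm_spec(c(0, 0, 1), levels = 2)),
               class = "radpanel_no_pairs")
  expect_error(compute_glcm(q, glcm_spec(c(1, 0, 0), distance = 5,
                                         levels = 2)),
               class = "radpanel_no_pairs")
})

test_that("first-order statistics match hand values and Gaussian moments", {
  v <- as_vol(matrix(c(1, 2, 3, 4), 2))
  fo <- first_order_stats(v, full_mask(dim(v)))
  expect_equal(fo$mean, 2.5)
  expect_equal(fo$sd, sqrt(1.25))

  set.seed(403)
  big <- array(rnorm(1e5), c(100, 100, 10))
  fo2 <- first_order_stats(big, full_mask(dim(big)))
  expect_equal(fo2$kurtosis, 3, tolerance = 0.1)

  # two equal-mass bins -> 1 bit
  v3 <- as_vol(matrix(c(0, 0, 1, 1), 2))
  expect_equal(first_order_stats(v3, full_mask(dim(v3)),
                                 entropy_bins = 2)$entropy, 1.0)

  const <- as_vol(matrix(2, 2, 2))
  expect_true(is.na(first_order_stats(const, full_mask(dim(const)))$kurtosis))
})

test_that("extract_features produces systematic columns and drops incomplete markers", {
  dirs_n <- nrow(glcm_directions("3D"))
  expect_equal(dirs_n, 13L)
  expect_equal(nrow(glcm_directions("2.5D")), 4L)
  specs <- glcm_spec_grid("3D", distances = c(1L, 2L), levels = 4L)
  expect_length(specs, 26L)

  set.seed(404)
  vol <- array(runif(8^3), c(8, 8, 8))
  subj <- list(image = list(voxels = vol), mask = list(voxels = full_mask(c(8, 8, 8))),
               grade = "HG", subject_id = "A")
  subj2 <- subj; subj2$grade <- "LG"; subj2$subject_id <- "B"
  tab <- extract_features(list(subj, subj2), specs = specs, levels = 4L)
  expect_s3_class(tab, "feature_table")
  expect_equal(sum(grepl("^GLCM3_", marker_names(tab))), 26L)
  expect_true(all(c("FO_mean", "FO_sd", "FO_kurtosis", "FO_entropy") %in%
                    marker_names(tab)))
  # identical volumes -> identical rows
  expect_equal(unname(unlist(tab[1, marker_names(tab)])),
               unname(unlist(tab[2, marker_names(tab)])))

  # a spec with no valid pairs anywhere is dropped with a warning
  bad <- c(specs, list(glcm_spec(c(0, 0, 1), distance = 10L, levels = 4L)))
  expect_warning(tab2 <- extract_features(list(subj, subj2), specs = bad,
                                          levels = 4L),
                 "dropping")
  expect_equal(sum(grepl("^GLCM3_", marker_names(tab2))), 26L)

  subj3 <- subj; subj3$mask <- list(voxels = full_mask(c(8, 8, 4)))
  expect_error(extract_features(list(subj3), specs = specs, levels = 4L),
               "shapes differ")
})
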