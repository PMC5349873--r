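test_that("texture cohort honors counts, masks, and reproducibility", {
  coh <- generate_texture_cohort(4, 3, shape = c(10, 10, 8), seed = 101)
  expect_length(coh, 7L)
  grades <- vapply(coh, `[[`, character(1), "grade")
  expect_equal(sum(grades == "HG"), 4L)
  for (s in coh) {
    expect_equal(dim(s$image$voxels), c(10L, 10L, 8L))
    expect_gte(mean(s$mask$voxels), 0.20)
  }
  coh2 <- generate_texture_cohort(4, 3, shape = c(10, 10, 8), seed = 101)
  expect_identical(coh, coh2)
  expect_error(generate_texture_cohort(2, 2, shape = c(6, 10, 10)), ">= 8")
})

test_that("identical class specs carry no texture signal", {
  spec <- texture_class_spec("HG", field_smoothing = 1.5)
  spec_lg <- spec; spec_lg$label <- "LG"
  coh <- generate_texture_cohort(20, 20, shape = c(12, 12, 8),
                                 hg_spec = spec, lg_spec = spec_lg,
                                 seed = 102)
  tab <- suppressWarnings(extract_features(
    coh, specs = glcm_spec_grid("3D", distances = 1L, levels = 16L),
    levels = 16L))
  aucs <- vapply(marker_names(tab), function(m) {
    a <- auc_mannwhitney(tab[[m]], tab$grade); max(a, 1 - a)
  }, numeric(1))
  # null markers at n=20/class: oriented AUCs stay within Monte-Carlo range
  expect_lt(max(aucs), 0.78)
  expect_lt(mean(aucs) - 0.5, 0.12)
})

test_that("binormal delta and empirical AUC recover the designed value", {
  expect_equal(binormal_delta(0.82), sqrt(2) * qnorm(0.82), tolerance = 1e-12)
  expect_equal(binormal_delta(0.82), 1.2945, tolerance = 1e-4)
  expect_equal(binormal_delta(0.5), 0)
  expect_error(binormal_marker_spec("m", 1.0), "0.5, 1")
  expect_error(binormal_marker_spec("m", 0.3), "0.5, 1")

  tab <- generate_feature_table(4000, 4000, specs = c(flat = 0.5),
                                seed = 103)
  expect_equal(auc_mannwhitney(tab$flat, tab$grade), 0.5, tolerance = 0.02)
})

test_that("feature tables are reproducible and support marker correlation", {
  sp <- list(binormal_marker_spec("a", 0.8),
             binormal_marker_spec("b", 0.7, correlation_to_previous = 0.9))
  t1 <- generate_feature_table(400, 400, specs = sp, seed = 104)
  t2 <- generate_feature_table(400, 400, specs = sp, seed = 104)
  expect_identical(t1, t2)
  # noise parts correlated: partial out the class shift by per-class cor
  lg <- t1[t1$grade == 0L, ]
  expect_gt(cor(lg$a, lg$b), 0.8)
})

test_that("Fukuoka cohort generation matches margins exactly and covers all", {
  m <- reference_fukuoka_margins()
  recs <- generate_fukuoka_cohort(34, 19, margins = m, seed = 105)
  expect_equal(nrow(recs), 53L)
  flags <- classify_fukuoka(recs)
  expect_true(all(flags$positive))
  for (g in c("HG", "LG")) {
    sub <- flags[recs$grade == g, ]
    got <- vapply(names(m[[g]]), function(cr) sum(sub[[cr]]), integer(1))
    expect_equal(got, m[[g]])
  }
  expect_equal(sum(recs$cyst_size_cm > 3), 23L)
  # continuous fields strictly satisfy their flags
  expect_true(all((recs$cyst_size_cm > 3) == flags$cyst_gt_3cm))
  expect_true(all((recs$mpd_diameter_mm > 5) == flags$mpd_gt_5mm))
})

test_that("degenerate and infeasible margins behave as specified", {
  one <- list(HG = c(main_duct = 5L, cyst_gt_3cm = 0L, mural_nodule = 0L,
                     mpd_gt_5mm = 0L, positive_cytology = 0L,
                     symptomatic = 0L),
              LG = c(main_duct = 3L, cyst_gt_3cm = 0L, mural_nodule = 0L,
                     mpd_gt_5mm = 0L, positive_cytology = 0L,
                     symptomatic = 0L))
  criteria <- c("main_duct", "cyst_gt_3cm", "mural_nodule", "mpd_gt_5mm",
                "positive_cytology", "symptomatic")
  recs <- generate_fukuoka_cohort(5, 3, margins = one, seed = 106)
  flags <- classify_fukuoka(recs)
  expect_true(all(flags$main_duct))
  expect_true(all(rowSums(flags[criteria]) == 1L))

  bad <- one
  bad$HG["main_duct"] <- 2L
  expect_error(generate_fukuoka_cohort(5, 3, margins = bad), "infeasible")
})

test_that("LG reference margins always leave every record covered", {
  m <- reference_fukuoka_margins()
  for (seed in 1:10) {
    recs <- generate_fukuoka_cohort(1, 19,
                                    margins = list(HG = m$HG * 0L + c(1L, rep(0L, 5)),
                                                   LG = m$LG),
                                    seed = seed)
    lg <- classify_fukuoka(recs[recs$grade == "LG", ])
    expect_true(all(lg$positive))
  }
})

test_that("NIfTI cohort round-trips through disk with its sidecar", {
  dir <- withr::local_tempdir()
  coh <- generate_texture_cohort(2, 1, shape = c(8, 8, 8), seed = 107)
  write_cohort_nifti(coh, dir, params = list(seed = 107))
  back <- read_cohort_nifti(dir)
  expect_length(back, 3L)
  expect_equal(back[[1]]$grade, "HG")
  expect_equal(back[[1]]$image$voxels, coh[[1]]$image$voxels,
               tolerance = 1e-5)                      # float32 storage
  expect_identical(back[[2]]$mask$voxels, coh[[2]]$mask$voxels)
})
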