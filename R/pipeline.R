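# End-to-end orchestration: simulate/load -> extract -> screen -> panel ->
# validate -> bootstrap -> PCA -> reports, driven by a single config list
# whose one root seed is expanded into per-stage seeds. Every artifact is a
# plain CSV/JSON file in the run directory; the config (with its expanded
# seeds) is written alongside so a run is reproducible from its artifacts.

#' Default pipeline configuration
#'
#' @param seed root seed; per-stage seeds are derived from it.
#' @return nested list of stage parameters (see the fields themselves).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_hg = 34L, n_lg = 19L, shape = c(24L, 24L, 16L),
                    hg_smoothing = 2.5, lg_smoothing = 1.0),
    extract = list(levels = 32L, mode = "3D", distances = c(1L, 4L),
                   statistics = "correlation", first_order = TRUE),
    screen = list(k_auc = 10L, k_roc = 5L, fpr_cap = 0.05, ci_draws = 1000L),
    validate = list(scheme1_repeats = 1000L, scheme2_repeats = 10L,
                    bootstrap_draws = 1000L, level = 0.95),
    pca = list(n_components = 2L)
  )
}

# Deterministic per-stage seed expansion, kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, screen = 211L, scheme1 = 307L,
               scheme2 = 401L, bootstrap = 503L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Either generates a synthetic texture cohort (`table = NULL`) and extracts
#' features from it, or starts from a supplied feature table. Then: marker
#' screening with FDR and bootstrap CIs, exhaustive-AIC panel construction
#' on the screened candidates, scheme-1 and scheme-2 cross-validation,
#' refit-per-draw panel bootstrap, and PCA. Artifacts (marker report,
#' subset ranking, panel JSON, CV JSON, PCA scores, run config) are written
#' to `out_dir`.
#'
#' @param config list from [default_config()].
#' @param out_dir run directory (created; pass `NULL` to skip writing).
#' @param table optional [feature_table()]; when `NULL` a synthetic cohort
#'   is generated and features extracted per `config$simulate`/`extract`.
#' @return list with `table`, `screen`, `search`, `cv1`, `cv2`, `boot`,
#'   `pca`, `pca_separation`, `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         table = NULL) {
  cfg <- config
  if (is.null(table)) {
    sim <- cfg$simulate
    cohort <- generate_texture_cohort(
      n_hg = sim$n_hg, n_lg = sim$n_lg, shape = sim$shape,
      hg_spec = texture_class_spec("HG", field_smoothing = sim$hg_smoothing),
      lg_spec = texture_class_spec("LG", field_smoothing = sim$lg_smoothing),
      seed = stage_seed(cfg$seed, "simulate"))
    ex <- cfg$extract
    table <- extract_features(
      cohort,
      specs = glcm_spec_grid(ex$mode, distances = ex$distances,
                             levels = ex$levels),
      levels = ex$levels, statistics = ex$statistics,
      first_order = ex$first_order)
  }
  scr <- screen_markers(table, k_auc = cfg$screen$k_auc,
                        k_roc = cfg$screen$k_roc,
                        fpr_cap = cfg$screen$fpr_cap,
                        ci_draws = cfg$screen$ci_draws,
                        seed = stage_seed(cfg$seed, "screen"))
  search <- exhaustive_aic_search(table, scr$candidates)
  markers <- search$best$marker_names
  resub_scores <- panel_predict(search$best, table)
  cv1 <- cv_fixed_panel(table, markers,
                        repeats = cfg$validate$scheme1_repeats,
                        seed = stage_seed(cfg$seed, "scheme1"))
  cv2 <- cv_full_procedure(table, repeats = cfg$validate$scheme2_repeats,
                           k_auc = cfg$screen$k_auc,
                           k_roc = cfg$screen$k_roc,
                           seed = stage_seed(cfg$seed, "scheme2"))
  boot <- bootstrap_panel_ci(table, markers,
                             draws = cfg$validate$bootstrap_draws,
                             level = cfg$validate$level,
                             seed = stage_seed(cfg$seed, "bootstrap"))
  proj <- pca_project(suppressWarnings(standardize_features(table)),
                      n_components = cfg$pca$n_components)
  result <- list(table = table, screen = scr, search = search,
                 resubstitution_auc = auc_mannwhitney(resub_scores,
                                                      table$grade),
                 cv1 = cv1, cv2 = cv2, boot = boot,
                 pca = proj, pca_separation = pca_separation(proj),
                 config = cfg)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_feature_csv(result$table, p("feature_table.csv"))
  utils::write.csv(result$screen$stats, p("marker_report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$search$ranking, p("panel_ranking.csv"),
                   row.names = FALSE)
  best <- result$search$best
  jsonlite::write_json(
    list(markers = best$marker_names,
         coefficients = as.list(best$coefficients),
         centers = as.list(best$centers), scales = as.list(best$scales),
         log_likelihood = best$log_likelihood, aic = best$aic,
         separation_flag = best$separation_flag,
         resubstitution_auc = result$resubstitution_auc),
    p("panel.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in c("cv1", "cv2")) {
    cv <- result[[nm]]
    jsonlite::write_json(
      list(scheme = cv$scheme, repeats = cv$repeats,
           per_repeat_auc = cv$per_repeat_auc, mean_auc = cv$mean_auc,
           sd_auc = cv$sd_auc, n_failed = cv$n_failed, seed = cv$seed),
      p(paste0(nm, ".json")), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(result$boot, p("panel_bootstrap.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  scores <- data.frame(subject_id = result$pca$subject_id,
                       grade = ifelse(result$pca$grade == 1L, "HG", "LG"),
                       result$pca$scores, check.names = FALSE)
  utils::write.csv(scores, p("pca_scores.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(explained = result$pca$explained,
         separation = result$pca_separation),
    p("pca_summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$config, p("run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Load a pipeline config from a JSON file, filling defaults
#' @param path JSON config file.
#' @export
load_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config(seed = user$seed %||% 1L)
  for (sec in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[sec]])) {
      for (k in intersect(names(user[[sec]]), names(cfg[[sec]])))
        cfg[[sec]][[k]] <- user[[sec]][[k]]
    } else cfg[[sec]] <- user[[sec]]
  }
  cfg
}
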