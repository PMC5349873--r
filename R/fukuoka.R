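# Fukuoka consensus worrisome features for pancreatic cysts. A lesion is
# flagged high risk when any of: main-duct involvement, cyst size > 3 cm,
# mural nodules, main pancreatic duct (MPD) diameter > 5 mm, positive
# cytology, or neoplasm-related symptoms. Size thresholds are strict (">").

FUKUOKA_CRITERIA <- c("main_duct", "cyst_gt_3cm", "mural_nodule",
                      "mpd_gt_5mm", "positive_cytology", "symptomatic")

#' Classify lesion records by the Fukuoka worrisome features
#'
#' @param records data.frame with columns `subject_id`,
#'   `main_duct_involvement`, `cyst_size_cm`, `mural_nodule`,
#'   `mpd_diameter_mm`, `positive_cytology`, `symptomatic` (and optionally
#'   `grade`).
#' @return data.frame with `subject_id`, one logical column per criterion
#'   (`main_duct`, `cyst_gt_3cm`, `mural_nodule`, `mpd_gt_5mm`,
#'   `positive_cytology`, `symptomatic`), and `positive` (any criterion).
#' @export
classify_fukuoka <- function(records) {
  req <- c("subject_id", "main_duct_involvement", "cyst_size_cm",
           "mural_nodule", "mpd_diameter_mm", "positive_cytology",
           "symptomatic")
  missing <- setdiff(req, names(records))
  if (length(missing)) stop("missing column: ", missing[1])
  if (any(records$cyst_size_cm < 0) || any(records$mpd_diameter_mm < 0))
    stop("sizes must be nonnegative")
  flags <- data.frame(
    subject_id = records$subject_id,
    main_duct = as.logical(records$main_duct_involvement),
    cyst_gt_3cm = records$cyst_size_cm > 3,
    mural_nodule = as.logical(records$mural_nodule),
    mpd_gt_5mm = records$mpd_diameter_mm > 5,
    positive_cytology = as.logical(records$positive_cytology),
    symptomatic = as.logical(records$symptomatic),
    stringsAsFactors = FALSE)
  flags$positive <- Reduce(`|`, flags[FUKUOKA_CRITERIA])
  flags
}

#' Cohort-level Fukuoka summary against pathological grade
#'
#' Tabulates each criterion (count and integer-rounded percentage) in total
#' and by grade, and reports the benign fraction among Fukuoka-positive
#' lesions. In a resected cohort where every lesion was called high risk,
#' that fraction is the criteria's false positive rate: the share of
#' operated lesions that pathology graded benign (low grade).
#'
#' @param records as for [classify_fukuoka()], with a `grade` column
#'   (HG/LG or 1/0).
#' @return list with `counts` (data.frame: criterion, n/pct total and by
#'   grade), `n`, `n_positive`, and `benign_among_positives_pct` (`NA` when
#'   no lesion is positive).
#' @export
fukuoka_cohort_summary <- function(records) {
  if (!"grade" %in% names(records)) stop("missing column: grade")
  grade <- parse_grade(records$grade)
  flags <- classify_fukuoka(records)
  n <- nrow(flags)
  n_hg <- sum(grade == 1L); n_lg <- sum(grade == 0L)
  counts <- do.call(rbind, lapply(FUKUOKA_CRITERIA, function(cr) {
    f <- flags[[cr]]
    data.frame(criterion = cr,
               n_total = sum(f), pct_total = round(100 * sum(f) / n),
               n_hg = sum(f & grade == 1L),
               pct_hg = round(100 * sum(f & grade == 1L) / n_hg),
               n_lg = sum(f & grade == 0L),
               pct_lg = round(100 * sum(f & grade == 0L) / n_lg),
               stringsAsFactors = FALSE)
  }))
  n_pos <- sum(flags$positive)
  benign_pct <- if (n_pos == 0) NA_real_ else
    round(100 * sum(flags$positive & grade == 0L) / n_pos)
  list(counts = counts, n = n, n_hg = n_hg, n_lg = n_lg,
       n_positive = n_pos, benign_among_positives_pct = benign_pct)
}
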