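# Feature-table container: a plain data.frame with a `subject_id` column, a
# binary `grade` column (1 = high grade, 0 = low grade) and numeric marker
# columns. Kept deliberately unexotic so users can manipulate it with base R.

#' Construct a feature table
#'
#' @param subject_id character vector of unique subject identifiers.
#' @param grade binary grade per subject: 1/0 or "HG"/"LG" (HG is the
#'   positive class).
#' @param markers data.frame or matrix of numeric marker columns.
#' @return a `data.frame` of class `feature_table`.
#' @export
feature_table <- function(subject_id, grade, markers) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id))
    stop("duplicate subject_id: ", subject_id[duplicated(subject_id)][1])
  grade <- parse_grade(grade)
  markers <- as.data.frame(markers, optional = TRUE)
  if (length(subject_id) != length(grade) ||
      nrow(markers) != length(grade))
    stop("subject_id, grade and markers disagree on the number of subjects")
  bad <- names(markers)[!vapply(markers, is.numeric, logical(1))]
  if (length(bad)) stop("non-numeric marker column: ", bad[1])
  tab <- data.frame(subject_id = subject_id, grade = grade, markers,
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

parse_grade <- function(grade) {
  if (is.character(grade) || is.factor(grade)) {
    grade <- as.character(grade)
    ok <- grade %in% c("HG", "LG")
    if (!all(ok)) stop("invalid grade label: '", grade[!ok][1],
                       "' (expected HG/LG or 1/0)")
    return(as.integer(grade == "HG"))
  }
  g <- as.integer(grade)
  if (any(is.na(g)) || !all(g %in% c(0L, 1L)))
    stop("grade must be coded HG/LG or 1/0")
  g
}

#' Marker column names of a feature table
#' @param table a `feature_table`.
#' @export
marker_names <- function(table) {
  setdiff(names(table), c("subject_id", "grade"))
}

#' Numeric marker matrix of a feature table
#' @param table a `feature_table`.
#' @param markers optional subset of marker names.
#' @export
marker_matrix <- function(table, markers = marker_names(table)) {
  missing <- setdiff(markers, names(table))
  if (length(missing)) stop("marker not in table: ", missing[1])
  as.matrix(table[, markers, drop = FALSE])
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects (%d HG / %d LG), %d markers\n",
              nrow(x), sum(x$grade == 1L), sum(x$grade == 0L),
              length(marker_names(x))))
  invisible(x)
}

#' Read a feature table from CSV
#'
#' The file must have a header with `subject_id` and `grade` columns; all
#' remaining columns are numeric markers. Grade may be coded HG/LG or 1/0.
#'
#' @param path CSV file path.
#' @return a `feature_table`.
#' @export
load_feature_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c("subject_id", "grade"))
    if (!col %in% names(raw)) stop("missing required column: ", col)
  mk <- setdiff(names(raw), c("subject_id", "grade"))
  markers <- lapply(mk, function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   raw[[col]][bad[1]], col, bad[1]))
    v
  })
  names(markers) <- mk
  feature_table(raw$subject_id, raw$grade,
                as.data.frame(markers, check.names = FALSE))
}

#' Write a feature table to CSV
#'
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @param grade_labels write grades as "HG"/"LG" (default) rather than 1/0.
#' @export
write_feature_csv <- function(table, path, grade_labels = TRUE) {
  out <- as.data.frame(table)
  if (grade_labels) out$grade <- ifelse(out$grade == 1L, "HG", "LG")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
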