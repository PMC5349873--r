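# Gray-level co-occurrence matrix (GLCM) texture features over ROI-masked
# volumes. Conventions follow Haralick: a symmetric GLCM accumulates each
# ordered voxel pair and its reverse; features are computed on the normalized
# joint probability matrix p(i, j) of quantized gray levels 0..levels-1.
#
# Offsets are integer voxel displacements (dx, dy, dz) applied as
# (row + dx*d, col + dy*d, slice + dz*d) in 0-based terms; anisotropic
# spacing is ignored. "2.5D" restricts offsets in-plane (dz = 0) so that all
# pairs stay within a slice and counts pool across slices.

#' Canonical GLCM direction sets
#'
#' The 13 unique 3D directions (one per opposite-direction pair), or the 4
#' unique in-plane directions used by 2.5D extraction.
#'
#' @param mode `"3D"` or `"2.5D"`.
#' @return matrix with one `(dx, dy, dz)` direction per row.
#' @export
glcm_directions <- function(mode = c("3D", "2.5D")) {
  mode <- match.arg(mode)
  inplane <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
  if (mode == "2.5D") return(inplane)
  rbind(inplane,
        c(0, 0, 1),
        c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

#' Specify one GLCM computation
#'
#' @param direction integer offset vector `(dx, dy, dz)`, components coprime.
#' @param distance positive integer multiplier of the direction.
#' @param mode `"3D"` or `"2.5D"` (2.5D requires `dz = 0`).
#' @param levels number of gray levels after quantization.
#' @param symmetric accumulate each pair in both orders (default, standard
#'   Haralick practice).
#' @return a `glcm_spec` list.
#' @export
glcm_spec <- function(direction, distance = 1L, mode = c("3D", "2.5D"),
                      levels = 32L, symmetric = TRUE) {
  mode <- match.arg(mode)
  direction <- as.integer(direction)
  stopifnot(length(direction) == 3L, distance >= 1L, levels >= 2L)
  if (all(direction == 0L)) stop("direction must be nonzero")
  if (mode == "2.5D" && direction[3] != 0L)
    stop("2.5D mode requires an in-plane direction (dz = 0)")
  structure(list(direction = direction, distance = as.integer(distance),
                 mode = mode, levels = as.integer(levels),
                 symmetric = isTRUE(symmetric)),
            class = "glcm_spec")
}

#' Default grid of GLCM specs
#'
#' All canonical directions for the given mode crossed with the given
#' distances. Default distances 1, 4 and 7 voxels.
#'
#' @inheritParams glcm_spec
#' @param distances integer vector of offset distances.
#' @return list of `glcm_spec`.
#' @export
glcm_spec_grid <- function(mode = c("3D", "2.5D"), distances = c(1L, 4L, 7L),
                           levels = 32L, symmetric = TRUE) {
  mode <- match.arg(mode)
  dirs <- glcm_directions(mode)
  specs <- list()
  for (d in distances)
    for (r in seq_len(nrow(dirs)))
      specs[[length(specs) + 1L]] <-
        glcm_spec(dirs[r, ], d, mode, levels, symmetric)
  specs
}

glcm_spec_name <- function(spec, statistic) {
  sprintf("GLCM%s_%s-%d_%s",
          if (spec$mode == "3D") "3" else "25",
          paste0(spec$direction, collapse = ""), spec$distance, statistic)
}

#' Quantize ROI voxels to integer gray levels
#'
#' Equal-width binning of the masked voxels over their own min-max range;
#' the maximum maps to `levels - 1` and a constant ROI maps to level 0.
#'
#' @param image list with a 3D `voxels` array (e.g. from [read_nifti()]).
#' @param mask binary array (or list with `voxels`) of the same shape.
#' @param levels number of gray levels (>= 2).
#' @return integer 3D array of levels 0..levels-1, `NA` outside the mask.
#' @export
quantize_roi <- function(image, mask, levels = 32L) {
  v <- if (is.list(image)) image$voxels else image
  m <- if (is.list(mask)) mask$voxels else mask
  stopifnot(levels >= 2L)
  if (!identical(dim(v), dim(m))) stop("image and mask shapes differ")
  m <- m != 0
  n_in <- sum(m)
  if (n_in < 2L) stop("mask selects fewer than 2 voxels")
  vals <- v[m]
  rng <- range(vals)
  q <- array(NA_integer_, dim = dim(v))
  if (rng[1] == rng[2]) {
    q[m] <- 0L
  } else {
    lev <- as.integer(floor((vals - rng[1]) / (rng[2] - rng[1]) * levels))
    lev[lev == levels] <- levels - 1L
    q[m] <- lev
  }
  q
}

#' Compute one GLCM over a quantized ROI
#'
#' Counts are accumulated only over voxel pairs whose both endpoints lie
#' inside the mask (non-`NA` in the quantized array), then normalized to a
#' joint probability matrix. Symmetric mode adds the transposed counts.
#'
#' @param quantized integer array from [quantize_roi()] (`NA` outside ROI).
#' @param spec a [glcm_spec()].
#' @return a `glcm` object: `p` (levels x levels), marginal means `mu_i`,
#'   `mu_j`, marginal SDs `sigma_i`, `sigma_j`, and `n_pairs`.
#' @export
compute_glcm <- function(quantized, spec) {
  stopifnot(inherits(spec, "glcm_spec"))
  d <- dim(quantized)
  o <- spec$direction * spec$distance
  idx <- lapply(1:3, function(k) {
    r <- seq_len(d[k])
    r[r + o[k] >= 1L & r + o[k] <= d[k]]
  })
  if (any(lengths(idx) == 0L))
    stop_no_pairs(spec)
  a1 <- quantized[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  a2 <- quantized[idx[[1]] + o[1], idx[[2]] + o[2], idx[[3]] + o[3],
                  drop = FALSE]
  ok <- !is.na(a1) & !is.na(a2)
  if (!any(ok)) stop_no_pairs(spec)
  L <- spec$levels
  cnt <- tabulate(a1[ok] + L * a2[ok] + 1L, nbins = L * L)
  cnt <- matrix(cnt, nrow = L, ncol = L)   # cnt[i+1, j+1]
  if (spec$symmetric) cnt <- cnt + t(cnt)
  n_pairs <- sum(cnt)
  p <- cnt / n_pairs
  lev <- 0:(L - 1)
  p_i <- rowSums(p); p_j <- colSums(p)
  mu_i <- sum(lev * p_i); mu_j <- sum(lev * p_j)
  structure(list(p = p, levels = L,
                 mu_i = mu_i, mu_j = mu_j,
                 sigma_i = sqrt(sum((lev - mu_i)^2 * p_i)),
                 sigma_j = sqrt(sum((lev - mu_j)^2 * p_j)),
                 n_pairs = n_pairs, spec = spec),
            class = "glcm")
}

stop_no_pairs <- function(spec) {
  stop(structure(class = c("radpanel_no_pairs", "error", "condition"),
                 list(message = sprintf(
                   "no valid voxel pair for offset (%s) x %d",
                   paste(spec$direction, collapse = ","), spec$distance),
                   call = NULL)))
}

#' Haralick correlation of a GLCM
#'
#' \eqn{\sum_{i,j} (i-\mu_i)(j-\mu_j) p(i,j) / (\sigma_i \sigma_j)}. When a
#' marginal SD is zero (homogeneous region) the conventional sentinel 1.0 is
#' returned so feature tables stay rectangular.
#'
#' @param glcm a `glcm` object.
#' @return correlation in `[-1, 1]`.
#' @export
glcm_correlation <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  s <- glcm$sigma_i * glcm$sigma_j
  if (s == 0) return(1.0)
  lev <- 0:(glcm$levels - 1)
  cross <- sum(outer(lev - glcm$mu_i, lev - glcm$mu_j) * glcm$p)
  max(-1, min(1, cross / s))
}

#' Secondary Haralick statistics of a GLCM
#'
#' @param glcm a `glcm` object.
#' @return list with `contrast`, `entropy` (bits), `energy`, `homogeneity`.
#' @export
glcm_secondary_stats <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  lev <- 0:(glcm$levels - 1)
  dif <- outer(lev, lev, "-")
  p <- glcm$p
  pos <- p > 0
  list(contrast = sum(p * dif^2),
       entropy = -sum(p[pos] * log2(p[pos])),
       energy = sum(p^2),
       homogeneity = sum(p / (1 + abs(dif))))
}

#' First-order intensity statistics over a masked ROI
#'
#' Mean and population SD of masked voxel values; non-excess kurtosis
#' (standardized fourth central moment, so a Gaussian gives 3); Shannon
#' entropy in bits of an equal-width histogram of the masked values.
#'
#' @inheritParams quantize_roi
#' @param entropy_bins number of histogram bins for the entropy estimate.
#' @return list with `mean`, `sd`, `kurtosis` (`NA` for < 4 voxels or zero
#'   variance), `entropy`.
#' @export
first_order_stats <- function(image, mask, entropy_bins = 32L) {
  v <- if (is.list(image)) image$voxels else image
  m <- if (is.list(mask)) mask$voxels else mask
  if (!identical(dim(v), dim(m))) stop("image and mask shapes differ")
  vals <- v[m != 0]
  n <- length(vals)
  if (n < 2L) stop("mask selects fewer than 2 voxels")
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  kurt <- if (n < 4L || m2 == 0) NA_real_ else mean((vals - mu)^4) / m2^2
  rng <- range(vals)
  ent <- if (rng[1] == rng[2]) 0 else {
    h <- tabulate(pmin(entropy_bins, 1L + as.integer(
      floor((vals - rng[1]) / (rng[2] - rng[1]) * entropy_bins))),
      nbins = entropy_bins)
    pr <- h[h > 0] / n
    -sum(pr * log2(pr))
  }
  list(mean = mu, sd = sqrt(m2), kurtosis = kurt, entropy = ent)
}

#' Extract a feature table from an image cohort
#'
#' Computes first-order statistics and the requested GLCM statistics for each
#' subject. GLCM columns are named `GLCM{3|25}_{dx}{dy}{dz}-{distance}_{stat}`.
#' A feature that cannot be computed for a subject (no valid voxel pair, or a
#' degenerate kurtosis) is recorded as missing; markers missing for any
#' subject are then dropped with a warning so the returned table is complete.
#'
#' @param cohort list of subjects, each a list with `image`, `mask`, `grade`
#'   and optionally `subject_id` (as produced by [generate_texture_cohort()]).
#' @param specs list of [glcm_spec()]; default [glcm_spec_grid()] in 3D.
#' @param levels quantization levels.
#' @param statistics GLCM statistics to compute, a subset of
#'   `c("correlation", "contrast", "entropy", "energy", "homogeneity")`.
#' @param first_order include first-order statistics columns (`FO_*`).
#' @return a [feature_table()].
#' @export
extract_features <- function(cohort,
                             specs = glcm_spec_grid("3D", levels = levels),
                             levels = 32L,
                             statistics = "correlation",
                             first_order = TRUE) {
  stopifnot(length(cohort) >= 1L, length(specs) >= 1L)
  statistics <- match.arg(statistics,
                          c("correlation", "contrast", "entropy", "energy",
                            "homogeneity"), several.ok = TRUE)
  rows <- lapply(seq_along(cohort), function(s) {
    subj <- cohort[[s]]
    v <- if (is.list(subj$image)) subj$image$voxels else subj$image
    m <- if (is.list(subj$mask)) subj$mask$voxels else subj$mask
    if (!identical(dim(v), dim(m)))
      stop("subject ", s, ": image and mask shapes differ")
    out <- list()
    if (first_order) {
      fo <- first_order_stats(v, m)
      out[paste0("FO_", names(fo))] <- fo
    }
    q <- quantize_roi(v, m, levels)
    for (spec in specs) {
      res <- tryCatch({
        g <- compute_glcm(q, spec)
        vals <- list()
        if ("correlation" %in% statistics)
          vals$correlation <- glcm_correlation(g)
        if (length(setdiff(statistics, "correlation"))) {
          sec <- glcm_secondary_stats(g)
          for (st in setdiff(statistics, "correlation")) vals[[st]] <- sec[[st]]
        }
        vals
      }, radpanel_no_pairs = function(e) {
        stats::setNames(as.list(rep(NA_real_, length(statistics))), statistics)
      })
      for (st in names(res))
        out[[glcm_spec_name(spec, st)]] <- res[[st]]
    }
    out
  })
  markers <- as.data.frame(do.call(rbind, lapply(rows, function(r)
    unlist(r)[names(rows[[1]])])), check.names = FALSE)
  ids <- vapply(seq_along(cohort), function(s)
    cohort[[s]]$subject_id %||% sprintf("S%03d", s), character(1))
  grades <- vapply(cohort, function(subj) subj$grade, character(1))
  incomplete <- names(markers)[vapply(markers, anyNA, logical(1))]
  if (length(incomplete)) {
    warning("dropping ", length(incomplete),
            " marker(s) missing for at least one subject: ",
            paste(utils::head(incomplete, 5), collapse = ", "),
            if (length(incomplete) > 5) ", ..." else "")
    markers <- markers[, setdiff(names(markers), incomplete), drop = FALSE]
  }
  feature_table(ids, grades, markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
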