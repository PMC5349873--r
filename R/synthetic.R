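# Seeded synthetic cohorts emulating the statistical structure the analysis
# assumes: (a) textured 3D volumes with ellipsoidal ROIs whose spatial
# correlation length differs by grade, (b) binormal marker tables with
# designed AUCs, (c) clinical lesion records reproducing requested Fukuoka
# criterion margins exactly while keeping every record criterion-positive.

#' Texture class specification
#'
#' Describes one grade's generative texture: an isotropic Gaussian random
#' field (white noise convolved with a Gaussian kernel of width
#' `field_smoothing` voxels), rescaled to `intensity_mean`/`intensity_sd`,
#' plus additive white noise. The smoothing length directly controls the
#' spatial gray-level correlation the GLCM correlation statistic measures.
#'
#' @param label grade label, `"HG"` or `"LG"`.
#' @param field_smoothing spatial correlation length in voxels (> 0).
#' @param intensity_mean,intensity_sd gray-value offset and scale
#'   (`intensity_sd` > 0).
#' @param noise_sd additive white-noise SD (>= 0).
#' @export
texture_class_spec <- function(label = c("HG", "LG"), field_smoothing = 1,
                               intensity_mean = 100, intensity_sd = 20,
                               noise_sd = 5) {
  label <- match.arg(label)
  stopifnot(field_smoothing > 0, intensity_sd > 0, noise_sd >= 0)
  structure(list(label = label, field_smoothing = field_smoothing,
                 intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd, noise_sd = noise_sd),
            class = "texture_class_spec")
}

# Periodic Gaussian random field via FFT convolution of white noise with a
# Gaussian kernel, standardized to mean 0 / SD 1 over the volume.
.gaussian_random_field <- function(shape, smoothing) {
  noise <- array(stats::rnorm(prod(shape)), dim = shape)
  if (smoothing <= 0.05) return((noise - mean(noise)) / stats::sd(noise))
  ax <- lapply(shape, function(d) {
    i <- seq_len(d) - 1L
    pmin(i, d - i)                        # periodic distance to origin
  })
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  kern <- exp(-d2 / (2 * smoothing^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern),
                      inverse = TRUE)) / prod(shape)
  (sm - mean(sm)) / stats::sd(sm)
}

# Centered axis-aligned ellipsoid mask with seeded +/-10% radius jitter.
# On coarse grids discretization can push coverage below the 20% floor; the
# radii are then grown in 5% steps until the floor is met.
.ellipsoid_mask <- function(shape, base_frac = 0.42, jitter = 0.10) {
  jit <- stats::runif(3, 1 - jitter, 1 + jitter)
  ctr <- (shape + 1) / 2
  repeat {
    radii <- base_frac * shape * jit
    ax <- lapply(1:3, function(k) ((seq_len(shape[k]) - ctr[k]) / radii[k])^2)
    d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
    mask <- array(d2 <= 1, dim = shape)
    if (mean(mask) >= 0.20 || base_frac > 0.6) return(mask)
    base_frac <- base_frac * 1.05
  }
}

#' Generate a textured two-class image cohort
#'
#' Each subject is a smoothed Gaussian random field (correlation length per
#' class spec) plus white noise, with an ellipsoidal ROI mask covering at
#' least 20\% of the volume. Fully reproducible from `seed`.
#'
#' @param n_hg,n_lg subjects per grade (>= 1); defaults 34 and 19, the
#'   cohort size the pipeline is designed around.
#' @param shape voxel dimensions, each >= 8.
#' @param hg_spec,lg_spec [texture_class_spec()] per grade. The defaults
#'   (smoothing 2.5 vs 1.0 voxels, identical intensity statistics) put the
#'   grade signal purely in texture, not in first-order intensity.
#' @param seed integer seed.
#' @return list of subjects, each
#'   `list(subject_id, image = list(voxels, spacing), mask = list(voxels,
#'   region_kind), grade)`.
#' @export
generate_texture_cohort <- function(n_hg = 34L, n_lg = 19L,
                                    shape = c(24L, 24L, 16L),
                                    hg_spec = texture_class_spec(
                                      "HG", field_smoothing = 2.5),
                                    lg_spec = texture_class_spec(
                                      "LG", field_smoothing = 1.0),
                                    seed = NULL) {
  stopifnot(n_hg >= 1L, n_lg >= 1L, length(shape) == 3L)
  shape <- as.integer(shape)
  if (any(shape < 8L))
    stop("each volume dimension must be >= 8 to contain an ellipsoidal ROI")
  if (!is.null(seed)) set.seed(seed)
  grades <- c(rep("HG", n_hg), rep("LG", n_lg))
  lapply(seq_along(grades), function(s) {
    spec <- if (grades[s] == "HG") hg_spec else lg_spec
    field <- .gaussian_random_field(shape, spec$field_smoothing)
    vox <- spec$intensity_mean + spec$intensity_sd * field +
      stats::rnorm(prod(shape), sd = spec$noise_sd)
    mask <- .ellipsoid_mask(shape)
    stopifnot(mean(mask) >= 0.20)
    list(subject_id = sprintf("%s%03d", grades[s], s),
         image = list(voxels = array(vox, dim = shape), spacing = c(1, 1, 1)),
         mask = list(voxels = mask, region_kind = "cyst"),
         grade = grades[s])
  })
}

#' Binormal marker specification
#'
#' A marker with LG ~ N(0, 1) and HG ~ N(delta, 1) where
#' `delta = sqrt(2) * qnorm(target_auc)`, so its population AUC equals
#' `target_auc`. `correlation_to_previous` optionally correlates the
#' marker's noise with the preceding spec's marker.
#'
#' @param name marker name.
#' @param target_auc designed AUC in `[0.5, 1)`.
#' @param correlation_to_previous optional correlation in `(-1, 1)`.
#' @export
binormal_marker_spec <- function(name, target_auc,
                                 correlation_to_previous = NULL) {
  if (target_auc < 0.5 || target_auc >= 1)
    stop("target_auc must lie in [0.5, 1)")
  if (!is.null(correlation_to_previous) &&
      abs(correlation_to_previous) >= 1)
    stop("correlation_to_previous must lie in (-1, 1)")
  structure(list(name = as.character(name), target_auc = target_auc,
                 correlation_to_previous = correlation_to_previous),
            class = "binormal_marker_spec")
}

#' Class-mean separation for a designed binormal AUC
#' @param target_auc AUC in `[0.5, 1)`.
#' @return `delta = sqrt(2) * qnorm(target_auc)`.
#' @export
binormal_delta <- function(target_auc) {
  if (any(target_auc < 0.5 | target_auc >= 1))
    stop("target_auc must lie in [0.5, 1)")
  sqrt(2) * stats::qnorm(target_auc)
}

#' Generate a binormal feature table with designed marker AUCs
#'
#' Informative markers follow the binormal model (unit variance in both
#' classes, HG mean shifted by [binormal_delta()]); noise markers are
#' standard normal in both classes.
#'
#' @param n_hg,n_lg subjects per grade.
#' @param specs list of [binormal_marker_spec()] (nonempty), or a named
#'   numeric vector of target AUCs.
#' @param n_noise_markers additional pure-noise markers (named `noise_k`).
#' @param seed integer seed.
#' @return a [feature_table()].
#' @export
generate_feature_table <- function(n_hg = 34L, n_lg = 19L, specs,
                                   n_noise_markers = 0L, seed = NULL) {
  stopifnot(n_hg >= 1L, n_lg >= 1L)
  if (is.numeric(specs)) {
    nm <- names(specs) %||% paste0("marker_", seq_along(specs))
    specs <- lapply(seq_along(specs), function(i)
      binormal_marker_spec(nm[i], specs[i]))
  }
  if (length(specs) == 0L) stop("specs must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  n <- n_hg + n_lg
  grade <- c(rep(1L, n_hg), rep(0L, n_lg))
  cols <- list()
  prev_noise <- NULL
  for (sp in specs) {
    stopifnot(inherits(sp, "binormal_marker_spec"))
    eps <- stats::rnorm(n)
    rho <- sp$correlation_to_previous
    if (!is.null(rho) && !is.null(prev_noise))
      eps <- rho * prev_noise + sqrt(1 - rho^2) * eps
    cols[[sp$name]] <- eps + binormal_delta(sp$target_auc) * grade
    prev_noise <- eps
  }
  if (n_noise_markers > 0L)
    for (k in seq_len(n_noise_markers))
      cols[[paste0("noise_", k)]] <- stats::rnorm(n)
  feature_table(sprintf("S%04d", seq_len(n)), grade,
                as.data.frame(cols, check.names = FALSE))
}

#' Criterion margins of the reference 53-subject cohort
#'
#' Per-grade counts of each worrisome feature in the 34 HG / 19 LG resected
#' cohort the pipeline is modeled on (main duct, cyst > 3 cm, mural
#' nodules, MPD > 5 mm, positive cytology, symptomatic).
#'
#' @return list with integer vectors `HG` and `LG`, named by criterion.
#' @export
reference_fukuoka_margins <- function() {
  list(HG = stats::setNames(c(2L, 13L, 6L, 9L, 4L, 8L), FUKUOKA_CRITERIA),
       LG = stats::setNames(c(4L, 10L, 1L, 3L, 2L, 2L), FUKUOKA_CRITERIA))
}

# Deterministic-greedy allocation of criterion flags: rarest criterion first,
# each assigned preferentially to still-uncovered subjects (seeded order),
# remainder round-robin over the least-flagged subjects. Guarantees every
# subject gets >= 1 flag whenever sum(counts) >= n.
.allocate_flags <- function(n, counts) {
  if (sum(counts) < n)
    stop("infeasible margins: ", sum(counts), " criterion slots for ", n,
         " subjects (every subject must trigger at least one criterion)")
  stopifnot(all(counts <= n), all(counts >= 0))
  flags <- matrix(FALSE, n, length(counts),
                  dimnames = list(NULL, names(counts)))
  for (cr in order(counts, sample.int(length(counts)))) {
    need <- counts[cr]
    if (need == 0L) next
    uncovered <- which(rowSums(flags) == 0L)
    take <- utils::head(sample(uncovered), min(need, length(uncovered)))
    flags[take, cr] <- TRUE
    need <- need - length(take)
    if (need > 0L) {
      rest <- setdiff(seq_len(n), take)
      rest <- rest[order(rowSums(flags[rest, , drop = FALSE]),
                         sample.int(length(rest)))]
      flags[rest[seq_len(need)], cr] <- TRUE
    }
  }
  flags
}

#' Generate Fukuoka lesion records matching per-grade criterion margins
#'
#' Boolean criterion flags are allocated so that the per-grade count of each
#' criterion matches `margins` exactly and every record triggers at least
#' one criterion (the cohort modeled is all-Fukuoka-positive). Continuous
#' fields are drawn to strictly satisfy their flag: cyst size
#' U(3.1, 6.0) cm when flagged else U(0.5, 3.0); MPD diameter U(5.5, 10) mm
#' when flagged else U(1, 5).
#'
#' @param n_hg,n_lg subjects per grade.
#' @param margins list with per-grade criterion counts (`HG`, `LG`), as in
#'   [reference_fukuoka_margins()].
#' @param seed integer seed.
#' @return data.frame of lesion records suitable for [classify_fukuoka()].
#' @export
generate_fukuoka_cohort <- function(n_hg = 34L, n_lg = 19L,
                                    margins = reference_fukuoka_margins(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per_grade <- list(HG = n_hg, LG = n_lg)
  recs <- lapply(c("HG", "LG"), function(g) {
    counts <- margins[[g]]
    stopifnot(length(counts) == length(FUKUOKA_CRITERIA))
    names(counts) <- FUKUOKA_CRITERIA
    n <- per_grade[[g]]
    flags <- .allocate_flags(n, counts)
    data.frame(
      subject_id = sprintf("%s%03d", g, seq_len(n)),
      main_duct_involvement = flags[, "main_duct"],
      cyst_size_cm = ifelse(flags[, "cyst_gt_3cm"],
                            stats::runif(n, 3.1, 6.0),
                            stats::runif(n, 0.5, 3.0)),
      mural_nodule = flags[, "mural_nodule"],
      mpd_diameter_mm = ifelse(flags[, "mpd_gt_5mm"],
                               stats::runif(n, 5.5, 10),
                               stats::runif(n, 1, 5)),
      positive_cytology = flags[, "positive_cytology"],
      symptomatic = flags[, "symptomatic"],
      grade = g,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write a generated image cohort as NIfTI files plus a JSON sidecar
#'
#' @param cohort output of [generate_texture_cohort()].
#' @param dir output directory (created if needed).
#' @param params list of generation parameters recorded in `cohort.json`.
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return the sidecar path, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir, params = list(), gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  manifest <- lapply(cohort, function(subj) {
    img <- file.path(dir, paste0(subj$subject_id, "_image", ext))
    msk <- file.path(dir, paste0(subj$subject_id, "_mask", ext))
    write_nifti(subj$image$voxels, img, subj$image$spacing)
    write_nifti(subj$mask$voxels + 0, msk, subj$image$spacing)
    list(subject_id = subj$subject_id, grade = subj$grade,
         image = basename(img), mask = basename(msk))
  })
  sidecar <- file.path(dir, "cohort.json")
  jsonlite::write_json(list(params = params, subjects = manifest),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Read a cohort written by [write_cohort_nifti()]
#' @param dir cohort directory containing `cohort.json`.
#' @export
read_cohort_nifti <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"))
  lapply(meta$subjects, function(s) {
    img <- read_nifti(file.path(dir, s$image))
    msk <- read_nifti(file.path(dir, s$mask))
    list(subject_id = s$subject_id, image = img,
         mask = list(voxels = msk$voxels != 0, region_kind = "cyst"),
         grade = s$grade)
  })
}
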