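#' Configuration for the synthetic follow-up cohort
#'
#' Defines the statistical structure of a fully in-silico multi-parametric MRI
#' cohort: a set of patients scanned at several follow-up time points, each
#' time point carrying the 16 co-registered parameter maps (4 cMRI, 5 PWI,
#' 7 DKI) plus a whole-tumor mask and a contralateral normal-appearing white
#' matter (NAWM) mask. Labeled time points are split between a progressive and
#' a responsive class at the patient level: all of one patient's labeled scans
#' share one label. Progressive time points carry an elevated T1pc and CBV
#' signal inside the enhancing rim of the tumor ellipsoid, scaled by
#' `effect_size`.
#'
#' The defaults reproduce the cohort structure the pipeline is designed for:
#' 29 patients contributing 55 complete labeled time points with a 34/21
#' progressive/responsive split, plus unlabeled pre-decision scans that enter
#' only the cohort-wide feature scaling.
#'
#' @param n_patients Number of patients (>= 2).
#' @param labeled_timepoints_total Total labeled time points across patients.
#' @param class_ratio Fraction of labeled time points that are progressive
#'   (strictly between 0 and 1). The progressive count is
#'   `round(class_ratio * labeled_timepoints_total)`.
#' @param n_unlabeled Unlabeled (pre-decision) time points per patient; these
#'   carry half the class effect and are used only for feature scaling.
#' @param grid_shape Integer vector of 3 voxel dimensions.
#' @param voxel_noise_sd Standard deviation of the additive Gaussian voxel
#'   noise, in the same arbitrary intensity units as the tissue baselines
#'   (which are of order 100).
#' @param effect_size Dimensionless multiplier on the T1pc/CBV rim elevation
#'   for progressive time points; 0 removes all class signal.
#' @param seed Integer RNG seed; identical seed and config give a
#'   bit-identical cohort.
#' @return A `cohort_config` list.
#' @examples
#' cfg <- cohort_config(n_patients = 4, labeled_timepoints_total = 8,
#'                      grid_shape = c(24, 24, 12), seed = 1)
#' @export
cohort_config <- function(n_patients = 29L,
                          labeled_timepoints_total = 55L,
                          class_ratio = 34 / 55,
                          n_unlabeled = 1L,
                          grid_shape = c(64L, 64L, 32L),
                          voxel_noise_sd = 8,
                          effect_size = 1,
                          seed = 1L) {
  stopifnot_scalar_count(n_patients, "n_patients", min = 2L)
  stopifnot_scalar_count(labeled_timepoints_total, "labeled_timepoints_total", min = 2L)
  stopifnot_scalar_count(n_unlabeled, "n_unlabeled", min = 0L)
  stopifnot_scalar_count(seed, "seed", min = 0L)
  if (!is.numeric(class_ratio) || length(class_ratio) != 1L ||
      class_ratio <= 0 || class_ratio >= 1) {
    abort("`class_ratio` must lie strictly between 0 and 1")
  }
  if (length(grid_shape) != 3L || any(grid_shape < 8) ||
      any(grid_shape != round(grid_shape))) {
    abort("`grid_shape` must be three integer dimensions, each >= 8")
  }
  if (!is.numeric(effect_size) || effect_size < 0) {
    abort("`effect_size` must be >= 0")
  }
  if (!is.numeric(voxel_noise_sd) || voxel_noise_sd < 0) {
    abort("`voxel_noise_sd` must be >= 0")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      labeled_timepoints_total = as.integer(labeled_timepoints_total),
      class_ratio = class_ratio,
      n_unlabeled = as.integer(n_unlabeled),
      grid_shape = as.integer(grid_shape),
      voxel_noise_sd = voxel_noise_sd,
      effect_size = effect_size,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Distribute labeled time points over patients (as evenly as possible) and
# pick which patients are progressive so that the progressive time-point
# count hits round(class_ratio * total) exactly. Deterministic.
allocate_labels <- function(n_patients, total, class_ratio) {
  base <- total %/% n_patients
  rem <- total %% n_patients
  counts <- rep(base, n_patients) + c(rep(1L, rem), rep(0L, n_patients - rem))
  target <- round(class_ratio * total)
  if (target < 1 || target > total - 1) {
    abort("class_ratio leaves one class without labeled time points")
  }
  sel <- logical(n_patients)
  s <- 0L
  for (i in order(counts, decreasing = TRUE)) {
    if (counts[i] > 0 && s + counts[i] <= target) {
      sel[i] <- TRUE
      s <- s + counts[i]
    }
  }
  gap <- target - s
  if (gap > 0L) {
    # swap one selected patient for an unselected one with `gap` more points,
    # or transfer `gap` time points from an unselected to a selected patient
    fixed <- FALSE
    for (i in which(sel)) {
      j <- which(!sel & counts == counts[i] + gap)
      if (length(j)) {
        sel[i] <- FALSE
        sel[j[1L]] <- TRUE
        fixed <- TRUE
        break
      }
    }
    if (!fixed && any(sel)) {
      j <- which(!sel & counts >= gap + 1L)
      if (length(j)) {
        i <- which(sel)[1L]
        counts[i] <- counts[i] + gap
        counts[j[1L]] <- counts[j[1L]] - gap
        fixed <- TRUE
      }
    }
    if (!fixed) {
      abort("cannot partition labeled time points to match class_ratio exactly")
    }
  }
  list(counts = counts,
       label = ifelse(sel, "progressive", "responsive"))
}

# Tumor (ellipsoid + rim) and NAWM (sphere) voxel geometry on the grid.
# Returns logical arrays plus the normalized ellipsoidal radius used to
# define the enhancing rim (outermost 25% of the radius).
cohort_geometry <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  ix <- array(rep(seq_len(nx), times = ny * nz), dim = grid_shape)
  iy <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = grid_shape)
  iz <- array(rep(seq_len(nz), each = nx * ny), dim = grid_shape)

  tc <- c(0.32 * nx, 0.50 * ny, 0.50 * nz)
  ax <- c(0.16 * nx, 0.20 * ny, 0.26 * nz)
  rho <- sqrt(((ix - tc[1]) / ax[1])^2 +
              ((iy - tc[2]) / ax[2])^2 +
              ((iz - tc[3]) / ax[3])^2)
  total <- rho <= 1
  rim <- total & rho > 0.75

  nc <- c(0.75 * nx, 0.50 * ny, 0.50 * nz)
  nr <- min(0.13 * min(nx, ny), 0.45 * nz)
  nawm <- sqrt((ix - nc[1])^2 + (iy - nc[2])^2 + (iz - nc[3])^2) <= nr

  if (!any(total) || sum(nawm) < 30 || any(total & nawm)) {
    abort("grid too small to fit disjoint tumor and NAWM masks")
  }
  list(total = total, nawm = nawm, rim = rim)
}

# Per-map tissue baselines in arbitrary intensity units. Distinct constants
# per map; absolute scale is irrelevant downstream because every feature is
# computed on NAWM-normalized intensities.
map_baselines <- function() {
  idx <- seq_along(MAP_NAMES)
  tibble(
    map = MAP_NAMES,
    background = 20,
    nawm = 100 + 6 * idx,
    tumor = 1.25 * (100 + 6 * idx)
  )
}

#' Generate a synthetic multi-parametric MRI cohort
#'
#' Simulates every time point of the configured cohort: 16 parameter maps
#' built as tissue baselines (background / NAWM / tumor) plus additive
#' Gaussian voxel noise, with a per-(time point, map) global intensity gain
#' (emulating scanner gain; it cancels under NAWM normalization) and a
#' tumor-local biological jitter that creates class overlap. Progressive time
#' points have T1pc and CBV elevated inside the enhancing rim by
#' `effect_size` times the tumor baseline; unlabeled pre-decision scans of
#' progressive patients carry half that elevation.
#'
#' @param config A [cohort_config()].
#' @return An object of class `gbm_cohort`: a list with `timepoints` (each a
#'   `gbm_timepoint` carrying `maps`, `total_mask`, `nawm_mask`, ids and
#'   label), `manifest` (tibble with `patient_id`, `time_index`, `label`) and
#'   the `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 3,
#'   labeled_timepoints_total = 6, grid_shape = c(20, 20, 10), seed = 7))
#' cohort$manifest
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config()")
  }
  geom <- cohort_geometry(config$grid_shape)
  alloc <- allocate_labels(config$n_patients, config$labeled_timepoints_total,
                           config$class_ratio)
  baselines <- map_baselines()

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  timepoints <- list()
  rows <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    lab <- alloc$label[p]
    n_lab <- alloc$counts[p]
    tps <- c(rep("unlabeled", config$n_unlabeled), rep(lab, n_lab))
    for (ti in seq_along(tps)) {
      tp_label <- tps[ti]
      eff <- if (tp_label == "progressive") config$effect_size
             else if (tp_label == "unlabeled" && lab == "progressive")
               0.5 * config$effect_size
             else 0
      tp <- simulate_timepoint(pid, ti, tp_label, eff, geom, baselines, config)
      timepoints[[length(timepoints) + 1L]] <- tp
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = pid, time_index = ti, label = tp_label
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  structure(
    list(timepoints = timepoints, manifest = manifest, config = config),
    class = "gbm_cohort"
  )
}

# Two-scale voxel noise: half the variance is i.i.d. Gaussian, half lives on
# 4-voxel blocks (spatially correlated "biological texture"), so intensity
# percentile sets form coherent clusters the way contrast enhancement does,
# instead of salt-and-pepper voxels.
two_scale_noise <- function(shape, sd) {
  if (sd == 0) return(array(0, dim = shape))
  fine <- array(rnorm(prod(shape), 0, sd * sqrt(0.5)), dim = shape)
  cs <- pmax(1L, ceiling(shape / 4))
  coarse <- array(rnorm(prod(cs), 0, sd * sqrt(0.5)), dim = cs)
  ix <- (seq_len(shape[1]) - 1L) %/% 4L + 1L
  iy <- (seq_len(shape[2]) - 1L) %/% 4L + 1L
  iz <- (seq_len(shape[3]) - 1L) %/% 4L + 1L
  fine + coarse[ix, iy, iz, drop = FALSE]
}

simulate_timepoint <- function(patient_id, time_index, label, effect,
                               geom, baselines, config) {
  shape <- config$grid_shape
  maps <- vector("list", length(MAP_NAMES))
  names(maps) <- MAP_NAMES
  for (m in seq_along(MAP_NAMES)) {
    b <- baselines[m, ]
    vol <- array(b$background, dim = shape)
    vol[geom$nawm] <- b$nawm
    # tumor-local multiplicative jitter: biological variability that does not
    # cancel under NAWM normalization, giving the classes finite overlap
    tumor_jitter <- exp(rnorm(1, 0, 0.10))
    vol[geom$total] <- b$tumor * tumor_jitter
    if (MAP_NAMES[m] %in% c("T1pc", "CBV")) {
      # every tumor has mildly enhancing rim tissue; progression elevates it
      # further in proportion to effect_size
      vol[geom$rim] <- b$tumor * (1 + 0.15 + effect) * tumor_jitter
    }
    gain <- exp(rnorm(1, 0, 0.08))   # global scanner gain, cancels on NAWM division
    vol <- vol * gain + two_scale_noise(shape, config$voxel_noise_sd)
    maps[[m]] <- vol
  }
  structure(
    list(patient_id = patient_id, time_index = time_index, label = label,
         maps = maps, total_mask = geom$total, nawm_mask = geom$nawm),
    class = "gbm_timepoint"
  )
}

#' @export
print.gbm_cohort <- function(x, ...) {
  lab <- table(factor(x$manifest$label,
                      levels = c(CLASS_LEVELS, "unlabeled")))
  cat(sprintf(
    "<gbm_cohort> %d patients, %d time points (%d progressive / %d responsive / %d unlabeled), grid %s\n",
    x$config$n_patients, nrow(x$manifest),
    lab[["progressive"]], lab[["responsive"]], lab[["unlabeled"]],
    paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

#' Write a synthetic cohort to a directory of NIfTI volumes
#'
#' One `.nii.gz` per map and mask per time point plus a `manifest.csv` with
#' columns `patient_id,time_index,label,path_prefix`. Read-back round-trips
#' masks bit-exactly and maps within single-precision float tolerance.
#'
#' @param cohort A `gbm_cohort`.
#' @param directory Output directory (created if missing).
#' @param overwrite Overwrite existing files? Defaults to `FALSE`, in which
#'   case a collision is an error.
#' @return Invisibly, the manifest tibble including `path_prefix`.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  if (!inherits(cohort, "gbm_cohort")) abort("`cohort` must be a gbm_cohort")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(cohort$timepoints, function(tp) {
    prefix <- sprintf("%s_T%02d", tp$patient_id, tp$time_index)
    files <- c(
      setNames(file.path(directory, sprintf("%s_%s.nii.gz", prefix, MAP_NAMES)),
               MAP_NAMES),
      mask_total = file.path(directory, sprintf("%s_mask_total.nii.gz", prefix)),
      mask_nawm = file.path(directory, sprintf("%s_mask_nawm.nii.gz", prefix))
    )
    if (!overwrite && any(file.exists(files))) {
      abort(sprintf("output files for %s already exist; use overwrite = TRUE",
                    prefix))
    }
    for (m in MAP_NAMES) {
      RNifti::writeNifti(RNifti::asNifti(tp$maps[[m]]), files[[m]])
    }
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(tp$total_mask),
                                             dim = dim(tp$total_mask))),
                       files[["mask_total"]])
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(tp$nawm_mask),
                                             dim = dim(tp$nawm_mask))),
                       files[["mask_nawm"]])
    tibble(patient_id = tp$patient_id, time_index = tp$time_index,
           label = tp$label, path_prefix = prefix)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param directory Directory containing the NIfTI volumes and `manifest.csv`.
#' @return A `gbm_cohort` (without a generating `config`).
#' @export
read_cohort <- function(directory) {
  manifest_path <- file.path(directory, "manifest.csv")
  if (!file.exists(manifest_path)) abort("no manifest.csv in directory")
  manifest <- as_tibble(utils::read.csv(manifest_path,
                                        stringsAsFactors = FALSE))
  timepoints <- purrr::pmap(manifest, function(patient_id, time_index, label,
                                               path_prefix) {
    read_vol <- function(suffix) {
      v <- RNifti::readNifti(file.path(directory,
                                       sprintf("%s_%s.nii.gz", path_prefix, suffix)))
      array(as.vector(v), dim = dim(v))
    }
    maps <- setNames(lapply(MAP_NAMES, read_vol), MAP_NAMES)
    structure(
      list(patient_id = patient_id, time_index = time_index, label = label,
           maps = maps,
           total_mask = read_vol("mask_total") > 0,
           nawm_mask = read_vol("mask_nawm") > 0),
      class = "gbm_timepoint"
    )
  })
  structure(
    list(timepoints = timepoints,
         manifest = dplyr::select(manifest, -"path_prefix"),
         config = NULL),
    class = "gbm_cohort"
  )
}
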