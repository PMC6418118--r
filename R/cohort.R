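# Synthetic imaging cohorts: per-subject skeleton-masked scalar maps (an
# axial-diffusivity surrogate in arbitrary units) plus a covariates table.
# The generator can plant a negative slope-diffusivity association in a
# contiguous lateralised sub-region of the skeleton: within the region each
# subject's voxels are shifted by -effect_size * z(beta), so a steeper slope
# (larger beta) means lower diffusivity - the sign reported for axial
# diffusivity against the meta-volitional measure. Small age and sex trends
# can be spread across the whole mask as nuisance realism.

#' Specification of a synthetic skeleton cohort
#'
#' Defaults reproduce the study conditions: 13 subjects aged 21-28 with a
#' 6:7 male:female split, a thin skeleton mask over a 40 x 48 x 40 volume of
#' 2 mm voxels, a 150-voxel contiguous planted region in the low-x half, an
#' effect of 3 standard deviations of the voxel noise per SD of slope, and
#' subject noise SD 0.05 around a baseline of 1 (arbitrary units; the
#' downstream statistics are scale-invariant).
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param betas Optional explicit per-subject slope values. If `NULL`, slopes
#'   are drawn uniformly from `beta_range` when the cohort is generated.
#' @param observers Optional list of [observer_spec()]s; when supplied, each
#'   subject's slope is *estimated* by running a full adaptive session
#'   (`session_config()`) instead of being read from `betas`.
#' @param beta_range Range for drawn slopes, default `c(-1.5, 1)`.
#' @param shape Volume dimensions (each >= 32).
#' @param voxel_size Voxel edge lengths in mm.
#' @param mask_fraction Skeleton fraction of the volume, in `[0.01, 0.05]`.
#' @param region_size Planted-region size in voxels (0 disables planting).
#' @param effect_size Planted effect in map units per SD of slope; the
#'   planted sign is negative (steeper slope, lower diffusivity). Set 0 for a
#'   global-null cohort.
#' @param noise_sd Subject-level voxel noise SD (default 0.05).
#' @param baseline Mean map value (default 1).
#' @param age_range Ages are drawn uniformly over this range (years).
#' @param sex_ratio Integer `c(male, female)` counts; recycled/truncated to
#'   `n_subjects`. Sex is coded 0 = male, 1 = female.
#' @param age_effect,sex_effect Nuisance trends (map units per year; map
#'   units), applied across the whole mask.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13L, betas = NULL, observers = NULL,
                        beta_range = c(-1.5, 1),
                        shape = c(40L, 48L, 40L), voxel_size = c(2, 2, 2),
                        mask_fraction = 0.03, region_size = 150L,
                        effect_size = 0.15, noise_sd = 0.05, baseline = 1,
                        age_range = c(21, 28), sex_ratio = c(6L, 7L),
                        age_effect = 0.002, sex_effect = 0.01) {
  if (n_subjects < 3L) {
    abort("`n_subjects` must be at least 3.", class = "psivox_config_error")
  }
  if (!is.null(betas) && length(betas) != n_subjects) {
    abort("`betas` must have one value per subject.", class = "psivox_config_error")
  }
  if (!is.null(observers) && length(observers) != n_subjects) {
    abort("`observers` must have one spec per subject.", class = "psivox_config_error")
  }
  structure(list(n_subjects = as.integer(n_subjects), betas = betas,
                 observers = observers, beta_range = beta_range,
                 shape = as.integer(shape), voxel_size = voxel_size,
                 mask_fraction = mask_fraction,
                 region_size = as.integer(region_size),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline = baseline, age_range = age_range,
                 sex_ratio = as.integer(sex_ratio),
                 age_effect = age_effect, sex_effect = sex_effect),
            class = "cohort_spec")
}

# Pick a contiguous `size`-voxel region by breadth-first search over the
# 26-connected mask graph, seeded at one end of the primary curve.
grow_region <- function(mask, start_idx, size) {
  adj <- mask_adjacency(mask, connectivity = 26L)
  vox_id <- match(start_idx, adj$index)
  if (is.na(vox_id)) abort("Region seed is outside the mask.",
                           class = "psivox_internal_error")
  visited <- logical(length(adj$index))
  queue <- vox_id; visited[vox_id] <- TRUE
  out <- integer(0)
  while (length(queue) > 0 && length(out) < size) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    if (adj$ptr[v + 1L] == adj$ptr[v]) next
    nb <- adj$neighbors[(adj$ptr[v] + 1L):adj$ptr[v + 1L]]
    fresh <- nb[!visited[nb]]
    visited[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  if (length(out) < size) {
    abort("Mask component too small for the requested planted region.",
          class = "psivox_config_error")
  }
  adj$index[out[seq_len(size)]]
}

#' Generate a synthetic skeleton cohort
#'
#' Builds the skeleton mask, the covariates table and the per-subject maps
#' according to `spec`. Voxel values are
#' `baseline + age_effect * (age - mean age) + sex_effect * sex + noise`,
#' with an additional `-effect_size * z(beta)` shift inside the planted
#' region (slopes standardised across subjects before planting). The cohort
#' is bit-reproducible per seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param session Optional [session_config()] used when `spec$observers` is
#'   supplied.
#' @return An object of class `skeleton_cohort`: `data` (subjects x mask
#'   voxels matrix), `mask` (logical 3D array), `region` (linear voxel
#'   indices of the planted region, `integer(0)` if none), `affine` (NIfTI
#'   affine), `voxel_size`, `covariates` (tibble: `subject_id`, `beta_slope`,
#'   `age`, `sex`).
#' @export
make_cohort <- function(spec = cohort_spec(), seed = 1L, session = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  mask <- skeleton_mask(spec$shape,
                        target_fraction = spec$mask_fraction,
                        primary_min = max(200L, spec$region_size),
                        seed = derive_seed(seed, "mask"))

  region <- integer(0)
  if (spec$region_size > 0L) {
    primary <- attr(mask, "primary")
    region <- grow_region(mask, primary[1L], spec$region_size)
  }

  betas <- spec$betas
  if (is.null(betas) && is.null(spec$observers)) {
    betas <- with_seed(derive_seed(seed, "betas"),
                       runif(n, spec$beta_range[1], spec$beta_range[2]))
  } else if (!is.null(spec$observers)) {
    if (is.null(session)) session <- session_config()
    betas <- vapply(seq_len(n), function(i) {
      run_session(make_observer(spec$observers[[i]]), session,
                  seed = derive_seed(seed, "session", i))$estimate$beta
    }, numeric(1))
  }

  covariates <- with_seed(derive_seed(seed, "covariates"), {
    sex <- c(rep(0L, spec$sex_ratio[1]), rep(1L, spec$sex_ratio[2]))
    sex <- rep_len(sex, n)
    tibble(subject_id = sprintf("sub-%02d", seq_len(n)),
           beta_slope = betas,
           age = round(runif(n, spec$age_range[1], spec$age_range[2]), 1),
           sex = sex)
  })

  nv <- sum(mask)
  mask_idx <- which(mask)
  region_col <- match(region, mask_idx)
  z_beta <- as.vector(scale(betas))
  if (any(!is.finite(z_beta))) z_beta <- rep(0, n) # constant slopes: no contrast

  data <- with_seed(derive_seed(seed, "maps"), {
    noise <- matrix(rnorm(n * nv, 0, spec$noise_sd), nrow = n)
    m <- spec$baseline +
      spec$age_effect * (covariates$age - mean(covariates$age)) +
      spec$sex_effect * covariates$sex
    maps <- sweep(noise, 1, m, "+")
    if (length(region_col) > 0 && spec$effect_size != 0) {
      maps[, region_col] <- maps[, region_col] - spec$effect_size * z_beta
    }
    maps
  })

  affine <- diag(c(spec$voxel_size, 1))
  structure(list(data = data, mask = mask, region = region, affine = affine,
                 voxel_size = spec$voxel_size, covariates = covariates,
                 spec = spec, seed = seed),
            class = "skeleton_cohort")
}

#' @export
print.skeleton_cohort <- function(x, ...) {
  cat(sprintf("<skeleton_cohort> %d subjects, %d mask voxels (%.1f%% of %s), %d-voxel planted region\n",
              nrow(x$data), ncol(x$data),
              100 * ncol(x$data) / prod(dim(x$mask)),
              paste(dim(x$mask), collapse = "x"), length(x$region)))
  invisible(x)
}

#' Write a cohort to a directory of NIfTI volumes plus covariates CSV
#'
#' Writes `mask.nii`, one `<subject_id>.nii` per subject (values outside the
#' mask are zero), `region.nii` when a planted region exists (synthetic
#' ground truth, for validation only), and `covariates.csv` with header
#' `subject_id,beta_slope,age,sex`.
#'
#' @param cohort A `skeleton_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "skeleton_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shape <- dim(cohort$mask)
  as_nifti <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- cohort$voxel_size
    img
  }
  RNifti::writeNifti(as_nifti(array(as.numeric(cohort$mask), shape)),
                     file.path(dir, "mask.nii"))
  if (length(cohort$region) > 0) {
    reg <- array(0, shape); reg[cohort$region] <- 1
    RNifti::writeNifti(as_nifti(reg), file.path(dir, "region.nii"))
  }
  mask_idx <- which(cohort$mask)
  for (i in seq_len(nrow(cohort$data))) {
    vol <- array(0, shape)
    vol[mask_idx] <- cohort$data[i, ]
    RNifti::writeNifti(as_nifti(vol),
                       file.path(dir, paste0(cohort$covariates$subject_id[i], ".nii")))
  }
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"))
  invisible(dir)
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir Directory containing `mask.nii`, per-subject volumes and
#'   `covariates.csv`.
#' @return A `skeleton_cohort` (without generator spec).
#' @export
read_cohort <- function(dir) {
  cov_path <- file.path(dir, "covariates.csv")
  if (!file.exists(cov_path)) {
    abort(sprintf("No covariates.csv in '%s'.", dir), class = "psivox_format_error")
  }
  covariates <- readr::read_csv(cov_path, col_types = readr::cols(
    subject_id = readr::col_character(), beta_slope = readr::col_double(),
    age = readr::col_double(), sex = readr::col_integer()))
  mask_img <- RNifti::readNifti(file.path(dir, "mask.nii"))
  mask <- array(as.vector(mask_img) > 0.5, dim = dim(mask_img))
  mask_idx <- which(mask)
  vsz <- RNifti::pixdim(mask_img)[1:3]
  data <- matrix(NA_real_, nrow = nrow(covariates), ncol = length(mask_idx))
  for (i in seq_len(nrow(covariates))) {
    f <- file.path(dir, paste0(covariates$subject_id[i], ".nii"))
    if (!file.exists(f)) {
      abort(sprintf("Missing volume for subject '%s'.", covariates$subject_id[i]),
            class = "psivox_format_error")
    }
    img <- RNifti::readNifti(f)
    if (!identical(dim(img), dim(mask))) {
      abort(sprintf("Grid mismatch for subject '%s'.", covariates$subject_id[i]),
            class = "psivox_format_error")
    }
    if (max(abs(RNifti::pixdim(img)[1:3] - vsz)) > 1e-5) {
      abort(sprintf("Voxel-size mismatch for subject '%s'.",
                    covariates$subject_id[i]),
            class = "psivox_format_error")
    }
    data[i, ] <- img[mask_idx]
  }
  region <- integer(0)
  reg_path <- file.path(dir, "region.nii")
  if (file.exists(reg_path)) {
    region <- which(as.vector(RNifti::readNifti(reg_path)) > 0.5)
  }
  structure(list(data = data, mask = mask, region = region,
                 affine = diag(c(vsz, 1)), voxel_size = vsz,
                 covariates = covariates, spec = NULL, seed = NULL),
            class = "skeleton_cohort")
}
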