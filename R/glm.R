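# Masked voxelwise general linear model. Each mask voxel's values across
# subjects are regressed on a design of [intercept | slope | nuisance]; the
# t statistic of the slope coefficient is the voxel statistic. For small
# cohorts the residual-variance image may be Gaussian-smoothed within the
# mask (renormalised at mask edges) before the standard error is formed -
# the "variance smoothing" used by permutation imaging tools to stabilise
# small-sample variance estimates.

#' Design matrix for the slope-diffusivity GLM
#'
#' Builds `[intercept | interest | nuisance...]` from a covariates table.
#' Default interest is the psychometric slope with age and sex as covariates
#' of no interest.
#'
#' @param covariates Data frame with one row per subject.
#' @param interest Column name of the regressor of interest.
#' @param nuisance Character vector of nuisance column names.
#' @return An object of class `voxel_design`: `X` (numeric matrix),
#'   `interest` (column index of the regressor of interest), `nuisance_cols`.
#' @export
design_matrix <- function(covariates, interest = "beta_slope",
                          nuisance = c("age", "sex")) {
  cols <- c(interest, nuisance)
  missing_cols <- setdiff(cols, names(covariates))
  if (length(missing_cols) > 0) {
    abort(sprintf("Covariates lack column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "psivox_config_error")
  }
  X <- cbind(intercept = 1,
             as.matrix(covariates[, cols, drop = FALSE]))
  storage.mode(X) <- "double"
  if (qr(X)$rank < ncol(X)) {
    abort("Design matrix is rank deficient.", class = "psivox_config_error")
  }
  structure(list(X = X, interest = 2L,
                 nuisance_cols = c(1L, seq_along(nuisance) + 2L)),
            class = "voxel_design")
}

# Gaussian smoothing matrix over mask voxels (rows renormalised within the
# mask, so edge voxels average only over in-mask neighbours). Built once per
# analysis; applied as a sparse matrix-vector product per permutation.
smoothing_matrix <- function(mask, voxel_size, sigma_mm) {
  idx <- which(mask)
  co <- sweep(arrayInd(idx, dim(mask)), 2, voxel_size, "*")
  nv <- nrow(co)
  cutoff2 <- (3 * sigma_mm)^2
  blocks <- split(seq_len(nv), ceiling(seq_len(nv) / 512))
  triplets <- purrr::map(blocks, function(rows) {
    d2 <- outer(co[rows, 1], co[, 1], "-")^2 +
      outer(co[rows, 2], co[, 2], "-")^2 +
      outer(co[rows, 3], co[, 3], "-")^2
    hit <- which(d2 <= cutoff2, arr.ind = TRUE)
    list(i = rows[hit[, 1]], j = hit[, 2],
         x = exp(-d2[hit] / (2 * sigma_mm^2)))
  })
  W <- Matrix::sparseMatrix(i = unlist(lapply(triplets, `[[`, "i")),
                            j = unlist(lapply(triplets, `[[`, "j")),
                            x = unlist(lapply(triplets, `[[`, "x")),
                            dims = c(nv, nv))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
}

# Core vectorised GLM over a subjects x voxels matrix. Returns the t map of
# the interest column. `smooth` is NULL or a precomputed smoothing matrix
# applied to the residual variance image. Zero residual variance (an exact
# fit) yields a capped, flagged t rather than an error.
glm_tmap <- function(Y, X, interest, smooth = NULL, t_cap = 1e6) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) {
    abort("Need more subjects than design columns (plus one).",
          class = "psivox_config_error")
  }
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  R <- Y - X %*% B
  sigma2 <- colSums(R^2) / (n - p)
  if (!is.null(smooth)) sigma2 <- as.vector(smooth %*% sigma2)
  se2 <- XtXi[interest, interest] * sigma2
  b <- B[interest, ]
  # numerically exact fits: residual variance at rounding-noise level gives a
  # capped t for a real coefficient, 0 for a rounding-noise coefficient
  scale2 <- colSums(Y^2) + .Machine$double.xmin
  degenerate <- sigma2 <= 1e-20 * scale2 / (n - p)
  t <- b / sqrt(pmax(se2, .Machine$double.xmin))
  t[degenerate] <- ifelse(abs(b[degenerate]) > 1e-8 * sqrt(scale2[degenerate] / n),
                          sign(b[degenerate]) * t_cap, 0)
  capped <- degenerate & t != 0
  t <- pmin(pmax(t, -t_cap), t_cap)
  attr(t, "df") <- n - p
  attr(t, "capped") <- which(capped)
  t
}

#' Voxelwise GLM t-map of the slope-diffusivity association
#'
#' Ordinary least squares of each mask voxel's values on the design; returns
#' the t statistic of the regressor of interest, with optional Gaussian
#' variance smoothing. A voxel fitting exactly (zero residual variance) gets
#' a capped t (`1e6`), flagged in the `capped` attribute.
#'
#' @param cohort A `skeleton_cohort`.
#' @param design A [design_matrix()].
#' @param var_smooth_sigma Variance-smoothing Gaussian sigma in mm
#'   (default 5); `0` or `NULL` disables smoothing.
#' @return An object of class `voxel_tmap`: `t` (vector over mask voxels),
#'   `map` (3D array, zero off-mask), `df`, `mask`.
#' @export
fit_glm <- function(cohort, design, var_smooth_sigma = 5) {
  stopifnot(inherits(cohort, "skeleton_cohort"), inherits(design, "voxel_design"))
  if (nrow(design$X) != nrow(cohort$data)) {
    abort("Design rows must match the number of subjects.",
          class = "psivox_config_error")
  }
  smooth <- NULL
  if (!is.null(var_smooth_sigma) && var_smooth_sigma > 0) {
    smooth <- smoothing_matrix(cohort$mask, cohort$voxel_size, var_smooth_sigma)
  }
  t <- glm_tmap(cohort$data, design$X, design$interest, smooth = smooth)
  map <- array(0, dim = dim(cohort$mask))
  map[which(cohort$mask)] <- t
  structure(list(t = as.vector(t), map = map, df = attr(t, "df"),
                 capped = attr(t, "capped"), mask = cohort$mask),
            class = "voxel_tmap")
}
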