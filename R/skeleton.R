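# Synthetic white-matter skeleton masks. The real analysis domain is a
# thinned "skeleton" of tract centres produced by tract-based spatial
# statistics; here we emulate its geometry - thin, connected, curvilinear 3D
# structures covering a few percent of the volume - by rasterising smooth
# random-walk curves. The first curve ("primary tract") is confined to one
# half of the x axis and made long enough to host a contiguous lateralised
# planted region.

#' Generate a synthetic skeleton mask
#'
#' Rasterises smooth 3D random-walk curves (unit steps with persistent,
#' slowly-wandering direction) into a binary mask, adding curves until the
#' target voxel fraction is reached. Each curve is 26-connected by
#' construction (step length below one voxel); optional width-2 dilation
#' thickens alternate curves. The first curve stays in the low-x half of the
#' volume and is traced long enough to contain at least `primary_min` voxels.
#'
#' @param shape Integer length-3 volume dimensions; each must be >= 32.
#' @param target_fraction Desired mask fraction of the volume, within
#'   `[0.01, 0.05]`.
#' @param primary_min Minimum voxel count of the primary (lateralised) curve.
#' @param seed Integer seed; the mask is deterministic per seed.
#' @return A logical 3D array of dimension `shape`, with the linear voxel
#'   indices of the primary curve in attribute `"primary"`.
#' @export
skeleton_mask <- function(shape, target_fraction = 0.02, primary_min = 200L,
                          seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L)) {
    abort("`shape` must be three dimensions, each at least 32.",
          class = "psivox_config_error")
  }
  if (target_fraction < 0.01 || target_fraction > 0.05) {
    abort("`target_fraction` must lie in [0.01, 0.05].",
          class = "psivox_config_error")
  }
  n_vox <- prod(shape)
  target <- target_fraction * n_vox

  with_seed(seed, {
    mask <- array(FALSE, dim = shape)

    trace_curve <- function(x_max, min_len, max_len) {
      pos <- c(runif(1, 4, x_max - 3), runif(1, 4, shape[2] - 3),
               runif(1, 4, shape[3] - 3))
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pts <- matrix(NA_real_, nrow = max_len, ncol = 3)
      k <- 0L
      for (s in seq_len(max_len)) {
        pos <- pos + 0.8 * dir
        if (any(pos < 2) || pos[1] > x_max - 1 ||
            pos[2] > shape[2] - 1 || pos[3] > shape[3] - 1) {
          if (k >= min_len) break
          # reflect back into the box and keep tracing
          pos <- pmin(pmax(pos, 2), c(x_max, shape[2], shape[3]) - 1)
          dir <- -dir + 0.5 * rnorm(3); dir <- dir / sqrt(sum(dir^2))
          next
        }
        k <- k + 1L
        pts[k, ] <- pos
        dir <- dir + 0.25 * rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
      }
      unique(round(pts[seq_len(k), , drop = FALSE]))
    }

    stamp <- function(vox, widen) {
      vox <- vox[vox[, 1] >= 1 & vox[, 2] >= 1 & vox[, 3] >= 1 &
                 vox[, 1] <= shape[1] & vox[, 2] <= shape[2] & vox[, 3] <= shape[3],
                 , drop = FALSE]
      idx <- vox[, 1] + (vox[, 2] - 1) * shape[1] +
        (vox[, 3] - 1) * shape[1] * shape[2]
      if (widen) { # width-2: duplicate one voxel along a fixed offset
        vox2 <- vox; vox2[, 2] <- pmin(vox2[, 2] + 1L, shape[2])
        idx <- c(idx, vox2[, 1] + (vox2[, 2] - 1) * shape[1] +
                   (vox2[, 3] - 1) * shape[1] * shape[2])
      }
      unique(idx)
    }

    # primary lateralised curve: low-x half, long
    primary_idx <- integer(0)
    tries <- 0L
    while (length(primary_idx) < primary_min && tries < 50L) {
      vox <- trace_curve(x_max = floor(shape[1] / 2), min_len = primary_min * 2L,
                         max_len = primary_min * 6L)
      primary_idx <- stamp(vox, widen = TRUE)
      tries <- tries + 1L
    }
    mask[primary_idx] <- TRUE

    widen <- TRUE
    while (sum(mask) < target) {
      vox <- trace_curve(x_max = shape[1], min_len = 40L, max_len = 160L)
      mask[stamp(vox, widen = widen)] <- TRUE
      widen <- !widen
    }
    attr(mask, "primary") <- primary_idx
    mask
  })
}
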