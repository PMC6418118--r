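# Threshold-free cluster enhancement. For each mask voxel v,
#   TFCE(v) = sum_h e(v,h)^E * h^H * dh
# over midpoint height steps h from 0 to the map maximum, where e(v,h) is
# the size (voxel count) of the connected component containing v after
# thresholding the map at h. This integrates cluster extent and height over
# all thresholds, avoiding an arbitrary cluster-forming threshold. The
# integration is done in compiled code with an incremental union-find over
# thresholds processed from high to low.

CONNECTIVITY_OFFSETS <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(off)) == 1,
                 "18" = rowSums(abs(off)) <= 2,
                 "26" = rep(TRUE, nrow(off)),
                 abort("`connectivity` must be 6, 18 or 26.",
                       class = "psivox_config_error"))
  off[keep, , drop = FALSE]
}

#' Adjacency structure of the mask voxels
#'
#' Compressed sparse neighbour lists of the masked voxel graph under
#' face (6), edge (18) or corner (26) connectivity. Shared by TFCE, cluster
#' labelling and the planted-region grower.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return A list: `index` (linear voxel indices of mask voxels), `neighbors`
#'   (concatenated 1-based neighbour ids into `index`), `ptr` (0-based CSR
#'   offsets, length `nv + 1`).
#' @export
mask_adjacency <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  shape <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) {
    abort("Mask is empty.", class = "psivox_config_error")
  }
  nv <- length(idx)
  lookup <- array(0L, dim = shape)
  lookup[idx] <- seq_len(nv)
  co <- arrayInd(idx, shape)
  off <- CONNECTIVITY_OFFSETS(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    ni <- co[, 1] + off[r, 1]; nj <- co[, 2] + off[r, 2]; nk <- co[, 3] + off[r, 3]
    ok <- ni >= 1 & ni <= shape[1] & nj >= 1 & nj <= shape[2] &
      nk >= 1 & nk <= shape[3]
    tgt <- integer(nv)
    tgt[ok] <- lookup[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- tgt > 0L
    from <- c(from, which(hit))
    to <- c(to, tgt[hit])
  }
  ord <- order(from)
  from <- from[ord]; to <- to[ord]
  counts <- tabulate(from, nbins = nv)
  list(index = idx, neighbors = to, ptr = c(0L, cumsum(counts)))
}

#' TFCE configuration
#'
#' @param E Extent exponent (default 0.5).
#' @param H Height exponent (default 2).
#' @param n_steps Number of integration height steps (default 100, minimum
#'   10).
#' @param connectivity Component connectivity: 6, 18 or 26 (default 26).
#' @return An object of class `tfce_config`.
#' @export
tfce_config <- function(E = 0.5, H = 2, n_steps = 100L, connectivity = 26L) {
  if (E < 0 || H < 0) abort("TFCE exponents must be non-negative.",
                            class = "psivox_config_error")
  if (n_steps < 10L) abort("`n_steps` must be at least 10.",
                           class = "psivox_config_error")
  connectivity <- as.integer(connectivity)
  CONNECTIVITY_OFFSETS(connectivity) # validates
  structure(list(E = E, H = H, n_steps = as.integer(n_steps),
                 connectivity = connectivity),
            class = "tfce_config")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Only positive map values are enhanced; to test a negative-direction
#' statistic, pass the sign-flipped map. Values must be finite within the
#' mask.
#'
#' @param statmap Numeric vector of statistic values over the mask voxels
#'   (in `mask_adjacency()$index` order) or a 3D array.
#' @param mask Logical 3D array.
#' @param config A [tfce_config()].
#' @param adjacency Optional precomputed [mask_adjacency()] (fast path for
#'   permutation loops).
#' @return Numeric vector of TFCE scores over mask voxels (same order as
#'   `mask_adjacency()$index`), or a 3D array if `statmap` was one.
#' @export
tfce <- function(statmap, mask, config = tfce_config(), adjacency = NULL) {
  stopifnot(inherits(config, "tfce_config"))
  if (is.null(adjacency)) adjacency <- mask_adjacency(mask, config$connectivity)
  was_array <- is.array(statmap) && length(dim(statmap)) == 3L
  vals <- if (was_array) statmap[adjacency$index] else statmap
  if (length(vals) != length(adjacency$index)) {
    abort("`statmap` length does not match the mask.", class = "psivox_config_error")
  }
  if (any(!is.finite(vals))) {
    abort("Statistic map must be finite within the mask.",
          class = "psivox_domain_error")
  }
  scores <- tfce_kernel(vals, adjacency$neighbors - 1L, adjacency$ptr,
                        config$E, config$H, config$n_steps)
  if (was_array) {
    out <- array(0, dim = dim(mask)); out[adjacency$index] <- scores; out
  } else {
    scores
  }
}
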