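# Cluster-extent reporting: connected components of the significant-voxel
# set, retained when strictly larger than the extent threshold ("over 100
# contiguous voxels" is a strict inequality).

#' Extract significant clusters from a permutation result
#'
#' Labels connected components of `{p_corr < alpha}` within the mask and
#' keeps those with size strictly greater than `min_extent`. Peak voxel =
#' smallest corrected p, ties broken by larger TFCE score.
#'
#' @param result A `voxel_ptest` from [permutation_test()].
#' @param alpha Corrected significance level (default 0.05).
#' @param min_extent Extent threshold in voxels (default 100; clusters must
#'   exceed it strictly).
#' @param connectivity Component connectivity (default 26).
#' @return A tibble sorted by decreasing size with columns `cluster_id`,
#'   `n_voxels`, `peak_i`, `peak_j`, `peak_k` (0-based voxel indices),
#'   `peak_p_corr`, `mean_p_corr`, `direction`.
#' @export
extract_clusters <- function(result, alpha = 0.05, min_extent = 100L,
                             connectivity = 26L) {
  stopifnot(inherits(result, "voxel_ptest"))
  adjacency <- if (connectivity == result$adjacency_connectivity %||% -1L) {
    result$adjacency
  } else {
    mask_adjacency(result$mask, connectivity)
  }
  sig <- result$p_corr < alpha
  empty <- tibble(cluster_id = integer(0), n_voxels = integer(0),
                  peak_i = integer(0), peak_j = integer(0), peak_k = integer(0),
                  peak_p_corr = numeric(0), mean_p_corr = numeric(0),
                  direction = character(0))
  if (!any(sig)) return(empty)
  labels <- label_components(sig, adjacency$neighbors - 1L, adjacency$ptr)
  sizes <- tabulate(labels)
  keep <- which(sizes > min_extent)
  if (length(keep) == 0L) return(empty)
  co <- arrayInd(adjacency$index, dim(result$mask)) - 1L # 0-based
  rows <- purrr::map(keep, function(lab) {
    vox <- which(labels == lab)
    peak <- vox[order(result$p_corr[vox], -result$tfce[vox])][1]
    tibble(n_voxels = length(vox),
           peak_i = co[peak, 1], peak_j = co[peak, 2], peak_k = co[peak, 3],
           peak_p_corr = result$p_corr[peak],
           mean_p_corr = mean(result$p_corr[vox]),
           direction = result$direction)
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$n_voxels)) |>
    dplyr::mutate(cluster_id = dplyr::row_number(), .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
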