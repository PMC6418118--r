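# broom-style tidiers for the package's fitted objects.

#' Tidy a psychometric posterior into a node table
#'
#' @param x A `psy_posterior`.
#' @param ... Unused.
#' @return A tibble with one row per grid node: `alpha`, `beta`, `lam`,
#'   `mass`.
#' @method tidy psy_posterior
#' @export
tidy.psy_posterior <- function(x, ...) {
  dplyr::mutate(x$grid$nodes, mass = x$mass)
}

#' One-row summary of a psychometric posterior
#'
#' @param x A `psy_posterior`.
#' @param ... Unused.
#' @return A tibble: posterior-mean parameters, 95% slope credible bounds,
#'   entropy, node count.
#' @method glance psy_posterior
#' @export
glance.psy_posterior <- function(x, ...) {
  est <- point_estimate(x)
  ci <- credible_interval(x, "beta")
  tibble(alpha = est$alpha, beta = est$beta, gamma = est$gamma, lam = est$lam,
         beta_ci_lower = ci$lower, beta_ci_upper = ci$upper,
         entropy = posterior_entropy(x), n_nodes = length(x$mass))
}

#' Tidy a session into its trial log
#'
#' @param x A `psy_session`.
#' @param ... Unused.
#' @return The trials tibble (`index`, `phase`, `kind`, `first_side`,
#'   `delta_ms`, `response_side`, `chose_first`).
#' @method tidy psy_session
#' @export
tidy.psy_session <- function(x, ...) x$trials

#' One-row summary of a simulated session
#'
#' @param x A `psy_session`.
#' @param ... Unused.
#' @return A tibble: trial counts, first adaptive asynchrony, final
#'   estimates and entropy.
#' @method glance psy_session
#' @export
glance.psy_session <- function(x, ...) {
  est <- x$estimate
  dbl <- x$trials[x$trials$phase == "main" & x$trials$kind == "double", ]
  tibble(n_trials = nrow(x$trials),
         n_main = sum(x$trials$phase == "main"),
         n_training = sum(x$trials$phase == "training"),
         n_estimation = x$n_estimation_trials,
         first_double_delta = dbl$delta_ms[1],
         alpha = est$alpha, beta = est$beta, lam = est$lam,
         entropy_final = posterior_entropy(x$posterior))
}

#' Tidy a permutation result into a per-voxel table
#'
#' @param x A `voxel_ptest`.
#' @param ... Unused.
#' @return A tibble with one row per mask voxel: 0-based `i`, `j`, `k`,
#'   `t`, `tfce`, `p_corr`, `direction`.
#' @method tidy voxel_ptest
#' @export
tidy.voxel_ptest <- function(x, ...) {
  co <- arrayInd(x$adjacency$index, dim(x$mask)) - 1L
  tibble(i = co[, 1], j = co[, 2], k = co[, 3],
         t = x$t, tfce = x$tfce, p_corr = x$p_corr, direction = x$direction)
}

#' One-row summary of a permutation result
#'
#' @param x A `voxel_ptest`.
#' @param ... Unused.
#' @return A tibble: direction, permutation count, minimum corrected p,
#'   significant-voxel count at 0.05, max TFCE, residual df.
#' @method glance voxel_ptest
#' @export
glance.voxel_ptest <- function(x, ...) {
  tibble(direction = x$direction, n_perm = x$n_perm,
         n_voxels = length(x$t), min_p_corr = min(x$p_corr),
         n_sig_05 = sum(x$p_corr < 0.05), max_tfce = max(x$tfce), df = x$df)
}

#' Tidy both directions of a paired analysis
#'
#' @param x A `voxel_ptest_pair`.
#' @param ... Passed to [extract_clusters()] (`alpha`, `min_extent`,
#'   `connectivity`).
#' @return The combined cluster table of both directions.
#' @method tidy voxel_ptest_pair
#' @export
tidy.voxel_ptest_pair <- function(x, ...) {
  dplyr::bind_rows(extract_clusters(x$negative, ...),
                   extract_clusters(x$positive, ...))
}
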