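# Permutation-based non-parametric inference with family-wise error
# correction by the maximum-TFCE distribution, under the Freedman-Lane
# scheme for nuisance covariates: the data are residualised against the
# nuisance-only model, the residual rows are permuted, the nuisance fit is
# re-added, and the full-model statistic is recomputed. The corrected
# p-value of a voxel is (1 + #{permutations whose max TFCE >= observed
# TFCE(v)}) / (n_perm + 1), the observed labelling always counting once.

# All n! permutations of 1..n (small n only; exhaustive fallback).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

draw_permutations <- function(n, n_perm, seed) {
  n_distinct <- factorial(n)
  if (n <= 7 && n_perm >= n_distinct - 1) {
    warn(sprintf(paste0("Requested %d permutations but only %d distinct ",
                        "orderings exist; enumerating exhaustively."),
                 n_perm, n_distinct))
    perms <- all_permutations(n)
    # drop the identity: the observed labelling is counted separately
    return(perms[rowSums(perms == matrix(seq_len(n), nrow(perms), n,
                                         byrow = TRUE)) != n, , drop = FALSE])
  }
  with_seed(seed, t(vapply(seq_len(n_perm), function(i) sample.int(n),
                           integer(n))))
}

#' Permutation test of the slope-diffusivity association
#'
#' One-sided test in the requested direction. The voxel statistic is the
#' GLM t of the slope (sign-flipped for `direction = "negative"`), enhanced
#' by TFCE; family-wise error is controlled by the permutation distribution
#' of the mask-wide maximum TFCE under Freedman-Lane exchange of
#' nuisance-residualised data. The permutation stream depends only on
#' `seed`, so both directions of [run_both_directions()] share identical
#' permutations.
#'
#' @param cohort A `skeleton_cohort`.
#' @param design A [design_matrix()].
#' @param direction `"negative"` or `"positive"` association of the regressor
#'   of interest with the voxel values.
#' @param n_perm Number of permutations (default 5000). If it reaches the
#'   number of distinct orderings (tiny cohorts), all are enumerated with a
#'   warning.
#' @param tfce A [tfce_config()].
#' @param var_smooth_sigma Variance-smoothing sigma in mm (default 5).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `voxel_ptest`: `t` (signed t over mask
#'   voxels), `tfce` (enhanced directed statistic), `p_corr` (FWE-corrected
#'   p), `max_null` (permutation maxima), plus `direction`, `n_perm`, `mask`,
#'   `adjacency`, `df`.
#' @export
permutation_test <- function(cohort, design, direction = c("negative", "positive"),
                             n_perm = 5000L, tfce = tfce_config(),
                             var_smooth_sigma = 5, seed = 1L) {
  direction <- rlang::arg_match(direction)
  stopifnot(inherits(cohort, "skeleton_cohort"), inherits(design, "voxel_design"))
  if (n_perm < 1L) abort("`n_perm` must be at least 1.",
                         class = "psivox_config_error")
  X <- design$X
  n <- nrow(X)
  sgn <- if (direction == "negative") -1 else 1

  adjacency <- mask_adjacency(cohort$mask, tfce$connectivity)
  smooth <- if (!is.null(var_smooth_sigma) && var_smooth_sigma > 0) {
    smoothing_matrix(cohort$mask, cohort$voxel_size, var_smooth_sigma)
  }

  t_obs <- glm_tmap(cohort$data, X, design$interest, smooth = smooth)
  tfce_obs <- tfce(sgn * as.vector(t_obs), cohort$mask, tfce,
                   adjacency = adjacency)

  # Freedman-Lane: residualise against the nuisance-only model
  Z <- X[, design$nuisance_cols, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z), crossprod(Z, cohort$data))
  Ez <- cohort$data - Hz

  perms <- draw_permutations(n, n_perm, derive_seed(seed, "perms"))
  max_null <- apply(perms, 1L, function(pr) {
    Yp <- Hz + Ez[pr, , drop = FALSE]
    tp <- glm_tmap(Yp, X, design$interest, smooth = smooth)
    max(tfce(sgn * as.vector(tp), cohort$mask, tfce, adjacency = adjacency))
  })

  m <- length(max_null)
  # corrected p: observed labelling included in the reference set
  exceed <- vapply(tfce_obs, function(v) sum(max_null >= v), numeric(1))
  p_corr <- (1 + exceed) / (m + 1)

  structure(list(t = sgn * as.vector(t_obs), tfce = tfce_obs, p_corr = p_corr,
                 max_null = max_null, direction = direction, n_perm = m,
                 mask = cohort$mask, adjacency = adjacency,
                 adjacency_connectivity = tfce$connectivity,
                 df = attr(t_obs, "df"), seed = seed),
            class = "voxel_ptest")
}

#' @export
print.voxel_ptest <- function(x, ...) {
  cat(sprintf("<voxel_ptest> %s direction, %d permutations, %d mask voxels\n",
              x$direction, x$n_perm, length(x$t)))
  cat(sprintf("  min corrected p = %.4g; voxels with p < 0.05: %d\n",
              min(x$p_corr), sum(x$p_corr < 0.05)))
  invisible(x)
}

#' Run the permutation analysis in both correlation directions
#'
#' Negative and positive one-sided analyses with identical permutation
#' streams, matching the practice of reporting each direction separately.
#'
#' @inheritParams permutation_test
#' @return An object of class `voxel_ptest_pair`: list with elements
#'   `negative` and `positive`, each a `voxel_ptest`.
#' @export
run_both_directions <- function(cohort, design, n_perm = 5000L,
                                tfce = tfce_config(), var_smooth_sigma = 5,
                                seed = 1L) {
  structure(list(
    negative = permutation_test(cohort, design, "negative", n_perm = n_perm,
                                tfce = tfce, var_smooth_sigma = var_smooth_sigma,
                                seed = seed),
    positive = permutation_test(cohort, design, "positive", n_perm = n_perm,
                                tfce = tfce, var_smooth_sigma = var_smooth_sigma,
                                seed = seed)),
    class = "voxel_ptest_pair")
}

#' @export
print.voxel_ptest_pair <- function(x, ...) {
  cat("<voxel_ptest_pair>\n")
  for (d in c("negative", "positive")) {
    cat(sprintf("  %s: min p = %.4g, voxels p < 0.05: %d\n", d,
                min(x[[d]]$p_corr), sum(x[[d]]$p_corr < 0.05)))
  }
  invisible(x)
}
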