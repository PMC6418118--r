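# Validation harnesses for the behavioural stage: parameter recovery over
# simulated pure observers, the adaptive-vs-random efficiency comparison,
# and the interference sweep that operationalises "weaker meta-volition
# flattens the slope".

#' Draw ground-truth parameters for recovery studies
#'
#' Uniform over the central 90% of each admissible range (alpha 30-270 ms,
#' beta -1.8 to 1.8, lapse 0.005-0.095), i.e. strictly inside the grid.
#'
#' @param n Number of observers.
#' @param seed Integer seed.
#' @return A tibble with columns `alpha`, `beta`, `lam`.
#' @export
draw_true_params <- function(n, seed) {
  with_seed(seed, tibble(alpha = runif(n, 30, 270),
                         beta = runif(n, -1.8, 1.8),
                         lam = runif(n, 0.005, 0.095)))
}

#' Parameter-recovery study over simulated pure observers
#'
#' Runs a full adaptive session per observer (no interference) and compares
#' posterior-mean estimates with ground truth. `glance()` summarises the
#' per-parameter truth-estimate correlation, RMSE, and the credible-interval
#' coverage of the slope.
#'
#' @param n_observers Number of simulated observers (default 200).
#' @param config A [session_config()].
#' @param seed Integer master seed.
#' @param truth Optional tibble of true `alpha`, `beta`, `lam` (one row per
#'   observer); defaults to [draw_true_params()].
#' @param ci_level Credible-interval level for the coverage column.
#' @return A tibble of class `psy_recovery`, one row per observer: true and
#'   estimated parameters, final posterior entropy, slope credible bounds
#'   and coverage indicator.
#' @export
recovery_study <- function(n_observers = 200L, config = session_config(),
                           seed = 1L, truth = NULL, ci_level = 0.95) {
  if (n_observers < 2L) {
    abort("`n_observers` must be at least 2.", class = "psivox_config_error")
  }
  if (is.null(truth)) {
    truth <- draw_true_params(n_observers, derive_seed(seed, "truth"))
  }
  stopifnot(nrow(truth) == n_observers)
  rows <- purrr::map(seq_len(n_observers), function(i) {
    obs <- make_observer(observer_spec(alpha = truth$alpha[i],
                                       beta = truth$beta[i],
                                       lam = truth$lam[i]))
    ses <- run_session(obs, config, seed = derive_seed(seed, "session", i))
    ci <- credible_interval(ses$posterior, "beta", level = ci_level)
    tibble(observer = i,
           alpha_true = truth$alpha[i], beta_true = truth$beta[i],
           lam_true = truth$lam[i],
           alpha_est = ses$estimate$alpha, beta_est = ses$estimate$beta,
           lam_est = ses$estimate$lam,
           entropy_final = posterior_entropy(ses$posterior),
           beta_ci_lower = ci$lower, beta_ci_upper = ci$upper,
           beta_covered = truth$beta[i] >= ci$lower & truth$beta[i] <= ci$upper)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("psy_recovery", class(out))
  out
}

#' @method glance psy_recovery
#' @export
glance.psy_recovery <- function(x, ...) {
  tibble(n_observers = nrow(x),
         r_alpha = cor(x$alpha_true, x$alpha_est),
         r_beta = cor(x$beta_true, x$beta_est),
         r_lam = cor(x$lam_true, x$lam_est),
         rmse_alpha = sqrt(mean((x$alpha_true - x$alpha_est)^2)),
         rmse_beta = sqrt(mean((x$beta_true - x$beta_est)^2)),
         rmse_lam = sqrt(mean((x$lam_true - x$lam_est)^2)),
         beta_coverage = mean(x$beta_covered),
         mean_entropy = mean(x$entropy_final))
}

#' Adaptive versus uniform-random asynchrony selection
#'
#' Paired comparison over matched simulated observers: each observer is run
#' once under expected-entropy selection and once under uniform-random
#' selection (same observer spec and master seed; outcomes are regenerated
#' under each schedule since the sampled asynchronies differ). Lower final
#' posterior entropy means a more informative session.
#'
#' @param n_observers Number of matched observers (default 100).
#' @param config A [session_config()] (its `selection` field is overridden).
#' @param seed Integer master seed.
#' @param truth Optional tibble of true parameters, as in [recovery_study()].
#' @return A tibble, one row per observer, with `entropy_adaptive` and
#'   `entropy_random`.
#' @export
selection_comparison <- function(n_observers = 100L, config = session_config(),
                                 seed = 1L, truth = NULL) {
  if (is.null(truth)) {
    truth <- draw_true_params(n_observers, derive_seed(seed, "truth"))
  }
  cfg_a <- config; cfg_a$selection <- "adaptive"
  cfg_r <- config; cfg_r$selection <- "random"
  rows <- purrr::map(seq_len(n_observers), function(i) {
    spec <- observer_spec(alpha = truth$alpha[i], beta = truth$beta[i],
                          lam = truth$lam[i])
    s <- derive_seed(seed, "session", i)
    tibble(observer = i,
           entropy_adaptive = posterior_entropy(
             run_session(make_observer(spec), cfg_a, seed = s)$posterior),
           entropy_random = posterior_entropy(
             run_session(make_observer(spec), cfg_r, seed = s)$posterior))
  })
  dplyr::bind_rows(rows)
}

#' Interference sweep: estimated slope versus interference weight
#'
#' Runs seeded sessions for the same underlying observer at several
#' interference mixture weights and records the estimated slope. The
#' estimated slope should fall (flatter function) as interference grows -
#' the mechanism by which weaker meta-volition is read off the function.
#'
#' @param pi_vol Interference weights to sweep (default `c(0, 0.25, 0.5)`).
#' @param n_seeds Seeded sessions per weight (default 50).
#' @param alpha,beta,lam True parameters of the underlying observer
#'   (defaults: 150 ms threshold, slope -1, 2% lapse).
#' @param bias Interference side-bias (default 0.5).
#' @param config A [session_config()].
#' @param seed Integer master seed.
#' @return A tibble with one row per (weight, seed): `pi_vol`, `rep`,
#'   `beta_est`, `alpha_est`.
#' @export
interference_sweep <- function(pi_vol = c(0, 0.25, 0.5), n_seeds = 50L,
                               alpha = 150, beta = -1, lam = 0.02, bias = 0.5,
                               config = session_config(), seed = 1L) {
  grid <- tidyr::expand_grid(pi_vol = pi_vol, rep = seq_len(n_seeds))
  rows <- purrr::pmap(grid, function(pi_vol, rep) {
    spec <- observer_spec(alpha = alpha, beta = beta, lam = lam,
                          pi_vol = pi_vol, bias = bias)
    ses <- run_session(make_observer(spec), config,
                       seed = derive_seed(seed, "sweep", rep))
    tibble(pi_vol = pi_vol, rep = rep,
           beta_est = ses$estimate$beta, alpha_est = ses$estimate$alpha)
  })
  dplyr::bind_rows(rows)
}
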