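# Psychometric model for the asynchronous saccadic-choice task.
#
# The probability of foveating the first-onset target as a function of the
# onset asynchrony delta (ms) is a four-parameter logistic,
#
#   P(delta) = gamma + (1 - gamma - lam) * sigma(10^beta * (delta - alpha))
#
# with guess rate gamma (fixed at 0.5: two-alternative spatial choice),
# threshold alpha in ms, slope beta as log10 of the logistic rate in 1/ms,
# and lapse rate lam shrinking the upper asymptote to 1 - lam. Steeper beta
# means choice is driven almost entirely by the asynchrony; flatter beta
# means delta-independent (volitional) influences intrude.

PSY_GAMMA <- 0.5

#' Psychometric function parameters
#'
#' A lightweight record of the four parameters of the asynchronous-choice
#' psychometric function. The guess rate is fixed at 0.5 for this paradigm.
#'
#' @param alpha Threshold in ms, the asynchrony at which the function reaches
#'   the midpoint between guess level and upper asymptote. Must lie in
#'   `[0, 300]`.
#' @param beta Slope, expressed as log10 of the logistic rate in 1/ms; must
#'   lie in `[-2, 2]` (rates 0.01 to 100 per ms).
#' @param lam Lapse rate in `[0, 0.1]`; the upper asymptote is `1 - lam`.
#' @param gamma Guess rate; fixed at 0.5.
#' @return An object of class `psy_params`.
#' @examples
#' psy_params(alpha = 150, beta = -1, lam = 0.02)
#' @export
psy_params <- function(alpha, beta, lam = 0, gamma = PSY_GAMMA) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L, length(lam) == 1L)
  if (gamma != PSY_GAMMA) {
    abort("`gamma` is fixed at 0.5 in this paradigm.", class = "psivox_domain_error")
  }
  if (lam < 0 || lam > 0.1) {
    abort("`lam` must lie in [0, 0.1].", class = "psivox_domain_error")
  }
  if (alpha < 0 || alpha > 300) {
    abort("`alpha` must lie in [0, 300] ms.", class = "psivox_domain_error")
  }
  if (beta < -2 || beta > 2) {
    abort("`beta` must lie in [-2, 2].", class = "psivox_domain_error")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lam = lam),
            class = "psy_params")
}

#' @export
print.psy_params <- function(x, ...) {
  cat(sprintf(
    "<psy_params> alpha = %.4g ms, beta = %.4g (rate %.4g /ms), gamma = %.2g, lam = %.4g\n",
    x$alpha, x$beta, 10^x$beta, x$gamma, x$lam))
  invisible(x)
}

#' Probability of choosing the first-onset target
#'
#' Evaluates the asynchronous-choice psychometric function
#' `gamma + (1 - gamma - lam) * plogis(10^beta * (delta - alpha))`.
#' Vectorised over `delta` and over the parameter arguments (recycled).
#'
#' @param delta Onset asynchrony in ms; must be non-negative.
#' @param params Optional `psy_params` object; if supplied its fields override
#'   the scalar arguments.
#' @inheritParams psy_params
#' @return Probabilities in `(gamma * 0, 1 - lam)`, monotone non-decreasing in
#'   `delta`.
#' @examples
#' psy_prob(150, alpha = 150, beta = 0) # 0.75: midpoint above a 0.5 guess rate
#' @export
psy_prob <- function(delta, params = NULL, alpha = NULL, beta = NULL,
                     lam = 0, gamma = PSY_GAMMA) {
  if (!is.null(params)) {
    alpha <- params$alpha; beta <- params$beta
    lam <- params$lam; gamma <- params$gamma
  }
  if (is.null(alpha) || is.null(beta)) {
    abort("Supply either `params` or `alpha` and `beta`.", class = "psivox_domain_error")
  }
  if (any(delta < 0)) {
    abort("`delta` must be non-negative.", class = "psivox_domain_error")
  }
  if (any(lam < 0 | lam > 0.1)) {
    abort("`lam` must lie in [0, 0.1].", class = "psivox_domain_error")
  }
  gamma + (1 - gamma - lam) * plogis(10^beta * (delta - alpha))
}

#' Parameter grid for grid-Bayesian estimation
#'
#' Discretises the admissible parameter space (threshold 0-300 ms, slope
#' -2 to 2, lapse 0-0.1) into a regular grid whose nodes carry posterior
#' mass during adaptive estimation. Axes include both endpoints.
#'
#' @param alpha_range,beta_range,lam_range Length-2 numeric ranges; defaults
#'   are the admissible ranges of the paradigm.
#' @param n_alpha,n_beta,n_lam Nodes per axis. Must be at least 2 on any axis
#'   whose range has distinct endpoints; a collapsed range (equal endpoints)
#'   may have a single node.
#' @return An object of class `psy_grid` with fields `alpha`, `beta`, `lam`
#'   (the axes) and `nodes` (a tibble with one row per grid node).
#' @examples
#' g <- psy_grid(n_alpha = 5, n_beta = 5, n_lam = 3)
#' nrow(g$nodes) # 75
#' @export
psy_grid <- function(alpha_range = c(0, 300), beta_range = c(-2, 2),
                     lam_range = c(0, 0.1),
                     n_alpha = 31L, n_beta = 41L, n_lam = 11L) {
  axis_of <- function(range, n, name) {
    stopifnot(length(range) == 2L, range[1] <= range[2])
    if (range[1] == range[2]) {
      if (n != 1L) abort(sprintf("Collapsed `%s` range requires a single node.", name),
                         class = "psivox_config_error")
      return(range[1])
    }
    if (n < 2L) {
      abort(sprintf("`%s` axis needs at least 2 nodes over a non-degenerate range.", name),
            class = "psivox_config_error")
    }
    seq(range[1], range[2], length.out = n)
  }
  alpha <- axis_of(alpha_range, n_alpha, "alpha")
  beta <- axis_of(beta_range, n_beta, "beta")
  lam <- axis_of(lam_range, n_lam, "lam")
  if (any(lam < 0 | lam > 0.1)) {
    abort("lapse axis must stay within [0, 0.1].", class = "psivox_config_error")
  }
  nodes <- tidyr::expand_grid(lam = lam, beta = beta, alpha = alpha)[, c("alpha", "beta", "lam")]
  structure(list(alpha = alpha, beta = beta, lam = lam, nodes = nodes),
            class = "psy_grid")
}

#' @export
print.psy_grid <- function(x, ...) {
  cat(sprintf("<psy_grid> %d x %d x %d = %d nodes (alpha x beta x lam)\n",
              length(x$alpha), length(x$beta), length(x$lam), nrow(x$nodes)))
  invisible(x)
}

#' Per-node likelihood of one trial outcome
#'
#' For every grid node, the probability of the observed binary outcome of a
#' double-target trial at asynchrony `delta`: `psy_prob(node, delta)` when the
#' first-onset target was chosen, its complement otherwise.
#'
#' @param grid A [psy_grid()].
#' @param delta Asynchrony in ms (scalar).
#' @param chose_first Logical scalar outcome.
#' @return Numeric vector with one likelihood in `(0, 1)` per grid node.
#' @export
likelihood_slice <- function(grid, delta, chose_first) {
  stopifnot(inherits(grid, "psy_grid"), is.logical(chose_first), length(chose_first) == 1L)
  p <- psy_prob(delta, alpha = grid$nodes$alpha, beta = grid$nodes$beta,
                lam = grid$nodes$lam)
  if (chose_first) p else 1 - p
}

#' Flat posterior over a parameter grid
#'
#' The adaptive run starts from flat priors: equal mass `1/N` on each of the
#' `N` grid nodes.
#'
#' @param grid A [psy_grid()].
#' @return An object of class `psy_posterior` (fields `grid`, `mass`).
#' @export
flat_posterior <- function(grid) {
  stopifnot(inherits(grid, "psy_grid"))
  n <- nrow(grid$nodes)
  new_posterior(grid, rep(1 / n, n))
}

new_posterior <- function(grid, mass) {
  stopifnot(length(mass) == nrow(grid$nodes), all(mass >= 0))
  s <- sum(mass)
  if (!is.finite(s) || s <= 0) {
    abort("Posterior mass must be positive and finite.", class = "psivox_internal_error")
  }
  structure(list(grid = grid, mass = mass / s), class = "psy_posterior")
}

#' @export
print.psy_posterior <- function(x, ...) {
  est <- point_estimate(x)
  cat(sprintf("<psy_posterior> %d nodes, entropy %.3f nats\n",
              length(x$mass), posterior_entropy(x)))
  cat(sprintf("  posterior means: alpha %.1f ms, beta %.3f, lam %.3f\n",
              est$alpha, est$beta, est$lam))
  invisible(x)
}

#' Shannon entropy of a posterior grid
#'
#' @param post A `psy_posterior`.
#' @return Entropy in nats, in `[0, log N]`.
#' @export
posterior_entropy <- function(post) {
  stopifnot(inherits(post, "psy_posterior"))
  -sum(xlogx(post$mass))
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Marginal posterior density along one parameter axis
#'
#' Sums the joint posterior over the other axes.
#'
#' @param post A `psy_posterior`.
#' @param axis One of `"alpha"`, `"beta"`, `"lam"`.
#' @return A tibble with columns `value` and `mass` (summing to 1), carrying
#'   the axis name in attribute `"axis"`.
#' @export
marginal_posterior <- function(post, axis = c("alpha", "beta", "lam")) {
  stopifnot(inherits(post, "psy_posterior"))
  axis <- rlang::arg_match(axis)
  vals <- post$grid[[axis]]
  key <- match(post$grid$nodes[[axis]], vals)
  mass <- as.vector(tapply(post$mass, factor(key, levels = seq_along(vals)), sum,
                           default = 0))
  out <- tibble(value = vals, mass = mass)
  attr(out, "axis") <- axis
  out
}

#' Joint (alpha, beta) marginal as a plot-ready raster
#'
#' Sums the lapse axis out, giving the threshold-by-slope posterior density
#' heatmap shown alongside each estimated function.
#'
#' @param post A `psy_posterior`.
#' @return A tibble with columns `alpha`, `beta`, `mass`.
#' @export
marginal_alpha_beta <- function(post) {
  stopifnot(inherits(post, "psy_posterior"))
  post$grid$nodes |>
    dplyr::mutate(mass = post$mass) |>
    dplyr::summarise(mass = sum(.data$mass), .by = c("alpha", "beta"))
}

#' Posterior point estimate of the psychometric parameters
#'
#' Returns the marginal posterior mean along each free axis (Bayes estimate
#' under squared loss; the mode would be quantised to the grid). The guess
#' rate is returned at its fixed value of 0.5.
#'
#' @param post A `psy_posterior`.
#' @return A [psy_params()] object.
#' @export
point_estimate <- function(post) {
  stopifnot(inherits(post, "psy_posterior"))
  m <- post$mass
  structure(list(alpha = sum(m * post$grid$nodes$alpha),
                 beta = sum(m * post$grid$nodes$beta),
                 gamma = PSY_GAMMA,
                 lam = sum(m * post$grid$nodes$lam)),
            class = "psy_params")
}

#' Equal-tailed credible interval from a marginal posterior
#'
#' Grid-discrete quantiles of the marginal mass: the reported bounds are the
#' smallest axis values at which the cumulative mass reaches the lower and
#' upper tail probabilities.
#'
#' @inheritParams marginal_posterior
#' @param level Interval mass, default 0.95.
#' @return A tibble with columns `axis`, `level`, `lower`, `upper`.
#' @export
credible_interval <- function(post, axis = c("alpha", "beta", "lam"), level = 0.95) {
  axis <- rlang::arg_match(axis)
  marg <- marginal_posterior(post, axis)
  cm <- cumsum(marg$mass)
  tail_p <- (1 - level) / 2
  lower <- marg$value[which(cm >= tail_p)[1]]
  upper <- marg$value[which(cm >= 1 - tail_p)[1]]
  tibble(axis = axis, level = level, lower = lower, upper = upper)
}

#' Serialise parameters or a posterior to JSON
#'
#' `psy_params` objects serialise to their four named fields; posteriors to
#' their axes and mass array, enough to reconstruct the grid and the joint
#' distribution.
#'
#' @param x A `psy_params` or `psy_posterior`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return `path` invisibly if written, otherwise a JSON string.
#' @export
psy_to_json <- function(x, path = NULL) {
  payload <-
    if (inherits(x, "psy_params")) {
      list(alpha = x$alpha, beta = x$beta, gamma = x$gamma, lam = x$lam)
    } else if (inherits(x, "psy_posterior")) {
      list(axes = list(alpha = x$grid$alpha, beta = x$grid$beta, lam = x$grid$lam),
           mass = x$mass)
    } else {
      abort("Unsupported object for JSON serialisation.", class = "psivox_domain_error")
    }
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
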