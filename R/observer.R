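# Simulated observers. A pure observer responds to a double-target trial by
# choosing the first-onset target with probability psy_prob(true params,
# delta). Volitional interference - influences on the saccadic choice other
# than the asynchrony - is modelled as a delta-independent mixture component:
# with probability pi_vol the choice ignores delta entirely and goes left
# with probability `bias`. Mixing towards this process flattens the
# *estimated* psychometric function, which is exactly the mechanism by which
# weaker meta-volition is read off the slope.

#' Specification of a simulated observer
#'
#' @param alpha,beta,lam,gamma True psychometric parameters; see
#'   [psy_params()].
#' @param pi_vol Interference mixture weight in `[0, 1]`: probability that a
#'   double-target choice is driven by the delta-independent volitional
#'   process instead of the asynchrony. `pi_vol = 0` is the pure
#'   four-parameter observer.
#' @param bias Probability of choosing the *left* target under the
#'   interference process (0.5 = unbiased).
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(alpha, beta, lam = 0, gamma = PSY_GAMMA,
                          pi_vol = 0, bias = 0.5) {
  params <- psy_params(alpha = alpha, beta = beta, lam = lam, gamma = gamma)
  if (pi_vol < 0 || pi_vol > 1 || bias < 0 || bias > 1) {
    abort("`pi_vol` and `bias` must lie in [0, 1].", class = "psivox_domain_error")
  }
  structure(list(params = params, pi_vol = pi_vol, bias = bias),
            class = "observer_spec")
}

#' Instantiate a responding observer from its specification
#'
#' The returned observer exposes `respond(kind, first_side, delta)`. On a
#' single-target trial it always foveates the lit target. On a double-target
#' trial it responds through the interference process with probability
#' `pi_vol` (left with probability `bias`), otherwise it chooses the
#' first-onset target with probability `psy_prob(true params, delta)`. Draws
#' come from the R RNG stream active at call time, so the session runner's
#' seeding makes responses reproducible.
#'
#' @param spec An [observer_spec()].
#' @return An object of class `psy_observer`.
#' @export
make_observer <- function(spec) {
  stopifnot(inherits(spec, "observer_spec"))
  respond <- function(kind, first_side, delta) {
    if (kind == "single") return(first_side)
    if (spec$pi_vol > 0 && runif(1) < spec$pi_vol) {
      return(if (runif(1) < spec$bias) "L" else "R")
    }
    p_first <- psy_prob(delta, params = spec$params)
    chose_first <- runif(1) < p_first
    other <- if (first_side == "L") "R" else "L"
    if (chose_first) first_side else other
  }
  structure(list(spec = spec, respond = respond), class = "psy_observer")
}

#' @export
print.psy_observer <- function(x, ...) {
  p <- x$spec$params
  cat(sprintf("<psy_observer> alpha %.1f, beta %.3f, lam %.3f, pi_vol %.2f, bias %.2f\n",
              p$alpha, p$beta, p$lam, x$spec$pi_vol, x$spec$bias))
  invisible(x)
}
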