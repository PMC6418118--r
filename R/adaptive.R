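# Trial-by-trial Bayesian adaptive engine (the psi method): flat prior,
# multiplicative posterior updates, and selection of the next asynchrony as
# the candidate minimising the expected Shannon entropy of the joint
# posterior (equivalently, maximising expected information gain, since the
# current entropy is fixed at selection time).
#
# For speed the expected entropy is reduced algebraically to matrix-vector
# products against a precomputed likelihood table L[node, candidate]:
# with w the posterior mass and p1(d) = sum_n w_n L_nd the predictive
# probability of "chose first",
#   H(posterior | outcome = 1) = log p1 - (1/p1) sum_n w_n L_nd log(w_n L_nd)
# and the inner sum splits into crossprod(w log w, L) + crossprod(w, L log L),
# both products against per-grid constants. The two-outcome enumeration this
# replaces is kept as an independent oracle in the test suite.

#' Candidate asynchrony set
#'
#' The default set the adaptive algorithm selects from: 0 to 300 ms inclusive
#' in 10 ms steps (31 values, matching the display's temporal resolution).
#'
#' @param from,to,by Range and step in ms.
#' @return Numeric vector of candidate asynchronies.
#' @export
candidate_deltas <- function(from = 0, to = 300, by = 10) {
  d <- seq(from, to, by = by)
  if (any(d < 0)) abort("Candidate asynchronies must be non-negative.",
                        class = "psivox_config_error")
  d
}

# Likelihood table and its entropy companions for a grid x candidate set.
likelihood_table <- function(grid, candidates) {
  nodes <- grid$nodes
  scale <- 10^nodes$beta
  span <- 1 - PSY_GAMMA - nodes$lam
  L <- vapply(candidates, function(d) {
    PSY_GAMMA + span * plogis(scale * (d - nodes$alpha))
  }, numeric(nrow(nodes)))
  M <- 1 - L
  # xlogx guard: likelihoods can round to exactly 0/1 at saturating deltas
  list(candidates = candidates, L = L, LlogL = xlogx(L), MlogM = xlogx(M))
}

#' Bayesian posterior update after one double-target trial
#'
#' Multiplies the current posterior mass by the per-node likelihood of the
#' observed outcome and renormalises. Vectors of `delta`/`chose_first` are
#' applied sequentially (the update is order-invariant, so this equals a
#' single batch update with the product likelihood).
#'
#' @param post A `psy_posterior`.
#' @param delta Asynchrony (ms) of the trial(s).
#' @param chose_first Logical outcome(s), same length as `delta`.
#' @return The updated `psy_posterior`.
#' @export
update_posterior <- function(post, delta, chose_first) {
  stopifnot(inherits(post, "psy_posterior"), length(delta) == length(chose_first))
  mass <- post$mass
  for (i in seq_along(delta)) {
    mass <- mass * likelihood_slice(post$grid, delta[i], chose_first[i])
    s <- sum(mass)
    if (!is.finite(s) || s <= 0) {
      abort("Posterior update annihilated all mass.", class = "psivox_internal_error")
    }
    mass <- mass / s
  }
  new_posterior(post$grid, mass)
}

#' Expected posterior entropy after a trial at each candidate asynchrony
#'
#' For each `delta`, the posterior-predictive average over the two possible
#' outcomes of the Shannon entropy of the updated posterior:
#' `sum_outcome P(outcome | post, delta) * H(update(post, delta, outcome))`.
#' The adaptive rule picks the minimiser.
#'
#' @param post A `psy_posterior`.
#' @param delta Numeric vector of candidate asynchronies (ms).
#' @param table Optional precomputed likelihood table for `delta` (internal
#'   fast path used by the session runner).
#' @return Numeric vector of expected entropies (nats), one per `delta`.
#' @export
expected_posterior_entropy <- function(post, delta, table = NULL) {
  stopifnot(inherits(post, "psy_posterior"))
  if (is.null(table)) table <- likelihood_table(post$grid, delta)
  w <- post$mass
  u <- xlogx(w)
  su <- sum(u)
  p1 <- as.vector(crossprod(w, table$L))
  a1 <- as.vector(crossprod(u, table$L))
  s1 <- a1 + as.vector(crossprod(w, table$LlogL))
  p0 <- 1 - p1
  s0 <- (su - a1) + as.vector(crossprod(w, table$MlogM))
  h1 <- ifelse(p1 > 0, log(p1) - s1 / p1, 0)
  h0 <- ifelse(p0 > 0, log(p0) - s0 / p0, 0)
  eh <- p1 * h1 + p0 * h0
  pmax(eh, 0) # clip tiny negative rounding residue near point-mass posteriors
}

#' Select the next asynchrony by expected information gain
#'
#' Returns the candidate minimising [expected_posterior_entropy()]; ties are
#' broken towards the smallest asynchrony so selection is deterministic.
#'
#' @param post A `psy_posterior`.
#' @param candidates Candidate asynchronies (ms), default [candidate_deltas()].
#' @param table Optional precomputed likelihood table (internal fast path).
#' @return A single asynchrony in ms.
#' @export
select_next_delta <- function(post, candidates = candidate_deltas(), table = NULL) {
  if (length(candidates) == 0L) {
    abort("Candidate set is empty.", class = "psivox_config_error")
  }
  eh <- expected_posterior_entropy(post, candidates, table = table)
  ord <- order(candidates)
  cand <- candidates[ord]
  cand[which.min(eh[ord])] # which.min takes the first minimum: smallest delta
}

#' Session configuration for the adaptive choice task
#'
#' Encodes the session design: 400 main trials split exactly 50/50 between
#' single-target and double-target trials, preceded by 50 training trials that
#' are excluded from estimation, with the first double-target asynchrony at
#' 300 ms and subsequent ones chosen adaptively.
#'
#' @param n_main Total main trials (default 400).
#' @param p_single Proportion of single-target main trials (default 0.5,
#'   allocated exactly).
#' @param n_training Training trials preceding the main run (default 50).
#' @param start_delta First double-target asynchrony in ms (default 300; must
#'   be in the candidate set).
#' @param candidates Candidate asynchronies, default [candidate_deltas()].
#' @param grid Parameter grid, default [psy_grid()].
#' @param selection `"adaptive"` (expected-entropy minimisation) or
#'   `"random"` (uniform draw from the candidates; used as a yardstick in
#'   efficiency comparisons).
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_main = 400L, p_single = 0.5, n_training = 50L,
                           start_delta = 300, candidates = candidate_deltas(),
                           grid = psy_grid(),
                           selection = c("adaptive", "random")) {
  selection <- rlang::arg_match(selection)
  n_single <- round(n_main * p_single)
  if (n_single != n_main * p_single) {
    abort("`n_main * p_single` must be a whole number (exact allocation).",
          class = "psivox_config_error")
  }
  if (!start_delta %in% candidates) {
    abort("`start_delta` must belong to the candidate set.",
          class = "psivox_config_error")
  }
  if (n_training < 0 || n_main < 1) {
    abort("Trial counts must be non-negative (and n_main >= 1).",
          class = "psivox_config_error")
  }
  structure(list(n_main = as.integer(n_main), p_single = p_single,
                 n_single = as.integer(n_single),
                 n_double = as.integer(n_main - n_single),
                 n_training = as.integer(n_training),
                 start_delta = start_delta, candidates = candidates,
                 grid = grid, selection = selection),
            class = "session_config")
}

# Interleaved trial schedule: kinds in seeded random order with exact
# allocation, single-target sides balanced L/R, double-target first sides
# random. Training mirrors the main mix.
make_schedule <- function(n_single, n_double, phase) {
  kind <- sample(c(rep("single", n_single), rep("double", n_double)))
  side <- character(length(kind))
  side[kind == "single"] <- sample(c(rep("L", ceiling(n_single / 2)),
                                     rep("R", floor(n_single / 2)))[seq_len(n_single)])
  side[kind == "double"] <- sample(c("L", "R"), n_double, replace = TRUE)
  tibble(phase = phase, kind = kind, first_side = side)
}

#' Run one simulated session of the adaptive choice task
#'
#' Simulates the full session against an observer: `n_training` training
#' trials (same single/double mix, uniformly random asynchronies, excluded
#' from estimation), then `n_main` main trials in seeded random order with the
#' exact single/double allocation. The posterior starts flat at the first main
#' double-target trial, whose asynchrony is `start_delta`; each subsequent
#' double-target asynchrony is chosen by [select_next_delta()] (or uniformly
#' at random under `selection = "random"`). Single-target trials produce no
#' posterior update: no model parameter is informed by them — their role in
#' the task is to discourage anticipatory strategies.
#'
#' All randomness flows from `seed`: the schedule and the observer use
#' sub-streams derived with [derive_seed()], so the same seed and observer
#' spec give a bit-identical trial log.
#'
#' @param observer An observer from [make_observer()].
#' @param config A [session_config()].
#' @param seed Integer seed for the session.
#' @return An object of class `psy_session`: a list with `trials` (tibble:
#'   `index`, `phase`, `kind`, `first_side`, `delta_ms`, `response_side`,
#'   `chose_first`), `posterior`, `estimate`, `entropy_trace` (posterior
#'   entropy after each estimation trial), `n_estimation_trials`, `config`,
#'   `seed`.
#' @export
run_session <- function(observer, config = session_config(), seed) {
  stopifnot(inherits(observer, "psy_observer"), inherits(config, "session_config"))
  table <- likelihood_table(config$grid, config$candidates)
  n_tr <- config$n_training
  tr_single <- round(n_tr * config$p_single)

  schedule <- with_seed(derive_seed(seed, "schedule"), {
    training <- make_schedule(tr_single, n_tr - tr_single, "training")
    main <- make_schedule(config$n_single, config$n_double, "main")
    training$delta_ms <- 0
    training$delta_ms[training$kind == "double"] <-
      sample(config$candidates, sum(training$kind == "double"), replace = TRUE)
    dplyr::bind_rows(training, main)
  })

  mass <- flat_posterior(config$grid)$mass
  n <- nrow(schedule)
  phase <- schedule$phase; kind <- schedule$kind; first_side <- schedule$first_side
  delta <- schedule$delta_ms
  if (is.null(delta)) delta <- rep(0, n)
  delta[is.na(delta)] <- 0
  response <- character(n)
  chose_first <- rep(NA, n)
  entropy_trace <- numeric(config$n_double)
  n_upd <- 0L
  first_main_double <- TRUE
  post_for <- function(m) new_posterior(config$grid, m)

  with_seed(derive_seed(seed, "observer"), {
    for (i in seq_len(n)) {
      if (kind[i] == "single") {
        response[i] <- observer$respond(kind = "single", first_side = first_side[i],
                                        delta = 0)
        delta[i] <- 0
        next
      }
      if (phase[i] == "main") {
        if (first_main_double) {
          delta[i] <- config$start_delta
          first_main_double <- FALSE
        } else if (config$selection == "adaptive") {
          delta[i] <- select_next_delta(post_for(mass), config$candidates,
                                        table = table)
        } else {
          delta[i] <- sample(config$candidates, 1L)
        }
      }
      side <- observer$respond(kind = "double", first_side = first_side[i],
                               delta = delta[i])
      if (!side %in% c("L", "R")) {
        abort("Observer returned an invalid response; session aborted.",
              class = "psivox_observer_error")
      }
      response[i] <- side
      chose_first[i] <- side == first_side[i]
      if (phase[i] == "main") {
        # delta is always a candidate: update straight from the table column
        d <- match(delta[i], table$candidates)
        lik <- if (chose_first[i]) table$L[, d] else 1 - table$L[, d]
        mass <- mass * lik
        s <- sum(mass)
        if (!is.finite(s) || s <= 0) {
          abort("Posterior update annihilated all mass.",
                class = "psivox_internal_error")
        }
        mass <- mass / s
        n_upd <- n_upd + 1L
        entropy_trace[n_upd] <- -sum(xlogx(mass))
      }
    }
  })

  entropy_trace <- entropy_trace[seq_len(n_upd)]
  post <- post_for(mass)
  trials <- tibble(index = seq_len(n), phase = phase, kind = kind,
                   first_side = first_side, delta_ms = delta,
                   response_side = response, chose_first = chose_first)
  structure(list(trials = trials, posterior = post,
                 estimate = point_estimate(post),
                 entropy_trace = entropy_trace,
                 n_estimation_trials = length(entropy_trace),
                 config = config, seed = seed),
            class = "psy_session")
}

#' @export
print.psy_session <- function(x, ...) {
  est <- x$estimate
  cat(sprintf("<psy_session> %d trials (%d estimation), final entropy %.3f nats\n",
              nrow(x$trials), x$n_estimation_trials,
              posterior_entropy(x$posterior)))
  cat(sprintf("  estimates: alpha %.1f ms, beta %.3f, lam %.3f\n",
              est$alpha, est$beta, est$lam))
  invisible(x)
}

#' Write or read a trial log as CSV
#'
#' The CSV header is exactly
#' `index,phase,kind,first_side,delta_ms,response_side,chose_first`.
#' `chose_first` is empty on single-target trials.
#'
#' @param session A `psy_session` (or its `trials` tibble).
#' @param path Output CSV path.
#' @return `path` invisibly; `read_trials()` returns the trials tibble.
#' @export
write_trials <- function(session, path) {
  trials <- if (inherits(session, "psy_session")) session$trials else session
  stopifnot(identical(names(trials),
                      c("index", "phase", "kind", "first_side", "delta_ms",
                        "response_side", "chose_first")))
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    index = readr::col_integer(), phase = readr::col_character(),
    kind = readr::col_character(), first_side = readr::col_character(),
    delta_ms = readr::col_double(), response_side = readr::col_character(),
    chose_first = readr::col_logical()))
}
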