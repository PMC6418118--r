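# The Bayesian adaptive engine: flat prior, multiplicative updates,
# expected-entropy stimulus selection, and the full session runner.

test_that("the flat prior is uniform with maximal entropy", {
  g <- psy_grid(n_alpha = 2, n_beta = 2, n_lam = 2)
  post <- flat_posterior(g)
  expect_equal(post$mass, rep(0.125, 8))
  expect_equal(sum(post$mass), 1, tolerance = 1e-12)
  expect_equal(posterior_entropy(post), log(8))
})

test_that("posterior updates implement Bayes rule on a hand-checked grid", {
  # single-node grid: posterior is trivially unchanged
  g1 <- psy_grid(alpha_range = c(120, 120), beta_range = c(-1, -1),
                 lam_range = c(0, 0), n_alpha = 1, n_beta = 1, n_lam = 1)
  expect_equal(update_posterior(flat_posterior(g1), 100, TRUE)$mass, 1)
  # 2x2x1 grid: hand Bayes from a uniform prior
  g2 <- psy_grid(alpha_range = c(80, 200), beta_range = c(-1.2, -0.5),
                 lam_range = c(0.02, 0.02), n_alpha = 2, n_beta = 2, n_lam = 1)
  lik <- numeric(4)
  for (i in 1:4) {
    lik[i] <- psy_prob(110, alpha = g2$nodes$alpha[i], beta = g2$nodes$beta[i],
                       lam = g2$nodes$lam[i])
  }
  hand <- (0.25 * lik) / sum(0.25 * lik)
  expect_equal(update_posterior(flat_posterior(g2), 110, TRUE)$mass, hand,
               tolerance = 1e-12)
})

test_that("sequential updates equal one batch update with the product likelihood", {
  g <- toy_grid()
  deltas <- c(100, 150, 80, 220, 150)
  outcomes <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  seq_post <- flat_posterior(g)
  for (i in seq_along(deltas)) {
    seq_post <- update_posterior(seq_post, deltas[i], outcomes[i])
  }
  # batch oracle: accumulate the product likelihood, normalise once
  prod_lik <- rep(1, nrow(g$nodes))
  for (i in seq_along(deltas)) {
    prod_lik <- prod_lik * likelihood_slice(g, deltas[i], outcomes[i])
  }
  batch <- prod_lik / sum(prod_lik)
  expect_equal(seq_post$mass, batch, tolerance = 1e-10)
  # order invariance: any permutation of the trials gives the same posterior
  perm <- c(3, 5, 1, 4, 2)
  perm_post <- update_posterior(flat_posterior(g), deltas[perm], outcomes[perm])
  expect_equal(perm_post$mass, seq_post$mass, tolerance = 1e-10)
})

test_that("expected posterior entropy matches the two-outcome enumeration oracle", {
  g <- toy_grid()
  post <- update_posterior(flat_posterior(g), c(100, 160), c(TRUE, FALSE))
  cands <- candidate_deltas()
  expect_length(cands, 31)
  expect_equal(expected_posterior_entropy(post, cands),
               brute_expected_entropy(post, cands), tolerance = 1e-10)
  # information never hurts in expectation
  expect_true(all(expected_posterior_entropy(post, cands) <=
                    posterior_entropy(post) + 1e-10))
  # a point-mass posterior has zero expected entropy at every delta
  mass <- rep(0, nrow(g$nodes)); mass[4] <- 1
  pm <- psivox:::new_posterior(g, mass)
  expect_equal(expected_posterior_entropy(pm, cands), rep(0, 31),
               tolerance = 1e-12)
})

test_that("delta selection is the entropy argmin with smallest-delta ties", {
  g <- toy_grid()
  cands <- candidate_deltas()
  # all-ties point mass: tie-break to the smallest candidate
  mass <- rep(0, nrow(g$nodes)); mass[2] <- 1
  expect_equal(select_next_delta(psivox:::new_posterior(g, mass), cands), 0)
  # random posteriors agree with the brute-force argmin
  set.seed(11)
  for (rep in 1:5) {
    m <- runif(nrow(g$nodes)); post <- psivox:::new_posterior(g, m)
    eh <- brute_expected_entropy(post, cands)
    expect_equal(select_next_delta(post, cands), cands[which.min(eh)])
    # removing the selected candidate never returns it again
    sel <- select_next_delta(post, cands)
    expect_false(select_next_delta(post, setdiff(cands, sel)) == sel)
  }
  expect_error(select_next_delta(flat_posterior(g), numeric(0)),
               class = "psivox_config_error")
})

test_that("a default session has the designed structure", {
  obs <- make_observer(observer_spec(alpha = 120, beta = -1, lam = 0.02))
  ses <- run_session(obs, session_config(), seed = 99)
  trials <- tidy(ses)
  expect_equal(nrow(trials), 450)
  expect_equal(sum(trials$phase == "training"), 50)
  main <- trials[trials$phase == "main", ]
  expect_equal(sum(main$kind == "single"), 200)
  expect_equal(sum(main$kind == "double"), 200)
  expect_equal(ses$n_estimation_trials, 200)
  # first main double-target trial starts the algorithm at 300 ms
  expect_equal(main$delta_ms[main$kind == "double"][1], 300)
  # single-target sides balanced exactly
  expect_equal(sum(main$first_side[main$kind == "single"] == "L"), 100)
  # single trials carry no outcome and no asynchrony
  expect_true(all(is.na(trials$chose_first[trials$kind == "single"])))
  expect_true(all(trials$delta_ms[trials$kind == "single"] == 0))
  # double-trial asynchronies come from the candidate set
  expect_true(all(trials$delta_ms[trials$kind == "double"] %in% candidate_deltas()))
  # and the posterior stays normalised after the full 200-update run
  expect_equal(sum(ses$posterior$mass), 1, tolerance = 1e-10)
})

test_that("training trials are excluded from the posterior", {
  obs <- make_observer(observer_spec(alpha = 150, beta = -0.8, lam = 0.03))
  ses <- run_session(obs, session_config(), seed = 7)
  main_dbl <- ses$trials[ses$trials$phase == "main" & ses$trials$kind == "double", ]
  replay <- update_posterior(flat_posterior(ses$config$grid),
                             main_dbl$delta_ms, main_dbl$chose_first)
  expect_equal(replay$mass, ses$posterior$mass, tolerance = 1e-10)
})

test_that("sessions are bit-reproducible for the same seed and observer spec", {
  spec <- observer_spec(alpha = 90, beta = -1.2, lam = 0.05, pi_vol = 0.2)
  s1 <- run_session(make_observer(spec), session_config(), seed = 123)
  s2 <- run_session(make_observer(spec), session_config(), seed = 123)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$posterior$mass, s2$posterior$mass)
  s3 <- run_session(make_observer(spec), session_config(), seed = 124)
  expect_false(identical(s1$trials, s3$trials))
})

test_that("an observer failure aborts the session", {
  broken <- structure(list(spec = NULL,
                           respond = function(kind, first_side, delta) "X"),
                      class = "psy_observer")
  expect_error(run_session(broken, session_config(), seed = 1),
               class = "psivox_observer_error")
})

test_that("averaged entropy traces decrease over the session", {
  traces <- sapply(1:8, function(i) {
    obs <- make_observer(observer_spec(alpha = 140, beta = -0.9, lam = 0.03))
    run_session(obs, session_config(), seed = 500 + i)$entropy_trace
  })
  avg <- rowMeans(traces)
  # strong monotone trend on the average trace (not asserted per trial)
  expect_true(avg[200] < avg[100])
  expect_true(avg[100] < avg[10])
  expect_gt(cor(seq_along(avg), avg, method = "spearman") * -1, 0.95)
})

test_that("trial logs round-trip through the exact CSV contract", {
  obs <- make_observer(observer_spec(alpha = 100, beta = -1))
  ses <- run_session(obs, session_config(n_main = 20, n_training = 4), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(ses, path)
  expect_identical(readLines(path, n = 1),
                   "index,phase,kind,first_side,delta_ms,response_side,chose_first")
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(ses$trials))
})
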