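# The four-parameter choice function, parameter grids, and posterior
# summaries.

test_that("choice probability matches the closed form at hand-checked points", {
  # midpoint: P = gamma + (1 - gamma)/2 with no lapse
  expect_equal(psy_prob(150, alpha = 150, beta = 0), 0.75)
  # steep slope saturates at the lapse-shrunk upper asymptote 1 - lam
  expect_equal(psy_prob(300, alpha = 50, beta = 2, lam = 0.1), 0.9,
               tolerance = 1e-9)
  # scalar hand evaluation: 10^-1 * (130 - 100) = 3 on the logistic scale
  expect_equal(psy_prob(130, alpha = 100, beta = -1, lam = 0.04),
               0.5 + 0.46 * plogis(3))
  expect_equal(0.5 + 0.46 * plogis(3), 0.9381840983, tolerance = 1e-8)
})

test_that("choice probability is monotone in delta and respects asymptotes", {
  grid <- psy_grid(n_alpha = 7, n_beta = 9, n_lam = 3)
  deltas <- seq(0, 300, by = 5)
  for (i in seq_len(nrow(grid$nodes))) {
    p <- psy_prob(deltas, alpha = grid$nodes$alpha[i], beta = grid$nodes$beta[i],
                  lam = grid$nodes$lam[i])
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0.5 - 1e-12 & p <= 1 - grid$nodes$lam[i] + 1e-12))
  }
})

test_that("domain violations are rejected", {
  expect_error(psy_prob(-1, alpha = 100, beta = 0), class = "psivox_domain_error")
  expect_error(psy_prob(10, alpha = 100, beta = 0, lam = 0.2),
               class = "psivox_domain_error")
  expect_error(psy_params(alpha = 100, beta = 0, lam = 0.11),
               class = "psivox_domain_error")
  expect_error(psy_params(alpha = 301, beta = 0), class = "psivox_domain_error")
  expect_error(psy_params(alpha = 100, beta = 2.5), class = "psivox_domain_error")
})

test_that("default grid spans the admissible ranges inclusively", {
  g <- psy_grid()
  expect_equal(range(g$alpha), c(0, 300))
  expect_equal(range(g$beta), c(-2, 2))
  expect_equal(range(g$lam), c(0, 0.1))
  expect_equal(nrow(g$nodes), 31 * 41 * 11)
})

test_that("grid endpoints are included and degenerate axes handled", {
  g <- psy_grid(n_alpha = 2, n_beta = 2, n_lam = 2)
  expect_equal(nrow(g$nodes), 8)
  expect_setequal(g$nodes$alpha, c(0, 300))
  expect_setequal(g$nodes$beta, c(-2, 2))
  expect_error(psy_grid(n_alpha = 1), class = "psivox_config_error")
  # collapsed lapse axis with one node is allowed
  g1 <- psy_grid(lam_range = c(0.02, 0.02), n_lam = 1)
  expect_equal(g1$lam, 0.02)
})

test_that("likelihood slices are complementary and match direct evaluation", {
  g <- toy_grid()
  l1 <- likelihood_slice(g, 100, TRUE)
  l0 <- likelihood_slice(g, 100, FALSE)
  expect_equal(l1 + l0, rep(1, nrow(g$nodes)))
  expect_true(all(l1 > 0 & l1 < 1))
  # node-by-node hand evaluation of the closed form
  direct <- numeric(nrow(g$nodes))
  for (i in seq_len(nrow(g$nodes))) {
    direct[i] <- 0.5 + (1 - 0.5 - g$nodes$lam[i]) *
      plogis(10^g$nodes$beta[i] * (100 - g$nodes$alpha[i]))
  }
  expect_equal(l1, direct)
  # single-node grid: one value equal to the point probability
  g1 <- psy_grid(alpha_range = c(120, 120), beta_range = c(-1, -1),
                 lam_range = c(0.05, 0.05), n_alpha = 1, n_beta = 1, n_lam = 1)
  expect_equal(likelihood_slice(g1, 90, TRUE),
               psy_prob(90, alpha = 120, beta = -1, lam = 0.05))
})

test_that("marginals sum the joint correctly", {
  g <- toy_grid()
  post <- flat_posterior(g)
  for (ax in c("alpha", "beta", "lam")) {
    m <- marginal_posterior(post, ax)
    expect_equal(sum(m$mass), 1, tolerance = 1e-10)
    expect_equal(m$mass, rep(1 / length(g[[ax]]), length(g[[ax]])))
  }
  # point mass propagates to a point-mass marginal at the right coordinate
  mass <- rep(0, nrow(g$nodes)); mass[5] <- 1
  pm <- psivox:::new_posterior(g, mass)
  mb <- marginal_posterior(pm, "beta")
  expect_equal(mb$mass[mb$value == g$nodes$beta[5]], 1)
  # 2x2x1 grid with hand-set masses: marginal = hand-summed rows/cols
  g2 <- psy_grid(alpha_range = c(100, 200), beta_range = c(-1, 0),
                 lam_range = c(0, 0), n_alpha = 2, n_beta = 2, n_lam = 1)
  # node order: alpha fastest then beta
  p2 <- psivox:::new_posterior(g2, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(marginal_posterior(p2, "alpha")$mass, c(0.1 + 0.3, 0.2 + 0.4))
  expect_equal(marginal_posterior(p2, "beta")$mass, c(0.1 + 0.2, 0.3 + 0.4))
})

test_that("point estimate is the marginal posterior mean with gamma fixed", {
  g <- toy_grid()
  mass <- rep(0, nrow(g$nodes)); mass[7] <- 1
  pm <- psivox:::new_posterior(g, mass)
  est <- point_estimate(pm)
  expect_equal(est$alpha, g$nodes$alpha[7])
  expect_equal(est$beta, g$nodes$beta[7])
  expect_equal(est$gamma, 0.5)
  # uniform posterior: midpoint of each range by symmetry
  est_u <- point_estimate(flat_posterior(g))
  expect_equal(est_u$alpha, 150)
  expect_equal(est_u$beta, -0.75)
  # asymmetric two-node posterior: mass-weighted average
  g2 <- psy_grid(alpha_range = c(100, 200), beta_range = c(0, 0),
                 lam_range = c(0, 0), n_alpha = 2, n_beta = 1, n_lam = 1)
  p2 <- psivox:::new_posterior(g2, c(0.25, 0.75))
  expect_equal(point_estimate(p2)$alpha, 0.25 * 100 + 0.75 * 200)
})

test_that("posterior and marginal masses stay normalised through updates", {
  post <- flat_posterior(psy_grid(n_alpha = 9, n_beta = 9, n_lam = 3))
  set.seed(4)
  for (i in 1:25) {
    post <- update_posterior(post, sample(seq(0, 300, 10), 1), runif(1) < 0.7)
  }
  expect_equal(sum(post$mass), 1, tolerance = 1e-10)
  expect_equal(sum(marginal_posterior(post, "beta")$mass), 1, tolerance = 1e-10)
  expect_true(all(post$mass >= 0))
})

test_that("parameters and posteriors serialise to JSON with stable keys", {
  est <- psy_params(alpha = 120, beta = -0.8, lam = 0.03)
  parsed <- jsonlite::fromJSON(psy_to_json(est))
  expect_equal(parsed, list(alpha = 120, beta = -0.8, gamma = 0.5, lam = 0.03))
  post <- flat_posterior(toy_grid())
  parsed2 <- jsonlite::fromJSON(psy_to_json(post))
  expect_equal(parsed2$axes$alpha, post$grid$alpha)
  expect_equal(sum(parsed2$mass), 1, tolerance = 1e-10)
})
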