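# Freedman-Lane permutation inference with max-TFCE FWE correction.

test_that("identical data across subjects give p = 1 everywhere", {
  coh <- make_cohort(small_cohort_spec(n_subjects = 8), seed = 12)
  coh$data <- matrix(rep(coh$data[1, ], each = 8), nrow = 8)
  res <- permutation_test(coh, design_matrix(coh$covariates),
                          n_perm = 50, seed = 1)
  expect_true(all(res$p_corr == 1))
})

test_that("the smallest attainable p is 1/(n_perm + 1)", {
  coh <- make_cohort(cohort_spec(shape = c(32, 40, 32), mask_fraction = 0.02),
                     seed = 13)
  res <- permutation_test(coh, design_matrix(coh$covariates),
                          "negative", n_perm = 99, seed = 2)
  expect_equal(min(res$p_corr), 1 / 100)
  expect_true(all(res$p_corr > 0 & res$p_corr <= 1))
})

test_that("tiny cohorts fall back to exhaustive enumeration with a warning", {
  coh <- make_cohort(small_cohort_spec(n_subjects = 6, sex_ratio = c(3, 3)),
                     seed = 14)
  expect_warning(
    res <- permutation_test(coh, design_matrix(coh$covariates),
                            n_perm = 1000, seed = 3),
    "exhaustively")
  expect_equal(res$n_perm, factorial(6) - 1) # identity excluded from the draws
})

test_that("corrected p-values are invariant to affine regressor rescaling", {
  coh <- make_cohort(cohort_spec(shape = c(32, 40, 32), mask_fraction = 0.02),
                     seed = 15)
  d1 <- design_matrix(coh$covariates)
  coh2 <- coh
  coh2$covariates$beta_slope <- 3.2 * coh$covariates$beta_slope - 1.4
  d2 <- design_matrix(coh2$covariates)
  r1 <- permutation_test(coh, d1, n_perm = 60, seed = 4)
  r2 <- permutation_test(coh2, d2, n_perm = 60, seed = 4)
  expect_equal(r1$p_corr, r2$p_corr, tolerance = 1e-12)
  expect_equal(r1$t, r2$t, tolerance = 1e-8)
})

test_that("negating the slopes swaps the two directions exactly", {
  coh <- make_cohort(cohort_spec(shape = c(32, 40, 32), mask_fraction = 0.02),
                     seed = 16)
  flipped <- coh
  flipped$covariates$beta_slope <- -coh$covariates$beta_slope
  pair <- run_both_directions(coh, design_matrix(coh$covariates),
                              n_perm = 60, seed = 5)
  pair_f <- run_both_directions(flipped, design_matrix(flipped$covariates),
                                n_perm = 60, seed = 5)
  expect_equal(pair$negative$p_corr, pair_f$positive$p_corr, tolerance = 1e-12)
  expect_equal(pair$positive$p_corr, pair_f$negative$p_corr, tolerance = 1e-12)
})

test_that("a planted negative effect is found only in the negative direction", {
  coh <- make_cohort(cohort_spec(shape = c(32, 40, 32), mask_fraction = 0.02),
                     seed = 17)
  pair <- run_both_directions(coh, design_matrix(coh$covariates),
                              n_perm = 200, seed = 6)
  cl <- tidy(pair)
  expect_gte(sum(cl$direction == "negative"), 1)
  expect_equal(sum(cl$direction == "positive"), 0)
  # the recovered cluster overlaps the planted region substantially
  sig <- pair$negative$adjacency$index[pair$negative$p_corr < 0.05]
  dice <- 2 * length(intersect(sig, coh$region)) /
    (length(sig) + length(coh$region))
  expect_gt(dice, 0.5)
})
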