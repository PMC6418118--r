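# Masked voxelwise GLM and variance smoothing.

# Hand-built cohort shell over an arbitrary mask, for controlled data.
shell_cohort <- function(data, mask, voxel_size = c(2, 2, 2)) {
  structure(list(data = data, mask = mask, region = integer(0),
                 affine = diag(c(voxel_size, 1)), voxel_size = voxel_size,
                 covariates = NULL, spec = NULL, seed = NULL),
            class = "skeleton_cohort")
}

line_mask <- function(n, shape = c(32, 32, 32)) {
  m <- array(FALSE, dim = shape)
  m[seq_len(n), 16, 16] <- TRUE
  m
}

test_that("voxel t statistics match an independent least-squares fit", {
  set.seed(21)
  cov <- tibble::tibble(beta_slope = rnorm(5), age = runif(5, 21, 28))
  Y <- matrix(rnorm(15), nrow = 5)
  coh <- shell_cohort(Y, line_mask(3))
  coh$covariates <- cov
  tm <- fit_glm(coh, design_matrix(cov, nuisance = "age"), var_smooth_sigma = 0)
  for (v in 1:3) {
    oracle <- summary(lm(Y[, v] ~ cov$beta_slope + cov$age))
    expect_equal(tm$t[v], oracle$coefficients["cov$beta_slope", "t value"],
                 tolerance = 1e-10)
  }
  expect_equal(tm$df, 2)
})

test_that("an orthogonal nuisance column changes t only through the df rescale", {
  set.seed(22)
  n <- 8
  x <- rnorm(n)
  y <- matrix(2 * x + rnorm(n, 0, 0.5), ncol = 1)
  cov1 <- tibble::tibble(beta_slope = x)
  # build a column orthogonal to the intercept, the regressor, and the data
  base <- cbind(1, x, y)
  cand <- rnorm(n)
  z <- as.vector(cand - base %*% solve(crossprod(base), crossprod(base, cand)))
  cov2 <- tibble::tibble(beta_slope = x, z = z)
  coh <- shell_cohort(y, line_mask(1))
  t1 <- fit_glm({coh$covariates <- cov1; coh},
                design_matrix(cov1, nuisance = character(0)),
                var_smooth_sigma = 0)
  t2 <- fit_glm({coh$covariates <- cov2; coh},
                design_matrix(cov2, nuisance = "z"), var_smooth_sigma = 0)
  # residual sum of squares is unchanged, so t scales exactly with sqrt(df)
  expect_equal(t2$t[1], t1$t[1] * sqrt((n - 3) / (n - 2)), tolerance = 1e-10)
})

test_that("an exact linear fit yields a capped, flagged t rather than an error", {
  x <- c(-1, -0.5, 0, 0.5, 1)
  cov <- tibble::tibble(beta_slope = x)
  Y <- cbind(3 - 2 * x, rnorm(5))
  coh <- shell_cohort(Y, line_mask(2))
  coh$covariates <- cov
  tm <- fit_glm(coh, design_matrix(cov, nuisance = character(0)),
                var_smooth_sigma = 0)
  expect_equal(tm$t[1], -1e6)
  expect_true(1L %in% tm$capped)
  expect_true(is.finite(tm$t[2]))
})

test_that("design validation catches rank deficiency and missing columns", {
  cov <- tibble::tibble(beta_slope = 1:5, age = 2 * (1:5), sex = rep(0, 5))
  expect_error(design_matrix(cov), class = "psivox_config_error") # age ~ slope
  expect_error(design_matrix(tibble::tibble(a = 1:5)),
               class = "psivox_config_error")
})

test_that("variance smoothing averages within the mask with unit row sums", {
  mask <- line_mask(10)
  S <- psivox:::smoothing_matrix(mask, c(2, 2, 2), sigma_mm = 4)
  expect_equal(Matrix::rowSums(S), rep(1, 10), tolerance = 1e-12)
  # smoothing a constant variance image is the identity on it
  expect_equal(as.vector(S %*% rep(2.5, 10)), rep(2.5, 10), tolerance = 1e-12)
  # a tiny kernel reduces to no smoothing
  S0 <- psivox:::smoothing_matrix(mask, c(2, 2, 2), sigma_mm = 1e-3)
  expect_equal(as.matrix(S0), diag(10), ignore_attr = TRUE)
})
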