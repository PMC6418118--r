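# Synthetic skeleton masks and imaging cohorts.

test_that("skeleton masks are thin, in-bounds, and seeded deterministically", {
  m <- skeleton_mask(c(32, 32, 32), target_fraction = 0.012, seed = 5)
  frac <- mean(m)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.05)
  expect_identical(dim(m), c(32L, 32L, 32L))
  m2 <- skeleton_mask(c(32, 32, 32), target_fraction = 0.012, seed = 5)
  expect_identical(which(m), which(m2))
  m3 <- skeleton_mask(c(32, 32, 32), target_fraction = 0.012, seed = 6)
  expect_false(identical(which(m), which(m3)))
  expect_error(skeleton_mask(c(16, 32, 32)), class = "psivox_config_error")
  expect_error(skeleton_mask(c(32, 32, 32), target_fraction = 0.2),
               class = "psivox_config_error")
})

test_that("default cohorts carry the designed covariate structure", {
  coh <- make_cohort(cohort_spec(), seed = 2)
  expect_equal(nrow(coh$covariates), 13)
  expect_equal(sum(coh$covariates$sex == 0), 6) # 6:7 male:female
  expect_equal(sum(coh$covariates$sex == 1), 7)
  expect_true(all(coh$covariates$age >= 21 & coh$covariates$age <= 28))
  expect_equal(nrow(coh$data), 13)
  expect_equal(ncol(coh$data), sum(coh$mask))
  expect_length(coh$region, 150)
  # planted region is contained in the mask
  expect_true(all(coh$region %in% which(coh$mask)))
  # reproducibility is bitwise
  coh2 <- make_cohort(cohort_spec(), seed = 2)
  expect_identical(coh$data, coh2$data)
  expect_identical(coh$covariates, coh2$covariates)
})

test_that("the planted region is a single connected component", {
  coh <- make_cohort(cohort_spec(), seed = 8)
  in_set <- which(coh$mask) %in% coh$region
  ff <- flood_fill_labels(coh$mask, in_set, 26)
  expect_equal(max(ff$labels), 1)
})

test_that("a null cohort has no slope-map association", {
  spec <- cohort_spec(n_subjects = 50, shape = c(32, 32, 32),
                      mask_fraction = 0.012, region_size = 0, effect_size = 0)
  coh <- make_cohort(spec, seed = 3)
  r <- cor(coh$covariates$beta_slope, coh$data)
  expect_lt(abs(mean(r)), 0.05)
})

test_that("a planted effect induces a strong negative within-region correlation", {
  rs <- vapply(1:20, function(s) {
    coh <- make_cohort(cohort_spec(shape = c(32, 40, 32), mask_fraction = 0.02),
                       seed = s)
    cols <- match(coh$region, which(coh$mask))
    mean(cor(coh$covariates$beta_slope, coh$data[, cols]))
  }, numeric(1))
  expect_lt(mean(rs), -0.7) # effect 3x noise SD: expected r near -0.95
  expect_true(all(rs < 0)) # the planted sign convention
})

test_that("cohorts round-trip through NIfTI + CSV", {
  coh <- make_cohort(cohort_spec(n_subjects = 4, shape = c(32, 32, 32),
                                 mask_fraction = 0.012, region_size = 120),
                     seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_identical(readLines(file.path(dir, "covariates.csv"), n = 1),
                   "subject_id,beta_slope,age,sex")
  back <- read_cohort(dir)
  expect_equal(back$data, coh$data, tolerance = 1e-12)
  expect_equal(which(back$mask), which(coh$mask))
  expect_equal(sort(back$region), sort(coh$region))
  expect_equal(as.data.frame(back$covariates), as.data.frame(coh$covariates))
  expect_equal(back$voxel_size, coh$voxel_size, ignore_attr = TRUE)
  # a missing subject volume is reported by name
  file.remove(file.path(dir, "sub-03.nii"))
  expect_error(read_cohort(dir), "sub-03", class = "psivox_format_error")
})
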