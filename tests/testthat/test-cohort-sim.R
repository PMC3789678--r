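test_that("ground-truth moments converge to the cohort spec", {
  spec <- cohort_spec(n_per_group = 2000L)
  tr <- simulate_cohort(spec, seed = 21)
  ctl <- tr[tr$role == "control", ]
  on <- tr[tr$role == "on", ]
  vals <- function(d) cbind(d$rnfl_um, d$gclipl_um, d$inl_um)
  expect_equal(unname(colMeans(vals(ctl))), spec$control_mean,
               tolerance = 0.01)
  expect_equal(unname(colMeans(vals(on))), spec$on_mean, tolerance = 0.01)
  expect_equal(unname(apply(vals(ctl), 2, sd)), spec$control_sd,
               tolerance = 0.05)
  expect_equal(unname(apply(vals(on), 2, sd)), spec$on_sd, tolerance = 0.05)
})

test_that("generative inter-layer correlations are recovered", {
  spec <- cohort_spec(n_per_group = 500L)
  tr <- simulate_cohort(spec, seed = 4)
  ctl <- tr[tr$role == "control", ]
  r <- cor(ctl$gclipl_um, ctl$inl_um)
  ci <- fisher_ci(0.65, 500)
  expect_gt(r, ci[1]); expect_lt(r, ci[2])
})

test_that("full fellow-eye coupling duplicates the ON eye exactly", {
  spec <- cohort_spec(n_per_group = 50L, fellow_coupling = 1)
  tr <- simulate_cohort(spec, seed = 2)
  on <- tr[tr$role == "on", ]
  fe <- tr[tr$role == "fellow", ]
  fe <- fe[match(on$subject, fe$subject), ]
  expect_equal(on$rnfl_um, fe$rnfl_um, tolerance = 1e-10)
  expect_equal(on$inl_um, fe$inl_um, tolerance = 1e-10)
})

test_that("exactly round(prevalence * n) ON eyes receive cysts", {
  tr <- simulate_cohort(cohort_spec(n_per_group = 36L,
                                    cyst_prevalence = 5 / 36), seed = 9)
  expect_identical(sum(tr$cyst[tr$role == "on"]), 5L)
  expect_identical(sum(tr$cyst[tr$role != "on"]), 0L)
  tr2 <- simulate_cohort(cohort_spec(n_per_group = 36L,
                                     cyst_prevalence = 0), seed = 9)
  expect_identical(sum(tr2$cyst), 0L)
})

test_that("extreme cyst assignment picks the thickest-INL eyes", {
  tr <- simulate_cohort(cohort_spec(n_per_group = 40L,
                                    cyst_prevalence = 0.25,
                                    cyst_assignment = "extreme"), seed = 3)
  on <- tr[tr$role == "on", ]
  expect_gt(min(on$inl_um[on$cyst]), max(on$inl_um[!on$cyst]) - 1e-9)
})

test_that("a non-PSD correlation matrix is rejected before rendering", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(cohort_spec(control_corr = bad), "positive semi-definite")
})

test_that("cohort simulation is reproducible under its seed", {
  a <- simulate_cohort(cohort_spec(n_per_group = 10L), seed = 5)
  b <- simulate_cohort(cohort_spec(n_per_group = 10L), seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
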