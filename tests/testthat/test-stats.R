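test_that("the pooled t statistic matches the closed form on a fixture", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      v = c(1, 2, 3, 4, 5, 6))
  out <- group_compare(d, "v")
  expect_equal(out$t, -3.674, tolerance = 5e-4)
  expect_equal(out$df, 4)
})

test_that("identical groups give t = 0, p = 1 by convention", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 4), v = rep(5, 8))
  expect_message(out <- group_compare(d, "v"), "convention")
  expect_identical(out$t, 0)
  expect_identical(out$p, 1)
})

test_that("t and r match brute-force formulas on random fixtures", {
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 3))
    y <- rnorm(n2, 1, sd = runif(1, 0.5, 3))
    d <- tibble::tibble(group = rep(c("a", "b"), c(n1, n2)), v = c(x, y))
    got <- group_compare(d, "v")
    ref <- oracle_t_pooled(x, y)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)

    m <- sample(4:30, 1)
    a <- rnorm(m); b <- 0.3 * a + rnorm(m)
    gr <- pearson_r(a, b)
    rr <- oracle_pearson(a, b)
    expect_equal(gr$r, rr$r, tolerance = 1e-10)
    expect_equal(gr$p, rr$p, tolerance = 1e-10)
  }
})

test_that("pearson_r handles exact, null and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  set.seed(1)
  big <- rnorm(10000)
  expect_lt(abs(pearson_r(big, rnorm(10000))$r), 0.03)
  expect_error(pearson_r(x, rep(1, 10)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("asymmetry records subtract fellow from ON eye with correct sign", {
  s <- tibble::tibble(
    subject = rep(c("p1", "p2", "p3"), each = 2),
    role = rep(c("on", "fellow"), 3),
    rnfl_um = c(20, 30, 25, 28, 30, 30),
    gclipl_um = c(60, 90, 70, 85, 80, 82),
    inl_um = c(48, 40, 45, 41, 42, 41))
  out <- asymmetry_analysis(s)
  expect_equal(out$records$d_gclipl_um, c(-30, -15, -2))
  expect_equal(out$records$d_inl_um, c(8, 4, 1))
  # thinner ON GCL/IPL -> negative delta; thicker ON INL -> positive
  expect_true(all(out$records$d_gclipl_um < 0))
})

test_that("identical fellow eyes give zero asymmetry and undefined r", {
  s <- tibble::tibble(
    subject = rep(sprintf("p%d", 1:4), each = 2),
    role = rep(c("on", "fellow"), 4),
    rnfl_um = rep(c(25, 25, 30, 30, 28, 28, 27, 27)),
    gclipl_um = rep(70, 8), inl_um = rep(40, 8))
  expect_message(out <- asymmetry_analysis(s), "undefined")
  expect_true(all(out$records$d_gclipl_um == 0))
  expect_null(out$correlation)
})

test_that("binocular-ON subjects are excluded from the asymmetry analysis", {
  s <- tibble::tibble(
    subject = rep(sprintf("p%d", 1:5), each = 2),
    role = rep(c("on", "fellow"), 5),
    rnfl_um = rnorm(10, 28), gclipl_um = rnorm(10, 70),
    inl_um = rnorm(10, 42),
    exclude = rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), each = 2))
  expect_message(out <- asymmetry_analysis(s), "dropped")
  expect_identical(nrow(out$records), 4L)
  expect_identical(out$n_excluded, 1L)
})

test_that("the asymmetry correlation recovers a negative generative coupling", {
  set.seed(31)
  n <- 200
  # construct per-subject eye pairs whose differences carry rho = -0.75
  S <- matrix(c(1, -0.75, -0.75, 1), 2)
  d <- MASS::mvrnorm(n, c(0, 0), S)
  base_g <- rnorm(n, 70, 10); base_i <- rnorm(n, 42, 4)
  s <- tibble::tibble(
    subject = rep(sprintf("p%03d", 1:n), each = 2),
    role = rep(c("on", "fellow"), n),
    rnfl_um = 28,
    gclipl_um = as.vector(rbind(base_g + 3 * d[, 1], base_g)),
    inl_um = as.vector(rbind(base_i + 1.5 * d[, 2], base_i)))
  out <- asymmetry_analysis(s)
  ci <- fisher_ci(-0.75, n)
  expect_gt(out$correlation$r, ci[1])
  expect_lt(out$correlation$r, ci[2])
})

test_that("identical groups give an all-zero deviation map", {
  g <- tidyr::expand_grid(subject = sprintf("s%d", 1:4),
                          line = 1:12, eccentricity_um = c(750, 1450, 2150),
                          layer = c("RNFL", "GCLIPL", "INL"))
  g$thickness_um <- 40 + g$line
  g$valid <- TRUE
  d <- pointwise_deviation(g, g)
  expect_true(all(d$map$deviation_um == 0))
})

test_that("a constructed proportional coupling yields r = -1", {
  base <- tidyr::expand_grid(subject = "c", line = 1:12,
                             eccentricity_um = c(750, 1450, 2150),
                             layer = c("RNFL", "GCLIPL", "INL"))
  base$thickness_um <- ifelse(base$layer == "GCLIPL", 95, 40)
  base$valid <- TRUE
  on <- base
  on$subject <- "p"
  loss <- 5 + 10 * abs(sin((on$line + on$eccentricity_um / 700)))
  on$thickness_um <- ifelse(on$layer == "GCLIPL",
                            on$thickness_um - loss,
                            ifelse(on$layer == "INL",
                                   on$thickness_um + 0.3 * loss,
                                   on$thickness_um))
  d <- pointwise_deviation(rbind(base, base, base), rbind(on, on),
                           min_eyes = 2)
  expect_equal(d$cross_layer$r, -1, tolerance = 0.01)
})

test_that("nasal-only GCL/IPL loss shows up as nasal-dominant deviation", {
  mk_grid <- function(subject, nasal_loss) {
    g <- tidyr::expand_grid(subject = subject, line = 1:12,
                            eccentricity_um = c(750, 1450, 2150),
                            layer = c("RNFL", "GCLIPL", "INL"))
    g$thickness_um <- ifelse(g$layer == "GCLIPL", 95, 40)
    nasal <- g$line %in% 5:9
    g$thickness_um <- g$thickness_um -
      ifelse(g$layer == "GCLIPL" & nasal, nasal_loss, 0)
    g$valid <- TRUE
    g
  }
  ctl <- rbind(mk_grid("c1", 0), mk_grid("c2", 0))
  on <- rbind(mk_grid("p1", 20), mk_grid("p2", 22))
  d <- pointwise_deviation(ctl, on)
  ag <- d$aggregates[d$aggregates$layer == "GCLIPL", ]
  expect_gt(ag$mean_deviation_um[ag$nasal],
            ag$mean_deviation_um[!ag$nasal] + 10)
})

test_that("covariate correlations behave at the extremes", {
  s <- tibble::tibble(inl_um = rnorm(20, 42, 3))
  expect_equal(covariate_correlation(s, s$inl_um)$r, 1)
  expect_error(covariate_correlation(s, rep(5, 20)), "zero variance")
  set.seed(7)
  s2 <- tibble::tibble(inl_um = rnorm(1000, 42, 3))
  expect_lt(abs(covariate_correlation(s2, rnorm(1000, 50, 40))$r), 0.07)
})

test_that("cyst subgroup comparison recovers a thicker-INL stratum", {
  set.seed(11)
  n <- 36
  cyst <- c(rep(TRUE, 5), rep(FALSE, n - 5))
  s <- tibble::tibble(
    cyst = cyst,
    rnfl_um = rnorm(n, ifelse(cyst, 22.7, 28.6), 4),
    gclipl_um = rnorm(n, ifelse(cyst, 54.2, 71.7), 8),
    inl_um = rnorm(n, ifelse(cyst, 53.8, 41.2), 3))
  out <- subgroup_compare(s)
  inl <- out$comparison[out$comparison$layer == "inl_um", ]
  expect_gt(inl$mean1, inl$mean2)  # cyst group thicker
  expect_lt(inl$p, 0.05)
  expect_identical(out$n_cyst, 5L)
  # both correlations computed from the same immutable table
  expect_identical(out$corr_all,
                   pearson_r(s$gclipl_um, s$inl_um))
  expect_identical(out$corr_no_cysts,
                   pearson_r(s$gclipl_um[!cyst], s$inl_um[!cyst]))
})

test_that("identical strata are rarely declared different (type I)", {
  set.seed(5)
  rej <- replicate(200, {
    s <- tibble::tibble(cyst = c(rep(TRUE, 5), rep(FALSE, 31)),
                        rnfl_um = rnorm(36, 28, 4),
                        gclipl_um = rnorm(36, 70, 10),
                        inl_um = rnorm(36, 41, 3))
    subgroup_compare(s)$comparison$p[3] < 0.05
  })
  expect_gte(mean(!rej), 0.9)
})

test_that("subgroups of size one are refused", {
  s <- tibble::tibble(cyst = c(TRUE, rep(FALSE, 9)),
                      rnfl_um = rnorm(10), gclipl_um = rnorm(10),
                      inl_um = rnorm(10))
  expect_error(subgroup_compare(s), "insufficient")
})
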