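test_that("death-time reconstruction redistributes censored mass via KM", {
  unc <- survival_dataset(c(18, 20, 22), c(1, 1, 1), c(0, 0, 0))
  r <- reconstruct_death_times(unc)
  expect_equal(r$times, c(18, 20, 22))
  expect_equal(r$weights, c(1, 1, 1))

  mid <- survival_dataset(c(1, 2), c(1, 1), c(1, 0))
  r2 <- reconstruct_death_times(mid)
  expect_equal(r2$weights, c(1, 2), tolerance = 1e-12)

  expect_warning(r3 <- reconstruct_death_times(
    survival_dataset(c(1, 2), c(1, 0), c(0, 1))), "truncated")
  expect_equal(r3$weights, 1)
  expect_equal(r3$truncated, 1, tolerance = 1e-12)

  expect_error(reconstruct_death_times(
    suppressWarnings(survival_dataset(5, 0, 4))), "censored")
  set.seed(51)
  for (i in 1:20) {
    ds <- rand_ds()
    r <- suppressWarnings(reconstruct_death_times(ds))
    expect_lte(sum(r$weights), ds$n_total + 1e-9)
    expect_gte(min(r$weights), 1 - 1e-9)  # observed deaths keep weight 1
  }
})

test_that("survival-time F-test matches the closed-form F(2,2) example", {
  d1 <- survival_dataset(c(18, 20, 22), c(1, 1, 1), c(0, 0, 0), "tight")
  d2 <- survival_dataset(c(16, 20, 24), c(1, 1, 1), c(0, 0, 0), "wide")
  res <- survival_time_f_test(d1, d2)
  expect_equal(res$statistic, 0.25, tolerance = 1e-12)  # s2 = 4 vs 16
  expect_equal(res$p_value, 0.4, tolerance = 1e-10)     # F(2,2) cdf x/(1+x)
  expect_equal(res$df, c(2L, 2L))

  self <- survival_time_f_test(d1, d1)
  expect_equal(self$statistic, 1)
  expect_equal(self$p_value, 1)
})

test_that("F-test obeys reciprocal symmetry under group swap", {
  set.seed(52)
  for (i in 1:20) {
    ds1 <- rand_ds("a", min_deaths = 3); ds2 <- rand_ds("b", min_deaths = 3)
    r12 <- tryCatch(suppressWarnings(survival_time_f_test(ds1, ds2)),
                    error = function(e) NULL)
    if (is.null(r12)) next
    r21 <- suppressWarnings(survival_time_f_test(ds2, ds1))
    expect_equal(r12$statistic, 1 / r21$statistic, tolerance = 1e-10)
    expect_equal(r12$p_value, r21$p_value, tolerance = 1e-10)
  }
})

test_that("the Shapiro-Wilk gate flags non-normal lifespans", {
  set.seed(53)
  x <- round(rexp(60, 0.05)) + 1
  y <- round(rnorm(60, 20, 4))
  dx <- survassay:::from_subjects(x, rep(1L, 60), "exp")
  dy <- survassay:::from_subjects(y, rep(1L, 60), "norm")
  res <- suppressWarnings(survival_time_f_test(dx, dy))
  expect_match(res$warnings, "not\\s+applicable", all = FALSE)
  expect_lt(res$extras$shapiro_p[1], 0.01)
})

test_that("shapiro_wilk_test wraps the reference implementation", {
  res <- shapiro_wilk_test(c(1, 2, 3))
  expect_equal(res$statistic, 1, tolerance = 1e-7)
  set.seed(54)
  x <- rexp(50)
  expect_lt(shapiro_wilk_test(x)$p_value, 0.01)
  expect_equal(shapiro_wilk_test(x)$p_value, shapiro.test(x)$p.value)
  expect_error(shapiro_wilk_test(c(1, 2)), "at least 3")
  # level: normal samples rarely fall below the 0.01 gate
  set.seed(55)
  flags <- replicate(200, shapiro_wilk_test(rnorm(50))$p_value > 0.01)
  expect_gte(mean(flags), 0.95)
})

test_that("partial slopes are difference quotients, shift-invariant", {
  expect_equal(partial_slopes(hazard_curve(c(1, 2, 3), c(0, 1, 2))),
               c(1, 1))
  expect_equal(partial_slopes(hazard_curve(c(0, 2), c(0, 1))), 0.5)
  h <- hazard_curve(c(1, 3, 4, 7), c(0.1, 0.5, 1.2, 1.3))
  expect_equal(partial_slopes(h),
               partial_slopes(hazard_curve(h$time, h$y + 2.5)))
  expect_error(partial_slopes(hazard_curve(5, 1)), "2")
})

test_that("rank-sum on slope sets: exact enumeration and degeneracies", {
  rs <- survassay:::slopes_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p, 0.1, tolerance = 1e-12)
  expect_true(rs$exact)
  same <- survassay:::slopes_ranksum(1:6, 1:6)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  set.seed(56)
  for (i in 1:30) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    s1 <- round(runif(m, 0, 100), 3); s2 <- round(runif(n, 0, 100), 3)
    if (anyDuplicated(c(s1, s2))) next
    mine <- survassay:::slopes_ranksum(s1, s2)
    expect_equal(mine$p, ranksum_enum_oracle(s1, s2), tolerance = 1e-10)
  }
})

test_that("exact and normal-approximation rank-sum p agree for >= 10", {
  set.seed(57)
  for (i in 1:15) {
    s1 <- runif(10, 0, 1); s2 <- runif(10, 0, 1)
    p_exact <- wilcox.test(s1, s2, exact = TRUE)$p.value
    p_norm <- wilcox.test(s1, s2, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("partial-slopes rank-sum gates on six observed time points", {
  a <- simulate_lifespans(120, mean = 20, sd = 3, seed = 61, label = "a")
  b <- simulate_lifespans(120, mean = 20, sd = 3, seed = 62, label = "b")
  res <- suppressWarnings(partial_slopes_ranksum_test(a, b))
  expect_s3_class(res, "survassay_test")
  expect_gte(res$p_value, 0)

  # the last death time drops off the curve (S = 0 there), so keep one
  # censored straggler to retain all death times
  small1 <- survival_dataset(1:5, c(rep(2, 4), 0), c(rep(0, 4), 1), "s1")
  small2 <- survival_dataset(1:8, c(rep(2, 7), 0), c(rep(0, 7), 1), "s2")
  expect_error(partial_slopes_ranksum_test(small1, small2), "six")
  s6 <- survival_dataset(1:7, c(rep(2, 6), 0), c(rep(0, 6), 1), "s6")
  s7 <- survival_dataset(1:8, c(rep(2, 7), 0), c(rep(0, 7), 1), "s7")
  expect_match(suppressWarnings(partial_slopes_ranksum_test(s6, s7))$warnings,
               "low power", all = FALSE)
})

test_that("normalized Chow compares slopes only", {
  set.seed(58)
  t1 <- sort(runif(8, 0, 10)); y1 <- 1 * t1 + rnorm(8, 0, 0.05)
  t2 <- sort(runif(8, 0, 10)); y2 <- 3 * t2 + rnorm(8, 0, 0.05)
  h1 <- hazard_curve(t1, y1); h2 <- hazard_curve(t2, y2)
  res <- normalized_chow_test(h1, h2)
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 0.05)

  # vertical shifts are removed by centring
  shifted <- normalized_chow_test(h1, hazard_curve(t1, y1 + 4))
  expect_lt(shifted$statistic, 1e-9)
  expect_equal(shifted$p_value, 1, tolerance = 1e-6)
  # ... but the un-normalized Chow test is sensitive to the same shift
  expect_gt(chow_test(h1, hazard_curve(t1, y1 + 4))$statistic, 1)

  same <- normalized_chow_test(h1, h1)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
})

test_that("normalized Chow is invariant under independent vertical shifts", {
  set.seed(59)
  t1 <- sort(runif(7, 0, 10)); y1 <- 0.6 * t1 + rnorm(7, 0, 0.2)
  t2 <- sort(runif(9, 0, 10)); y2 <- 0.9 * t2 + rnorm(9, 0, 0.2)
  base <- normalized_chow_test(hazard_curve(t1, y1), hazard_curve(t2, y2))
  moved <- normalized_chow_test(hazard_curve(t1, y1 - 3),
                                hazard_curve(t2, y2 + 11))
  expect_equal(base$statistic, moved$statistic, tolerance = 1e-9)
})
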