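test_that("KS statistic is the supremum gap between KM curves", {
  g1 <- survival_dataset(1, 1, 0, "g1")
  g2 <- survival_dataset(2, 1, 0, "g2")
  res <- ks_test(g1, g2, n_perm = 200, seed = 1)
  expect_equal(res$statistic, 1)

  ds <- survival_dataset(c(4, 9, 11), c(1, 2, 1), c(0, 1, 0))
  self <- ks_test(ds, ds, n_perm = 200, seed = 1)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  expect_error(ks_test(g1, g2, n_perm = 50), "configuration")
})

test_that("tied deaths trigger the applicability warning", {
  a <- survival_dataset(c(3, 5), c(2, 1), c(0, 0), "a")
  b <- survival_dataset(c(4, 6), c(1, 1), c(0, 0), "b")
  res <- ks_test(a, b, n_perm = 150, seed = 2)
  expect_match(res$warnings, "tied", all = FALSE)
  nt <- survival_dataset(c(1, 2), c(1, 1), c(0, 0), "nt")
  nt2 <- survival_dataset(c(3, 4), c(1, 1), c(0, 0), "nt2")
  expect_length(ks_test(nt, nt2, n_perm = 150, seed = 2)$warnings, 0)
})

test_that("KS permutation p converges to the enumeration oracle", {
  set.seed(41)
  for (i in 1:5) {
    ds1 <- rand_ds("a", max_t = 6); ds2 <- rand_ds("b", max_t = 6)
    if (ds1$n_total + ds2$n_total > 8 || ds1$n_total + ds2$n_total < 3) next
    exact <- ks_enum_oracle(ds1, ds2)
    approx <- ks_test(ds1, ds2, n_perm = 4000, seed = i)$p_value
    expect_equal(approx, exact, tolerance = 0.035)
  }
  # fixed small case so the comparison always runs at least once
  ds1 <- survival_dataset(c(2, 5), c(1, 1), c(1, 0), "a")
  ds2 <- survival_dataset(c(4, 7), c(2, 1), c(0, 1), "b")
  expect_equal(ks_test(ds1, ds2, n_perm = 6000, seed = 9)$p_value,
               ks_enum_oracle(ds1, ds2), tolerance = 0.03)
})

test_that("KS is invariant under swapping the group labels", {
  set.seed(42)
  for (i in 1:10) {
    ds1 <- rand_ds("a"); ds2 <- rand_ds("b")
    r12 <- suppressWarnings(ks_test(ds1, ds2, n_perm = 300, seed = 7))
    r21 <- suppressWarnings(ks_test(ds2, ds1, n_perm = 300, seed = 7))
    expect_equal(r12$statistic, r21$statistic, tolerance = 1e-12)
    expect_equal(r12$p_value, r21$p_value, tolerance = 1e-12)
  }
})

test_that("smooth test: identical groups give p = 1 and minimal dimension", {
  ds <- survival_dataset(c(2, 5, 7, 9), c(1, 2, 1, 1), c(0, 1, 0, 0))
  res <- neyman_smooth_test(ds, ds, n_perm = 200, seed = 3)
  expect_equal(res$p_value, 1)
  expect_equal(res$extras$dimension, 1L)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_error(neyman_smooth_test(ds, ds, max_dim = 0), "configuration")
})

test_that("smooth test dimension 1 spans the log-rank direction", {
  set.seed(43)
  for (i in 1:15) {
    ds1 <- rand_ds("a", min_deaths = 3); ds2 <- rand_ds("b", min_deaths = 3)
    res <- suppressWarnings(
      neyman_smooth_test(ds1, ds2, max_dim = 1, n_perm = 150, seed = 1,
                         p_method = "asymptotic"))
    expect_equal(res$statistic, logrank_test(ds1, ds2)$statistic,
                 tolerance = 1e-8)
  }
})

test_that("selected dimension tracks the type of difference", {
  set.seed(44)
  dims_ph <- integer(0); dims_cross <- integer(0)
  for (i in 1:60) {
    # constant hazard ratio 3
    t1 <- ceiling(rexp(150, 0.03)); t2 <- ceiling(rexp(150, 0.09))
    d_ph <- suppressWarnings(neyman_smooth_test(
      survassay:::from_subjects(t1, rep(1L, 150), "a"),
      survassay:::from_subjects(t2, rep(1L, 150), "b"),
      p_method = "asymptotic"))$extras$dimension
    dims_ph <- c(dims_ph, d_ph)
    # crossing hazards: equal means, different spread
    a <- simulate_lifespans(150, mean = 20, sd = 2, seed = 4000 + i)
    b <- simulate_lifespans(150, mean = 20, sd = 4, seed = 8000 + i)
    d_cr <- suppressWarnings(neyman_smooth_test(
      a, b, p_method = "asymptotic"))$extras$dimension
    dims_cross <- c(dims_cross, d_cr)
  }
  modal <- function(x) as.integer(names(which.max(table(x))))
  expect_equal(modal(dims_ph), 1L)
  expect_gte(modal(dims_cross), 2L)
})

test_that("Chow F matches the worked example and the lm oracle", {
  h1 <- hazard_curve(c(1, 2, 3), c(1, 2, 2))
  h2 <- hazard_curve(c(1, 2, 3), c(2, 3, 5))
  res <- chow_test(h1, h2, k = 2)
  expect_equal(res$statistic, 15.5, tolerance = 1e-10)
  expect_equal(res$p_value, pf(15.5, 2, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$extras$rss1, 1 / 6, tolerance = 1e-12)
  expect_equal(res$extras$rss_pooled, 5.5, tolerance = 1e-10)

  expect_error(chow_test(h1, h2, k = 3), "smaller k")

  same <- chow_test(h1, h1, k = 1)
  expect_lt(same$statistic, 1e-6)
  expect_equal(same$p_value, 1, tolerance = 1e-6)

  set.seed(45)
  for (i in 1:25) {
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    t1 <- sort(runif(n1, 0, 10)); t2 <- sort(runif(n2, 0, 10))
    y1 <- 0.5 * t1 + rnorm(n1, 0, 0.3); y2 <- 0.8 * t2 + rnorm(n2, 0, 0.3)
    mine <- chow_test(hazard_curve(t1, y1), hazard_curve(t2, y2), k = 3)
    expect_equal(mine$statistic, chow_oracle(t1, y1, t2, y2, 3),
                 tolerance = 1e-8)
  }
})

test_that("Chow F is invariant under a common affine time transform", {
  set.seed(46)
  t1 <- sort(runif(6, 0, 10)); y1 <- 0.4 * t1 + rnorm(6, 0, 0.2)
  t2 <- sort(runif(7, 0, 10)); y2 <- 0.7 * t2 + rnorm(7, 0, 0.2)
  f0 <- chow_test(hazard_curve(t1, y1), hazard_curve(t2, y2))$statistic
  f1 <- chow_test(hazard_curve(3 * t1 + 5, y1),
                  hazard_curve(3 * t2 + 5, y2))$statistic
  expect_equal(f0, f1, tolerance = 1e-9)
})
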