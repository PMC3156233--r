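test_that("log-rank matches hand computation on the two-subject example", {
  g1 <- survival_dataset(1, 1, 0, "g1")
  g2 <- survival_dataset(2, 1, 0, "g2")
  res <- logrank_test(g1, g2)
  expect_equal(res$statistic, 1.0, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(1, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("identical groups give statistic 0 and p = 1", {
  ds <- survival_dataset(c(5, 8, 12), c(2, 1, 2), c(0, 1, 0))
  res <- logrank_test(ds, ds)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
})

test_that("log-rank agrees with survdiff and a loop oracle", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (i in 1:60) {
    ds1 <- rand_ds("a"); ds2 <- rand_ds("b")
    mine <- logrank_test(ds1, ds2)$statistic
    expect_equal(mine, logrank_oracle(ds1, ds2), tolerance = 1e-10)
    s <- surv_frame(ds1, ds2)
    sd <- survival::survdiff(survival::Surv(time, status) ~ group,
                             data = s)
    expect_equal(mine, unname(sd$chisq), tolerance = 1e-8)
  }
})

test_that("weighted log-rank reduces to log-rank at rho = gamma = 0", {
  set.seed(32)
  for (i in 1:50) {
    ds1 <- rand_ds("a"); ds2 <- rand_ds("b")
    expect_equal(weighted_logrank_test(ds1, ds2, 0, 0)$statistic,
                 logrank_test(ds1, ds2)$statistic, tolerance = 1e-14)
  }
})

test_that("Fleming-Harrington weights follow the left-continuous KM", {
  g1 <- survival_dataset(1, 1, 0, "g1")
  g2 <- survival_dataset(2, 1, 0, "g2")
  expect_equal(weighted_logrank_test(g1, g2, rho = 1, gamma = 0)$statistic,
               1.0, tolerance = 1e-12)
  expect_error(weighted_logrank_test(g1, g2, rho = 0, gamma = 1),
               "degenerate weights")
  set.seed(33)
  for (i in 1:25) {
    ds1 <- rand_ds("a", min_deaths = 2); ds2 <- rand_ds("b", min_deaths = 2)
    for (par in list(c(1, 0), c(0, 1), c(1, 1))) {
      mine <- tryCatch(
        weighted_logrank_test(ds1, ds2, par[1], par[2])$statistic,
        error = function(e) NA_real_)
      if (is.na(mine)) next
      expect_equal(mine, logrank_oracle(ds1, ds2, par[1], par[2]),
                   tolerance = 1e-10)
    }
  }
})

test_that("Fisher's exact test enumerates the hypergeometric tail", {
  x <- survival_dataset(c(5, 30), c(2, 8), c(0, 0), "x")
  y <- survival_dataset(c(5, 30), c(8, 2), c(0, 0), "y")
  res <- fisher_exact_at_mortality(x, y, mortality_fraction = 0.5)
  # table at t* = 5: alive 8/2, dead 2/8
  expect_equal(res$p_value, fisher_oracle(8, 2, 2, 8), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0230, tolerance = 1e-3)
  expect_equal(res$extras$t_star, 5)

  ds <- survival_dataset(c(3, 9), c(2, 3), c(1, 0), "same")
  expect_equal(fisher_exact_at_mortality(ds, ds, 0.5)$p_value, 1.0)

  # 1 vs 1 subjects (table 1,0 / 0,1): both tables have probability 1/2
  a <- survival_dataset(3, 1, 0, "a")
  b <- survival_dataset(1, 1, 0, "b")
  expect_equal(fisher_exact_at_mortality(a, b, 0.5)$p_value, 1.0)
})

test_that("Fisher p equals fisher.test and the enumeration oracle", {
  set.seed(34)
  for (i in 1:80) {
    m1 <- sample(2:15, 1); m2 <- sample(2:15, 1)
    A <- sample(seq_len(min(10, m1 + m2 - 1)), 1)
    rng <- max(0, A - m2):min(A, m1)
    a <- rng[sample.int(length(rng), 1)]
    mine <- survassay:::fisher_two_sided(a, m1, m2, A)
    expect_equal(mine, fisher_oracle(a, A - a, m1 - a, m2 - (A - a)),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(c(a, m1 - a, A - a, m2 - (A - a)), 2))
    expect_equal(mine, ft$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher table excludes subjects censored before t*", {
  x <- survival_dataset(c(2, 5, 30), c(0, 2, 8), c(3, 0, 0), "x")
  y <- survival_dataset(c(5, 30), c(8, 2), c(0, 0), "y")
  res <- fisher_exact_at_mortality(x, y, mortality_fraction = 0.4)
  expect_equal(res$extras$n_excluded, 3)
  expect_equal(sum(res$extras$table), 20)
  # pooled mortality plateaus at 0.75 because two subjects are censored
  # after the last death
  u <- survival_dataset(c(1, 5), c(3, 0), c(0, 2), "u")
  v <- survival_dataset(2, 3, 0, "v")
  expect_error(fisher_exact_at_mortality(u, v, mortality_fraction = 1),
               "lower")
})

test_that("location tests are symmetric under group swap", {
  set.seed(35)
  for (i in 1:20) {
    ds1 <- rand_ds("a"); ds2 <- rand_ds("b")
    expect_equal(logrank_test(ds1, ds2)$p_value,
                 logrank_test(ds2, ds1)$p_value, tolerance = 1e-12)
    expect_equal(weighted_logrank_test(ds1, ds2, 1, 0)$p_value,
                 weighted_logrank_test(ds2, ds1, 1, 0)$p_value,
                 tolerance = 1e-12)
    f12 <- tryCatch(fisher_exact_at_mortality(ds1, ds2, 0.5)$p_value,
                    error = function(e) NA)
    f21 <- tryCatch(fisher_exact_at_mortality(ds2, ds1, 0.5)$p_value,
                    error = function(e) NA)
    expect_equal(f12, f21, tolerance = 1e-12)
  }
})

test_that("log-rank outpowers late-weighted FH under proportional hazards", {
  set.seed(36)
  wins_lr <- 0; wins_fh <- 0
  for (i in 1:60) {
    t1 <- ceiling(rexp(100, 0.05)); t2 <- ceiling(rexp(100, 0.10))
    ds1 <- survassay:::from_subjects(t1, rep(1L, 100), "a")
    ds2 <- survassay:::from_subjects(t2, rep(1L, 100), "b")
    wins_lr <- wins_lr + (logrank_test(ds1, ds2)$p_value < 0.05)
    wins_fh <- wins_fh +
      (weighted_logrank_test(ds1, ds2, 0, 2)$p_value < 0.05)
  }
  expect_gt(wins_lr, wins_fh)
})
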