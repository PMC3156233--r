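#' Reconstruct a weighted death-time sample from censored data
#'
#' Turns a (possibly censored) grouped survival dataset into a weighted
#' sample of death times suitable for moment-based comparisons. Every
#' observed death contributes its time with weight 1. Every censored
#' subject is redistributed over the death times after its censoring
#' time, proportionally to the Kaplan-Meier conditional probability of
#' dying in each later interval,
#' \eqn{w_{c,j} = (S(t_{j-1}) - S(t_j)) / S(c)} for death times
#' \eqn{t_j > c}. Conditional mass beyond the last observed death time
#' cannot be placed and is truncated with a warning, so the weights can
#' sum to less than the number of subjects.
#'
#' @param ds a [survival_dataset] with at least one death.
#' @return A list with `times` (distinct death times), `weights`
#'   (estimated deaths at each), `truncated` (mass dropped beyond the
#'   last death time) and `label`.
#' @examples
#' ds <- survival_dataset(c(1, 2), deaths = c(1, 1), censored = c(1, 0))
#' reconstruct_death_times(ds)$weights  # 1, 2
#' @export
reconstruct_death_times <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (sum(ds$deaths) == 0L)
    stop("all subjects are censored; death times cannot be reconstructed")
  km <- km_estimate(ds)
  jumps <- c(1, head(km$surv, -1L)) - km$surv     # KM mass at each death time
  w <- as.numeric(km$n_event)
  truncated <- 0
  cens_t <- rep(ds$time, ds$censored)
  for (cc in cens_t) {
    s_c <- km_surv_at(km, cc)
    later <- km$time > cc
    if (s_c <= 0) next                     # no mass left to redistribute
    mass <- jumps[later] / s_c
    w[later] <- w[later] + mass
    truncated <- truncated + (1 - sum(mass))
  }
  if (truncated > 1e-8)
    warning(sprintf(paste("%.3f subjects' worth of censored mass falls",
                          "beyond the last death time and was truncated"),
                    truncated))
  list(times = km$time, weights = w, truncated = truncated,
       label = ds$label)
}

weighted_var <- function(x, w) {
  W <- sum(w)
  m <- sum(w * x) / W
  list(mean = m, var = sum(w * (x - m)^2) / (W - 1), W = W)
}

#' Survival-time F-test for equal lifespan variance
#'
#' Compares the variances of two lifespan distributions through the
#' variance ratio of their (reconstructed) death-time samples. Censored
#' subjects are redistributed over later death times via
#' [reconstruct_death_times()]; the weighted sample variances
#' \eqn{s_1^2, s_2^2} form \eqn{F = s_1^2 / s_2^2}, referred two-sidedly
#' to the F distribution with `round(sum(weights)) - 1` degrees of
#' freedom per group. The test assumes normally distributed survival
#' times: each reconstructed sample is checked with the Shapiro-Wilk
#' test, and when either normality p-value falls below
#' `normality_alpha` a warning is attached because the F-test is then
#' not applicable.
#'
#' @inheritParams logrank_test
#' @param normality_alpha Shapiro-Wilk gate threshold (default 0.01).
#' @return A [test_result]; the statistic is the variance ratio F,
#'   extras record both variances and the Shapiro-Wilk p-values.
#' @export
survival_time_f_test <- function(ds1, ds2, normality_alpha = 0.01) {
  check_two_sample(ds1, ds2)
  r1 <- reconstruct_death_times(ds1)
  r2 <- reconstruct_death_times(ds2)
  v1 <- weighted_var(r1$times, r1$weights)
  v2 <- weighted_var(r2$times, r2$weights)
  nu1 <- round(v1$W) - 1L; nu2 <- round(v2$W) - 1L
  if (nu1 <= 0 || nu2 <= 0)
    stop("not enough effective deaths for a variance ratio")
  if (v2$var <= 0 || v1$var < 0)
    stop("degenerate variance (all reconstructed deaths at one time)")
  Fstat <- v1$var / v2$var
  p <- 2 * min(pf(Fstat, nu1, nu2), pf(Fstat, nu1, nu2, lower.tail = FALSE))
  p <- min(1, p)

  warns <- character(0)
  sw_p <- vapply(list(r1, r2), function(r) {
    samp <- rep(r$times, times = pmax(0L, round(r$weights)))
    if (length(samp) < 3L || length(unique(samp)) < 2L) return(NA_real_)
    if (length(samp) > 5000L)
      samp <- sort(samp)[round(seq(1L, length(samp), length.out = 5000L))]
    tryCatch(stats::shapiro.test(samp)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  if (any(!is.na(sw_p) & sw_p < normality_alpha))
    warns <- sprintf(paste("Shapiro-Wilk normality p-value below %g for",
                           "at least one group; F-test results are not",
                           "applicable"), normality_alpha)

  test_result("survival-time F", Fstat, p, df = c(nu1, nu2),
              warnings = warns,
              extras = list(var1 = v1$var, var2 = v2$var,
                            shapiro_p = sw_p,
                            labels = c(ds1$label, ds2$label)))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning the package's
#' common [test_result] container. Sample size must be between 3 and
#' 5000.
#'
#' @param sample numeric vector.
#' @return A [test_result] with the W statistic.
#' @export
shapiro_wilk_test <- function(sample) {
  if (length(sample) < 3L)
    stop("Shapiro-Wilk test needs at least 3 observations")
  sw <- stats::shapiro.test(sample)
  test_result("shapiro-wilk", sw$statistic, sw$p.value)
}

#' Partial slopes of a log cumulative hazard curve
#'
#' The partial slope between neighbouring curve points is the change in
#' log cumulative hazard divided by the change in time,
#' \eqn{D_i = (y_{i+1} - y_i) / (t_{i+1} - t_i)}. These difference
#' quotients are the unit of comparison for the partial-slopes rank-sum
#' test; they are invariant under vertical shifts of the curve.
#'
#' @param h a [hazard_curve] with at least 2 points.
#' @return Numeric vector of `length(points) - 1` slopes.
#' @export
partial_slopes <- function(h) {
  stopifnot(inherits(h, "hazard_curve"))
  if (length(h$time) < 2L)
    stop("at least 2 curve points are needed for partial slopes")
  dt <- diff(h$time)
  if (any(dt == 0)) stop("duplicate time points give a zero denominator")
  diff(h$y) / dt
}

# Two-sided Wilcoxon rank-sum on two slope sets: exact null by
# enumeration when the combined count is <= 20 with no ties, otherwise
# normal approximation with tie-corrected variance and continuity
# correction. Returns the standardized statistic and p-value.
slopes_ranksum <- function(s1, s2) {
  m <- length(s1); n <- length(s2); N <- m + n
  pooled <- c(s1, s2)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  varU <- m * n / 12 * ((N + 1) - tie_term)
  z <- if (varU > 0) (U - m * n / 2) / sqrt(varU) else 0
  exact <- N <= 20 && !any(ties > 1)
  p <- suppressWarnings(
    wilcox.test(s1, s2, exact = exact, correct = TRUE)$p.value)
  list(statistic = z, p = p, U = U, exact = exact)
}

#' Partial-slopes rank-sum test for lifespan variance
#'
#' Nonparametric comparison of the steepness profiles of two log
#' cumulative hazard curves: the sets of partial slopes of each curve
#' (see [partial_slopes()]) are compared with a two-sided Wilcoxon
#' rank-sum (Mann-Whitney) test. Slopes being a per-interval quantity,
#' the number of observed death times — not the number of subjects —
#' drives the power; at least six time points per curve are required,
#' and a low-power warning is attached for six to ten.
#'
#' The exact null distribution is used when the combined slope count is
#' at most 20 with no ties; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is applied.
#'
#' @inheritParams logrank_test
#' @param estimator hazard estimator passed to [log_cumulative_hazard()].
#' @return A [test_result]; the statistic is the standardized rank-sum,
#'   extras record the Mann-Whitney `U`, the slope counts and whether
#'   the exact distribution was used.
#' @export
partial_slopes_ranksum_test <- function(ds1, ds2,
                                        estimator = c("km",
                                                      "nelson-aalen")) {
  check_two_sample(ds1, ds2)
  estimator <- match.arg(estimator)
  h1 <- log_cumulative_hazard(km_estimate(ds1), estimator)
  h2 <- log_cumulative_hazard(km_estimate(ds2), estimator)
  np <- c(length(h1$time), length(h2$time))
  if (any(np < 6L))
    stop("at least six observed time points per group are needed for ",
         "the partial-slopes rank-sum test (got ", np[1L], " and ",
         np[2L], ")")
  warns <- character(0)
  if (any(np <= 10L))
    warns <- paste("only", min(np), "time points in one group;",
                   "the rank-sum comparison has low power")
  rs <- slopes_ranksum(partial_slopes(h1), partial_slopes(h2))
  test_result("partial-slopes rank-sum", rs$statistic, rs$p,
              warnings = warns,
              extras = list(U = rs$U, exact = rs$exact,
                            n_slopes = np - 1L,
                            labels = c(ds1$label, ds2$label)))
}

#' Normalized Chow test for lifespan variance
#'
#' Variant of [chow_test()] that compares only the slopes of two log
#' cumulative hazard regressions. Each curve's times and values are
#' centred to mean zero, so each linear regression passes through the
#' origin and the y-intercept drops out of the comparison; the pooled
#' fit uses the union of the centred points. The Chow F statistic is
#' then formed with parameter count `k`, which defaults to 1 because
#' the slope is the only parameter fitted after centring.
#'
#' @inheritParams chow_test
#' @param k parameter count; default 1 (slope only).
#' @return A [test_result] with the F statistic and degrees of freedom.
#' @export
normalized_chow_test <- function(h1, h2, k = 1) {
  stopifnot(inherits(h1, "hazard_curve"), inherits(h2, "hazard_curve"))
  if (length(h1$time) < 2L || length(h2$time) < 2L)
    stop("each hazard curve needs at least 2 points")
  N1 <- length(h1$time); N2 <- length(h2$time)
  if (N1 + N2 <= 2 * k)
    stop("too few points for k = ", k,
         ": need N1 + N2 > 2k; choose a smaller k")
  centre <- function(h) list(t = h$time - mean(h$time),
                             y = h$y - mean(h$y))
  c1 <- centre(h1); c2 <- centre(h2)
  rss_origin <- function(t, y) {
    b <- sum(t * y) / sum(t * t)
    sum((y - b * t)^2)
  }
  rss1 <- rss_origin(c1$t, c1$y)
  rss2 <- rss_origin(c2$t, c2$y)
  rssp <- rss_origin(c(c1$t, c2$t), c(c1$y, c2$y))
  if (rss1 + rss2 <= 0)
    stop("degenerate regression: both centred curves are perfectly ",
         "collinear")
  Fstat <- max(0, ((rssp - rss1 - rss2) / k) /
                    ((rss1 + rss2) / (N1 + N2 - 2 * k)))
  test_result("normalized chow", Fstat,
              pf(Fstat, k, N1 + N2 - 2 * k, lower.tail = FALSE),
              df = c(k, N1 + N2 - 2 * k),
              extras = list(rss1 = rss1, rss2 = rss2, rss_pooled = rssp,
                            k = k))
}
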