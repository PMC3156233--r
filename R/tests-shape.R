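#' Two-sample Kolmogorov-Smirnov test for censored lifespan data
#'
#' Compares the whole shape of two survival curves through the supremum
#' distance \eqn{D = \sup_t |\hat S_1(t) - \hat S_2(t)|} between the
#' Kaplan-Meier estimates over the pooled death times. Unlike the
#' log-rank test it retains power when the hazard functions cross. The
#' p-value is obtained by permuting group labels of the subject-level
#' records (the permutation distribution is exact up to Monte Carlo
#' error, and remains valid under tied observations); a warning is still
#' issued when ties are present because the classical asymptotic theory
#' for the censored KS statistic assumes continuous data.
#'
#' @inheritParams logrank_test
#' @param n_perm number of label permutations (at least 100).
#' @param seed optional integer seed for the permutation draw; the
#'   caller's RNG state is preserved.
#' @return A [test_result]; the statistic is `D`, extras record `D`,
#'   `n_perm` and whether tied deaths were seen.
#' @export
ks_test <- function(ds1, ds2, n_perm = 2000, seed = NULL) {
  check_two_sample(ds1, ds2)
  if (n_perm < 100)
    stop("configuration error: 'n_perm' must be at least 100")
  warns <- character(0)
  if (has_tied_deaths(ds1, ds2))
    warns <- paste("tied observations present; the asymptotic KS",
                   "distribution does not apply (permutation p-value",
                   "reported)")
  st <- perm_structure(ds1, ds2)
  D_obs <- perm_ks_stat(st, matrix(st$obs1, ncol = 1))
  D_perm <- with_seed(seed, {
    A <- perm_tables(st, n_perm)
    perm_ks_stat(st, A)
  })
  test_result("kolmogorov-smirnov", D_obs, perm_pvalue(D_obs, D_perm),
              warnings = warns,
              extras = list(D = D_obs, n_perm = n_perm,
                            tied = length(warns) > 0,
                            labels = c(ds1$label, ds2$label)))
}

# Legendre polynomials P_0 .. P_{dmax-1} evaluated at x in [-1, 1];
# returns length(x) x dmax matrix (columns ordered by degree).
legendre_basis <- function(x, dmax) {
  P <- matrix(0, length(x), dmax)
  P[, 1L] <- 1
  if (dmax >= 2L) P[, 2L] <- x
  if (dmax >= 3L) for (k in 2:(dmax - 1L))
    P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
  P
}

# Data-driven smooth statistics for one or many permutations.
# Returns list(stat, dim) vectors of length B.
neyman_stats <- function(st, A, Psi, penalty) {
  cnt <- perm_counts(st, A)
  n1 <- cnt$n1; d1 <- cnt$d1
  n <- st$n_pool; d <- st$d_pool
  e1 <- d * n1 / n
  v <- d * (n1 / n) * ((n - n1) / n) * (n - d) / pmax(n - 1, 1)
  v[n <= 1, ] <- 0
  U <- crossprod(Psi, d1 - e1)                       # dmax x B
  dmax <- ncol(Psi)
  pairs <- which(upper.tri(diag(dmax), diag = TRUE), arr.ind = TRUE)
  W <- Psi[, pairs[, 1L], drop = FALSE] * Psi[, pairs[, 2L], drop = FALSE]
  SigAll <- crossprod(W, v)                          # npairs x B
  B <- ncol(U)
  stat <- numeric(B); dim_sel <- integer(B)
  Sig <- matrix(0, dmax, dmax)
  for (b in seq_len(B)) {
    Sig[cbind(pairs[, 1L], pairs[, 2L])] <- SigAll[, b]
    Sig[cbind(pairs[, 2L], pairs[, 1L])] <- SigAll[, b]
    Td <- rep(NA_real_, dmax)
    for (dd in seq_len(dmax)) {
      Td[dd] <- tryCatch(
        drop(crossprod(U[seq_len(dd), b],
                       solve(Sig[seq_len(dd), seq_len(dd), drop = FALSE],
                             U[seq_len(dd), b]))),
        error = function(e) NA_real_)
    }
    ok <- which(is.finite(Td))
    if (!length(ok)) { stat[b] <- 0; dim_sel[b] <- 1L; next }
    sel <- ok[which.max(Td[ok] - ok * penalty)]
    stat[b] <- Td[sel]; dim_sel[b] <- sel
  }
  list(stat = stat, dim = dim_sel)
}

#' Neyman's smooth test for two survival samples
#'
#' Score test of survival-curve equality against smooth alternatives in
#' which the log hazard ratio is a low-order Legendre polynomial in the
#' (rescaled) pooled cumulative-hazard time transform. Score statistics
#' are computed for nested dimensions `1..max_dim`; the reported
#' dimension is chosen by Schwarz's (BIC-penalised) rule,
#' \eqn{d^* = \arg\max_d (T_d - d \log n_{events})}. Dimension 1 spans
#' the constant-hazard-ratio (log-rank) direction, so a selected `d* = 1`
#' suggests a constant hazard ratio, `d* = 2` a monotone change, and
#' `d* = 3` a convex/concave (e.g. crossing) difference. The default
#' p-value is by label permutation of the full data-driven statistic;
#' `p_method = "asymptotic"` uses the chi-square(1) approximation for
#' Schwarz-selected smooth statistics.
#'
#' @inheritParams ks_test
#' @param max_dim largest smooth-alternative dimension (>= 1); reduced
#'   with a warning when there are fewer pooled death times.
#' @param p_method `"permutation"` (default) or `"asymptotic"`.
#' @return A [test_result]; extras record the selected `dimension`, its
#'   `interpretation`, and the score statistics of every dimension.
#' @export
neyman_smooth_test <- function(ds1, ds2, max_dim = 5, n_perm = 2000,
                               seed = NULL,
                               p_method = c("permutation", "asymptotic")) {
  check_two_sample(ds1, ds2)
  p_method <- match.arg(p_method)
  if (max_dim < 1)
    stop("configuration error: 'max_dim' must be at least 1")
  if (p_method == "permutation" && n_perm < 100)
    stop("configuration error: 'n_perm' must be at least 100")
  warns <- character(0)
  if (has_tied_deaths(ds1, ds2))
    warns <- c(warns,
               paste("tied observations present; the smooth-test theory",
                     "assumes continuous data (permutation p-value",
                     "reported)"))
  st <- perm_structure(ds1, ds2)
  n_times <- length(st$tt)
  if (n_times < max_dim) {
    warns <- c(warns, sprintf(
      "only %d pooled death times; reducing max_dim from %d to %d",
      n_times, max_dim, n_times))
    max_dim <- n_times
  }
  # time transform: pooled Nelson-Aalen cumulative hazard mapped to [-1,1]
  Ahat <- cumsum(st$d_pool / st$n_pool)
  x <- if (max(Ahat) > 0) 2 * Ahat / max(Ahat) - 1 else rep(0, n_times)
  Psi <- legendre_basis(x, max_dim)
  penalty <- log(max(sum(st$d_pool), 2))

  obs <- neyman_stats(st, matrix(st$obs1, ncol = 1), Psi, penalty)
  if (p_method == "permutation") {
    perm <- with_seed(seed, {
      A <- perm_tables(st, n_perm)
      neyman_stats(st, A, Psi, penalty)
    })
    p <- perm_pvalue(obs$stat, perm$stat)
  } else {
    p <- pchisq(obs$stat, df = 1, lower.tail = FALSE)
  }
  interp <- c("constant hazard ratio", "monotonic difference",
              "convex or concave difference")
  d_star <- obs$dim
  test_result("neyman-smooth", obs$stat, p, warnings = warns,
              extras = list(
                dimension = d_star,
                interpretation = if (d_star <= 3) interp[d_star]
                                 else "higher-order difference",
                p_method = p_method,
                labels = c(ds1$label, ds2$label)))
}

#' Chow test on log cumulative hazard regressions
#'
#' Tests whether two log cumulative hazard curves share one linear
#' time trend. Least-squares lines are fitted to each curve and to the
#' pooled points; with residual sums of squares \eqn{RSS_1, RSS_2}
#' (separate fits) and \eqn{RSS_p} (pooled fit), the statistic
#' \deqn{F = \frac{(RSS_p - RSS_1 - RSS_2)/k}
#'   {(RSS_1 + RSS_2)/(N_1 + N_2 - 2k)}}
#' is referred to the \eqn{F(k, N_1 + N_2 - 2k)} distribution. The
#' parameter count defaults to `k = 3`, the convention used by lifespan
#' web tools for this comparison (a slope-and-intercept line has 2 mean
#' parameters; the extra count can be read as the error variance); `k`
#' is configurable.
#'
#' @param h1,h2 [hazard_curve] objects with at least 2 points each.
#' @param k parameter count for the numerator degrees of freedom.
#' @return A [test_result] with the F statistic and degrees of freedom;
#'   extras record the three residual sums of squares.
#' @export
chow_test <- function(h1, h2, k = 3) {
  stopifnot(inherits(h1, "hazard_curve"), inherits(h2, "hazard_curve"))
  if (length(h1$time) < 2L || length(h2$time) < 2L)
    stop("each hazard curve needs at least 2 points")
  N1 <- length(h1$time); N2 <- length(h2$time)
  if (N1 + N2 <= 2 * k)
    stop("too few points for k = ", k,
         ": need N1 + N2 > 2k; choose a smaller k")
  rss_line <- function(t, y) {
    f <- stats::lm.fit(cbind(1, t), y)
    sum(f$residuals^2)
  }
  rss1 <- rss_line(h1$time, h1$y)
  rss2 <- rss_line(h2$time, h2$y)
  rssp <- rss_line(c(h1$time, h2$time), c(h1$y, h2$y))
  if (rss1 + rss2 <= 0)
    stop("degenerate regression: both curves are perfectly collinear")
  Fstat <- max(0, ((rssp - rss1 - rss2) / k) /
                    ((rss1 + rss2) / (N1 + N2 - 2 * k)))
  test_result("chow", Fstat,
              pf(Fstat, k, N1 + N2 - 2 * k, lower.tail = FALSE),
              df = c(k, N1 + N2 - 2 * k),
              extras = list(rss1 = rss1, rss2 = rss2, rss_pooled = rssp,
                            k = k))
}
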