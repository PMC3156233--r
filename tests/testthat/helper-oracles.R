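# Fixture generators and independent brute-force oracles. The oracles
# deliberately use naive loops (or the survival package) rather than any
# code path from the package under test.

# Random small grouped dataset; uses the ambient RNG stream.
rand_ds <- function(label = "x", max_t = 15, censor = TRUE,
                    min_deaths = 1) {
  repeat {
    k <- sample(2:6, 1)
    tt <- sort(sample(seq_len(max_t), k))
    d <- rpois(k, 1.2)
    cns <- if (censor) rpois(k, 0.6) else rep(0L, k)
    if (sum(d) < min_deaths) next
    keep <- d + cns > 0
    if (sum(keep) == 0) next
    return(survival_dataset(tt[keep], d[keep], cns[keep], label = label))
  }
}

# Subject-level data frame with a group column, for the survival package.
surv_frame <- function(ds1, ds2) {
  s1 <- survassay:::subject_level(ds1)
  s2 <- survassay:::subject_level(ds2)
  rbind(cbind(s1, group = 1L), cbind(s2, group = 2L))
}

# Naive product-limit oracle: walks subjects one time at a time.
km_oracle <- function(ds) {
  s <- survassay:::subject_level(ds)
  times <- sort(unique(s$time[s$status == 1]))
  surv <- numeric(length(times))
  gw <- numeric(length(times))
  S <- 1; gsum <- 0
  for (j in seq_along(times)) {
    t <- times[j]
    n <- sum(s$time >= t)
    d <- sum(s$time == t & s$status == 1)
    S <- S * (1 - d / n)
    gsum <- gsum + if (n > d) d / (n * (n - d)) else Inf
    surv[j] <- S
    gw[j] <- if (S == 0) 0 else S^2 * gsum
  }
  list(time = times, surv = surv, greenwood_var = gw)
}

# Hand-rolled (weighted) log-rank oracle over pooled death times.
logrank_oracle <- function(ds1, ds2, rho = 0, gamma = 0) {
  s <- surv_frame(ds1, ds2)
  tt <- sort(unique(s$time[s$status == 1]))
  num <- 0; den <- 0; Spool <- 1
  for (t in tt) {
    at1 <- s$group == 1 & s$time >= t
    at2 <- s$group == 2 & s$time >= t
    n1 <- sum(at1); n2 <- sum(at2); n <- n1 + n2
    d1 <- sum(s$group == 1 & s$time == t & s$status == 1)
    d <- d1 + sum(s$group == 2 & s$time == t & s$status == 1)
    w <- Spool^rho * (1 - Spool)^gamma
    num <- num + w * (d1 - d * n1 / n)
    if (n > 1)
      den <- den + w^2 * d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
    Spool <- Spool * (1 - d / n)
  }
  num^2 / den
}

# Fisher enumeration oracle from binomial coefficients only.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + c; m2 <- b + d; A <- a + b; N <- m1 + m2
  support <- max(0, A - m2):min(A, m1)
  prob <- choose(m1, support) * choose(m2, A - support) / choose(N, A)
  p_obs <- choose(m1, a) * choose(m2, b) / choose(N, A)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon rank-sum oracle by full enumeration of group
# assignments (requires no ties).
ranksum_enum_oracle <- function(s1, s2) {
  m <- length(s1)
  pooled <- c(s1, s2)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combos <- combn(length(pooled), m)
  U_all <- apply(combos, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
}

# Chow oracle built on lm().
chow_oracle <- function(t1, y1, t2, y2, k) {
  rss <- function(t, y) sum(resid(lm(y ~ t))^2)
  r1 <- rss(t1, y1); r2 <- rss(t2, y2)
  rp <- rss(c(t1, t2), c(y1, y2))
  N <- length(t1) + length(t2)
  ((rp - r1 - r2) / k) / ((r1 + r2) / (N - 2 * k))
}

# Exact KS permutation p-value by full enumeration of label assignments
# on a tiny pooled sample.
ks_enum_oracle <- function(ds1, ds2) {
  s <- surv_frame(ds1, ds2)
  n <- nrow(s); n1 <- sum(s$group == 1)
  km_curve <- function(sub, tt) {
    S <- 1; out <- numeric(length(tt))
    for (j in seq_along(tt)) {
      at <- sum(sub$time >= tt[j])
      d <- sum(sub$time == tt[j] & sub$status == 1)
      if (at > 0) S <- S * (1 - d / at)
      out[j] <- S
    }
    out
  }
  tt <- sort(unique(s$time[s$status == 1]))
  Dstat <- function(idx) {
    max(abs(km_curve(s[idx, ], tt) - km_curve(s[-idx, ], tt)))
  }
  D_obs <- Dstat(seq_len(n1))
  combos <- combn(n, n1)
  D_all <- apply(combos, 2, Dstat)
  mean(D_all >= D_obs - 1e-12)
}

# Global Cox score statistic at beta = 0 (no fitting), via the package's
# partial-likelihood derivatives.
fit_cox0_score <- function(d) {
  pl <- survassay:::cox_loglik(d$time, d$status, d$covariates,
                               numeric(ncol(d$covariates)), "breslow")
  drop(crossprod(pl$score, solve(pl$info, pl$score)))
}
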