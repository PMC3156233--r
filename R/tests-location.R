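#' Log-rank (Mantel-Cox) test
#'
#' Two-sample log-rank test for a difference in overall lifespan. Over the
#' pooled distinct death times, observed deaths in group 1 are compared to
#' their conditional expectation \eqn{e_i = d_i n_{1i} / n_i}; the
#' statistic
#' \deqn{\chi^2 = \frac{\left(\sum_i (d_{1i} - e_i)\right)^2}{\sum_i v_i},
#'   \quad v_i = d_i \frac{n_{1i}}{n_i}\frac{n_{2i}}{n_i}
#'   \frac{n_i - d_i}{n_i - 1}}
#' is referred to a chi-square distribution with 1 degree of freedom.
#' Times where only one subject is at risk contribute zero variance.
#' The test is most powerful under proportional hazards.
#'
#' @param ds1,ds2 [survival_dataset] objects, each with at least one death.
#' @return A [test_result] with the chi-square statistic, p-value, and
#'   extras `observed` and `expected` (deaths in group 1).
#' @examples
#' a <- survival_dataset(c(10, 12, 15), c(2, 1, 1), c(0, 0, 0), "ctrl")
#' b <- survival_dataset(c(14, 18, 20), c(1, 2, 1), c(0, 0, 0), "drug")
#' logrank_test(a, b)
#' @export
logrank_test <- function(ds1, ds2) {
  check_two_sample(ds1, ds2)
  tab <- pooled_event_table(ds1, ds2)
  V <- sum(tab$v)
  if (V <= 0)
    stop("log-rank variance is zero; the groups cannot be compared")
  OmE <- sum(tab$d1 - tab$e1)
  stat <- OmE^2 / V
  test_result("log-rank", stat, pchisq(stat, df = 1, lower.tail = FALSE),
              df = 1,
              extras = list(observed = sum(tab$d1), expected = sum(tab$e1),
                            labels = c(ds1$label, ds2$label)))
}

#' Fleming-Harrington weighted log-rank test
#'
#' The G(rho, gamma) family of weighted log-rank tests. Each pooled death
#' time is weighted by
#' \eqn{w_i = \hat S(t_i-)^{\rho} (1 - \hat S(t_i-))^{\gamma}} where
#' \eqn{\hat S(t-)} is the left-continuous pooled Kaplan-Meier estimate.
#' With `rho > 0, gamma = 0` the test emphasises early deaths; with
#' `rho = 0, gamma > 0` it emphasises late deaths; `rho = gamma = 0`
#' reduces exactly to [logrank_test()].
#'
#' @inheritParams logrank_test
#' @param rho,gamma non-negative weight exponents.
#' @return A [test_result]; extras record `rho` and `gamma`.
#' @export
weighted_logrank_test <- function(ds1, ds2, rho = 0, gamma = 0) {
  check_two_sample(ds1, ds2)
  if (rho < 0 || gamma < 0) stop("'rho' and 'gamma' must be non-negative")
  tab <- pooled_event_table(ds1, ds2)
  w <- tab$s_prev^rho * (1 - tab$s_prev)^gamma
  V <- sum(w^2 * tab$v)
  if (V <= 0)
    stop("degenerate weights: the weighted log-rank variance is zero ",
         "(try different rho/gamma)")
  stat <- sum(w * (tab$d1 - tab$e1))^2 / V
  test_result(sprintf("weighted log-rank G(%g,%g)", rho, gamma), stat,
              pchisq(stat, df = 1, lower.tail = FALSE), df = 1,
              extras = list(rho = rho, gamma = gamma,
                            labels = c(ds1$label, ds2$label)))
}

#' Fisher's exact test at a mortality quantile
#'
#' Compares the proportion of survivors between two groups at the first
#' pooled death time where the pooled Kaplan-Meier mortality reaches
#' `mortality_fraction` (by default 90% mortality). The 2x2 table counts
#' subjects alive versus dead at that time in each group; subjects
#' censored before it are excluded because their status there is unknown.
#' The two-sided p-value is the sum of hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one.
#'
#' @inheritParams logrank_test
#' @param mortality_fraction target pooled mortality in `(0, 1]`; default
#'   0.9.
#' @return A [test_result]; extras record the chosen time `t_star`, the
#'   2x2 `table` (rows alive/dead, columns group 1/group 2) and the number
#'   of subjects excluded as censored before `t_star`.
#' @export
fisher_exact_at_mortality <- function(ds1, ds2, mortality_fraction = 0.9) {
  check_two_sample(ds1, ds2)
  if (mortality_fraction <= 0 || mortality_fraction > 1)
    stop("'mortality_fraction' must be in (0, 1]")
  tab <- pooled_event_table(ds1, ds2)
  hit <- which(1 - tab$s_pool >= mortality_fraction - 1e-12)
  if (!length(hit))
    stop("pooled mortality never reaches ",
         round(100 * mortality_fraction), "%; try a lower ",
         "'mortality_fraction'")
  t_star <- tab$time[hit[1L]]

  cell <- function(ds) {
    dead <- sum(ds$deaths[ds$time <= t_star])
    alive <- sum(ds$deaths[ds$time > t_star]) +
      sum(ds$censored[ds$time >= t_star])
    excl <- sum(ds$censored[ds$time < t_star])
    c(alive = alive, dead = dead, excluded = excl)
  }
  g1 <- cell(ds1); g2 <- cell(ds2)
  a <- g1["alive"]; b <- g2["alive"]; cc <- g1["dead"]; dd <- g2["dead"]
  m1 <- a + cc; m2 <- b + dd; A <- a + b
  p <- fisher_two_sided(unname(a), unname(m1), unname(m2), unname(A))

  tbl <- matrix(c(a, cc, b, dd), 2, 2,
                dimnames = list(c("alive", "dead"),
                                c(ds1$label, ds2$label)))
  test_result("fisher-exact", statistic = NA_real_, p_value = p,
              extras = list(t_star = t_star, table = tbl,
                            mortality_fraction = mortality_fraction,
                            n_excluded = unname(g1["excluded"] +
                                                g2["excluded"])))
}

# Two-sided Fisher p by probability-mass ordering: a = alive in group 1,
# m1/m2 = group sizes, A = total alive. Sums dhyper over all feasible
# tables with probability <= the observed one (within a relative epsilon).
fisher_two_sided <- function(a, m1, m2, A) {
  support <- max(0, A - m2):min(A, m1)
  probs <- dhyper(support, m1, m2, A)
  p_obs <- dhyper(a, m1, m2, A)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
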