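#' Simulate a lifespan assay
#'
#' Draws death times from a Gaussian, Gompertz or exponential lifespan
#' model, optionally censors a fraction of subjects at a uniform time
#' before their death, records times as whole days (the resolution of a
#' typical lifespan assay) and aggregates the cohort into a grouped
#' [survival_dataset]. Draws that would round below day 1 are redrawn,
#' so all recorded times are positive integers when `round_to_days` is
#' on. Deterministic for a given `seed`.
#'
#' @param n number of subjects (>= 1).
#' @param family `"gaussian"`, `"gompertz"` or `"exponential"`.
#' @param mean,sd Gaussian mean and standard deviation of lifespan, in
#'   days.
#' @param rate exponential rate, or the Gompertz baseline rate `a`.
#' @param shape Gompertz shape `b` (log-linear increase of hazard with
#'   age).
#' @param censor_rate fraction of subjects censored, in `[0, 1)`.
#' @param round_to_days record times as whole days (default `TRUE`).
#' @param seed optional integer seed; the caller's RNG state is
#'   preserved.
#' @param label dataset label.
#' @return A [survival_dataset].
#' @examples
#' simulate_lifespans(50, mean = 20, sd = 4, seed = 1)
#' @export
simulate_lifespans <- function(n, family = c("gaussian", "gompertz",
                                             "exponential"),
                               mean = 20, sd = 4, rate = 0.1,
                               shape = 0.1, censor_rate = 0,
                               round_to_days = TRUE, seed = NULL,
                               label = NULL) {
  family <- match.arg(family)
  if (n < 1) stop("'n' must be at least 1")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("'censor_rate' must be in [0, 1)")
  if (family == "gaussian" && sd <= 0) stop("'sd' must be positive")
  if (family != "gaussian" && rate <= 0) stop("'rate' must be positive")
  if (family == "gompertz" && shape <= 0) stop("'shape' must be positive")
  if (is.null(label))
    label <- switch(family,
                    gaussian = sprintf("gaussian(%g,%g)", mean, sd),
                    gompertz = sprintf("gompertz(%g,%g)", rate, shape),
                    exponential = sprintf("exponential(%g)", rate))

  with_seed(seed, {
    draw <- function(m) switch(family,
      gaussian = rnorm(m, mean, sd),
      gompertz = flexsurv::rgompertz(m, shape = shape, rate = rate),
      exponential = rexp(m, rate))
    lo <- if (round_to_days) 0.5 else 0     # keeps recorded days >= 1
    t_death <- draw(n)
    bad <- which(t_death < lo)
    while (length(bad)) {
      t_death[bad] <- draw(length(bad))
      bad <- bad[t_death[bad] < lo]
    }
    n_cens <- floor(censor_rate * n)
    status <- rep(1L, n)
    if (n_cens > 0) {
      idx <- sample.int(n, n_cens)
      status[idx] <- 0L
      t_death[idx] <- runif(n_cens, 0, t_death[idx])
    }
    t_rec <- if (round_to_days) pmax(1, round(t_death)) else t_death
    from_subjects(t_rec, status, label = label)
  })
}

#' Simulate the three-cohort validation design
#'
#' Generates the hypothetical triplet of Gaussian lifespan cohorts used
#' to validate the variance tests: A and B share a mean lifespan of 20
#' days but differ in spread (SD 2 vs 4 days), while B and C share the
#' spread (SD 4 days) but differ in mean (20 vs 30 days). Lifespans are
#' recorded as whole days with no censoring. A location test (log-rank)
#' should separate B from C but not A from B, while the variance tests
#' (survival-time F, partial-slopes rank-sum, normalized Chow) should
#' separate A from B.
#'
#' @param n subjects per cohort (>= 30; default 250).
#' @param seed integer seed; per-cohort streams are derived from it.
#' @return A named list of three [survival_dataset]s, `A`, `B`, `C`.
#' @export
make_validation_triplet <- function(n = 250, seed = NULL) {
  if (n < 30) stop("'n' must be at least 30 per cohort")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  list(
    A = simulate_lifespans(n, "gaussian", mean = 20, sd = 2,
                           seed = seeds[1L], label = "A"),
    B = simulate_lifespans(n, "gaussian", mean = 20, sd = 4,
                           seed = seeds[2L], label = "B"),
    C = simulate_lifespans(n, "gaussian", mean = 30, sd = 4,
                           seed = seeds[3L], label = "C"))
}

#' Simulate subject-level data from a proportional-hazards model
#'
#' Draws death times with hazard
#' \eqn{h_i(t) = h_0 \exp(x_i' \beta)} for an exponential baseline
#' \eqn{h_0}, with optional uniform administrative censoring. Used to
#' validate Cox coefficient recovery.
#'
#' @param n subjects.
#' @param beta true log hazard ratios, one per covariate.
#' @param baseline_rate exponential baseline hazard.
#' @param covariates matrix of covariates (default: one standard
#'   Bernoulli(0.5) column per element of `beta`).
#' @param censor_time administrative censoring time, `Inf` for none.
#' @param seed optional integer seed.
#' @return A [cox_dataset].
#' @export
simulate_cox <- function(n, beta = 0.7, baseline_rate = 0.05,
                         covariates = NULL, censor_time = Inf,
                         seed = NULL) {
  with_seed(seed, {
    k <- length(beta)
    if (is.null(covariates))
      covariates <- matrix(stats::rbinom(n * k, 1, 0.5), n, k)
    covariates <- as.matrix(covariates)
    rate_i <- baseline_rate * exp(drop(covariates %*% beta))
    t_death <- rexp(n, rate_i)
    status <- as.integer(t_death <= censor_time)
    time <- pmin(t_death, censor_time)
    cox_dataset(time, status, covariates)
  })
}
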