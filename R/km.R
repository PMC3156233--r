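#' Kaplan-Meier product-limit estimate
#'
#' Computes the Kaplan-Meier survival estimate from a grouped survival
#' dataset. Subjects censored at an observed time leave the risk set after
#' the deaths at that time are counted (the usual right-censoring
#' convention), so the at-risk count at time `t` includes everyone whose
#' recorded time is `>= t`. The variance of the estimate follows
#' Greenwood's formula
#' \deqn{\widehat{Var}(S(t_j)) = S(t_j)^2 \sum_{i \le j}
#'   \frac{d_i}{n_i (n_i - d_i)},}
#' set to 0 where the curve has dropped to 0.
#'
#' @param ds a [survival_dataset].
#' @return An object of class `km_estimate` with components `time`
#'   (distinct death times), `surv` (S at each death time), `greenwood_var`,
#'   `n_risk`, `n_event`, `n_censor_after` (censored at or after each death
#'   time, before the next one), `n_total` and `label`. If the dataset
#'   contains no deaths the estimate is identically 1 and a warning is
#'   issued.
#' @examples
#' ds <- survival_dataset(c(10, 20, 30), c(1, 1, 0), c(0, 0, 2))
#' km_estimate(ds)$surv  # 0.75, 0.50
#' @export
km_estimate <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  # at-risk just before each record time (censored at t still at risk at t)
  n_after <- ds$n_total - cumsum(ds$deaths + ds$censored)
  n_risk_all <- c(ds$n_total, head(n_after, -1L))

  ev <- ds$deaths > 0L
  if (!any(ev)) {
    warning("dataset '", ds$label, "' contains no deaths; survival is ",
            "identically 1 and the hazard cannot be estimated")
    return(structure(list(time = numeric(0), surv = numeric(0),
                          greenwood_var = numeric(0), n_risk = numeric(0),
                          n_event = integer(0), n_censor_after = integer(0),
                          n_total = ds$n_total, label = ds$label,
                          max_time = max(ds$time), no_events = TRUE),
                     class = "km_estimate"))
  }

  time <- ds$time[ev]
  d <- ds$deaths[ev]
  n <- n_risk_all[ev]
  surv <- cumprod(1 - d / n)
  # Greenwood sum; the increment is infinite where n == d (curve hits 0)
  inc <- ifelse(n > d, d / (n * (n - d)), Inf)
  gw <- surv^2 * cumsum(inc)
  gw[surv == 0] <- 0

  # censored subjects attributed to the death-time interval they follow
  cuts <- findInterval(ds$time, time)          # 0 = before first death time
  cens_after <- vapply(seq_along(time), function(j)
    sum(ds$censored[cuts == j]), numeric(1))

  structure(list(time = time, surv = surv, greenwood_var = gw,
                 n_risk = n, n_event = d,
                 n_censor_after = as.integer(cens_after),
                 n_total = ds$n_total, label = ds$label,
                 max_time = max(ds$time), no_events = FALSE),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate for '", x$label, "' (n = ", x$n_total,
      ")\n", sep = "")
  if (length(x$time))
    print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     survival = round(x$surv, 4),
                     std_err = round(sqrt(x$greenwood_var), 4)),
          row.names = FALSE)
  else cat("  no deaths observed; S(t) = 1 throughout\n")
  invisible(x)
}

# S(t) of a KM estimate evaluated at arbitrary times (right-continuous
# step function).
km_surv_at <- function(km, t) {
  if (length(km$time) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

#' Descriptive lifespan statistics from a Kaplan-Meier estimate
#'
#' Computes the restricted mean lifespan (area under the Kaplan-Meier step
#' function from 0 to `tau`), its standard error by the classic
#' Kaplan-Meier area-variance formula
#' \eqn{\sum_j A_j^2 d_j / (n_j (n_j - d_j))} with
#' \eqn{A_j = \int_{t_j}^{\tau} S(t) dt}, a normal-approximation 95%
#' confidence interval, and the age at 25/50/75/90/100% mortality. The age
#' at q% mortality is the smallest death time with \eqn{S(t) \le 1 - q/100}
#' (no interpolation); the age at 100% mortality is undefined (`NA`,
#' printed "-") when the longest-surviving subject was censored.
#'
#' @param km a [km_estimate].
#' @param ds the [survival_dataset] the estimate came from (for the
#'   truncation time).
#' @param tau truncation time for the restricted mean; defaults to the
#'   last observed time (death or censoring).
#' @param percentiles mortality percentages to report ages for.
#' @return An object of class `lifespan_summary` with components
#'   `restricted_mean`, `restricted_mean_se`, `ci95`, `median` and
#'   `percentile_ages`.
#' @export
summary_stats <- function(km, ds, tau = NULL,
                          percentiles = c(25, 50, 75, 90, 100)) {
  stopifnot(inherits(km, "km_estimate"))
  if (is.null(tau)) tau <- if (!missing(ds)) max(ds$time) else km$max_time
  tt <- km$time[km$time <= tau]
  ss <- km$surv[km$time <= tau]
  # area under the step function: S is 1 on [0, t_1), ss[j] on [t_j, t_{j+1})
  widths <- diff(c(0, tt, tau))
  heights <- c(1, ss)
  rmean <- sum(widths * heights)

  # A_j = area under S from t_j to tau
  if (length(tt)) {
    areas_after <- rev(cumsum(rev(ss * diff(c(tt, tau)))))
    n <- km$n_risk[km$time <= tau]
    d <- km$n_event[km$time <= tau]
    terms <- ifelse(n > d, areas_after^2 * d / (n * (n - d)), 0)
    rse <- sqrt(sum(terms))
  } else rse <- 0

  pct <- vapply(percentiles, function(q) {
    hit <- which(km$surv <= 1 - q / 100 + 1e-12)
    if (length(hit)) km$time[hit[1L]] else NA_real_
  }, numeric(1))
  names(pct) <- percentiles

  structure(list(label = km$label, n = km$n_total,
                 restricted_mean = rmean, restricted_mean_se = rse,
                 ci95 = c(rmean - 1.96 * rse, rmean + 1.96 * rse),
                 median = unname(pct[as.character(50)]),
                 percentile_ages = pct, tau = tau),
            class = "lifespan_summary")
}

#' @export
print.lifespan_summary <- function(x, digits = 2, ...) {
  cat("Lifespan summary for '", x$label, "' (n = ", x$n, ")\n", sep = "")
  cat("  restricted mean: ", round(x$restricted_mean, digits),
      " days (SE ", round(x$restricted_mean_se, digits), ", 95% CI ",
      round(x$ci95[1], digits), "-", round(x$ci95[2], digits), ")\n",
      sep = "")
  ages <- ifelse(is.na(x$percentile_ages), "-",
                 format(x$percentile_ages, trim = TRUE))
  cat("  age at % mortality:",
      paste0(names(x$percentile_ages), "%: ", ages, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a hazard curve from explicit points
#'
#' @param time strictly increasing times.
#' @param y log cumulative hazard values at those times.
#' @param estimator label for how the points were obtained.
#' @return An object of class `hazard_curve`.
#' @export
hazard_curve <- function(time, y, estimator = "manual") {
  if (length(time) != length(y))
    stop("'time' and 'y' must have equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop("hazard-curve times must be strictly increasing")
  structure(list(time = as.numeric(time), y = as.numeric(y),
                 estimator = estimator),
            class = "hazard_curve")
}

#' Log cumulative hazard curve
#'
#' Derives the log cumulative hazard \eqn{\ln H(t)} at each death time
#' with \eqn{0 < S(t) < 1}. The default uses the Kaplan-Meier transform
#' \eqn{H(t) = -\ln S_{KM}(t)}; `estimator = "nelson-aalen"` uses the
#' Nelson-Aalen estimator \eqn{H(t) = \sum_{t_i \le t} d_i / n_i}. On a
#' log-time axis the slope of this curve reads as the age-dependent
#' acceleration of mortality (linear in `t` for Gompertz mortality) and
#' the intercept as the initial hazard.
#'
#' @param km a [km_estimate].
#' @param estimator `"km"` (default) or `"nelson-aalen"`.
#' @return A [hazard_curve]. An error is raised when fewer than one point
#'   is available; downstream slope-based tests require at least two.
#' @export
log_cumulative_hazard <- function(km, estimator = c("km", "nelson-aalen")) {
  stopifnot(inherits(km, "km_estimate"))
  estimator <- match.arg(estimator)
  usable <- km$surv > 0 & km$surv < 1
  if (!any(usable))
    stop("no death times with 0 < S(t) < 1; cannot form a log cumulative ",
         "hazard curve")
  if (estimator == "km") {
    H <- -log(km$surv[usable])
  } else {
    H <- cumsum(km$n_event / km$n_risk)[usable]
  }
  hazard_curve(km$time[usable], log(H), estimator = estimator)
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat("Log cumulative hazard curve (", x$estimator, " estimator), ",
      length(x$time), " points\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.hazard_curve <- function(x, ...) {
  data.frame(time = x$time, log_cum_hazard = x$y)
}

#' Export plot data for survival and hazard curves
#'
#' Returns (and optionally writes as TSV) the step-function vertices of a
#' Kaplan-Meier curve or the points of a hazard curve, ready for any
#' plotting tool.
#'
#' @param x a [km_estimate] or [hazard_curve].
#' @param file optional TSV path.
#' @return A data frame of plot vertices, invisibly when writing.
#' @export
plot_data <- function(x, file = NULL) {
  if (inherits(x, "km_estimate")) {
    t <- rep(c(0, x$time), each = 2)[-1L]
    s <- rep(c(1, x$surv), each = 2)
    s <- s[-length(s)]
    out <- data.frame(time = t, survival = s)
  } else if (inherits(x, "hazard_curve")) {
    out <- data.frame(time = x$time, log_cum_hazard = x$y)
  } else stop("no plot data for objects of class ", class(x)[1L])
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @export
plot.km_estimate <- function(x, xlab = "time (days)", ylab = "survival",
                             ...) {
  pd <- plot_data(x)
  graphics::plot(pd$time, pd$survival, type = "l", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
plot.hazard_curve <- function(x, xlab = "time (days)",
                              ylab = "log cumulative hazard", ...) {
  graphics::plot(x$time, x$y, type = "b", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
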