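# Shared two-sample bookkeeping over pooled event times.

# Number of subjects in ds still at risk just before (and at) each time t:
# everyone whose recorded time is >= t (censored subjects leave after the
# deaths at their recorded time).
risk_at <- function(ds, t) {
  n <- ds$deaths + ds$censored
  vapply(t, function(ti) sum(n[ds$time >= ti]), numeric(1))
}

deaths_at <- function(ds, t) {
  idx <- match(t, ds$time)
  d <- ifelse(is.na(idx), 0L, ds$deaths[idx])
  as.numeric(d)
}

# Pooled two-sample event table over the distinct death times of both
# groups: per-time at-risk and death counts per group, pooled counts, the
# log-rank expectation and hypergeometric variance, and the left-continuous
# pooled Kaplan-Meier estimate (S just before each event time).
pooled_event_table <- function(ds1, ds2) {
  tt <- sort(unique(c(ds1$time[ds1$deaths > 0], ds2$time[ds2$deaths > 0])))
  d1 <- deaths_at(ds1, tt); d2 <- deaths_at(ds2, tt)
  n1 <- risk_at(ds1, tt);   n2 <- risk_at(ds2, tt)
  d <- d1 + d2; n <- n1 + n2
  e1 <- d * n1 / n
  v <- ifelse(n > 1, d * (n1 / n) * (n2 / n) * (n - d) / (n - 1), 0)
  s_pool <- cumprod(1 - d / n)
  data.frame(time = tt, d1 = d1, d2 = d2, n1 = n1, n2 = n2, d = d, n = n,
             e1 = e1, v = v, s_pool = s_pool,
             s_prev = c(1, head(s_pool, -1L)))
}

check_two_sample <- function(ds1, ds2) {
  stopifnot(inherits(ds1, "survival_dataset"),
            inherits(ds2, "survival_dataset"))
  if (sum(ds1$deaths) < 1L || sum(ds2$deaths) < 1L)
    stop("both datasets must contain at least one death")
  invisible(NULL)
}

# Any observed time with more than one death, within or between samples?
has_tied_deaths <- function(ds1, ds2) {
  tab <- pooled_event_table(ds1, ds2)
  any(tab$d > 1)
}

#' Construct a test result
#'
#' Container for the outcome of a two-sample (or one-sample) test:
#' method identifier, statistic, p-value, optional degrees of freedom,
#' warnings accumulated during computation, and method-specific extras.
#'
#' @param method character identifier.
#' @param statistic numeric test statistic.
#' @param p_value numeric in `[0, 1]`.
#' @param df degrees of freedom (scalar or vector), or `NULL`.
#' @param warnings character vector of warnings.
#' @param extras named list of method-specific values.
#' @return An object of class `survassay_test`.
#' @export
test_result <- function(method, statistic, p_value, df = NULL,
                        warnings = character(0), extras = list()) {
  if (!is.na(p_value) && (p_value < -1e-12 || p_value > 1 + 1e-12))
    stop("p-value outside [0, 1]")
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(min(max(p_value, 0), 1)), df = df,
                 warnings = warnings, extras = extras),
            class = "survassay_test")
}

#' @export
print.survassay_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 5),
      if (!is.null(x$df)) paste0(", df = ", paste(x$df, collapse = ", ")),
      ", p = ", format_pvalue(x$p_value), "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
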