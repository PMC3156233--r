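#' Construct a grouped survival dataset
#'
#' A `survival_dataset` holds one labelled lifespan experiment as interval
#' records of (time, deaths, censored). Times must be non-negative and are
#' stored in strictly increasing order; rows sharing a time are merged by
#' summing counts. Rows with neither deaths nor censored subjects are
#' dropped with a warning.
#'
#' @param time numeric vector of observation times (typically integer days).
#' @param deaths non-negative integer vector, deaths at each time.
#' @param censored non-negative integer vector, subjects censored at each
#'   time (lost to follow-up; they leave the risk set after deaths at the
#'   same time are counted).
#' @param label character identifier for the experiment.
#' @return An object of class `survival_dataset` with components `label`,
#'   `time`, `deaths`, `censored` and `n_total` (total number of subjects).
#' @examples
#' survival_dataset(c(10, 20), deaths = c(1, 1), censored = c(0, 2),
#'                  label = "wild type")
#' @export
survival_dataset <- function(time, deaths, censored, label = "unnamed") {
  if (length(time) == 0L)
    stop("a survival dataset needs at least one record")
  if (length(deaths) != length(time) || length(censored) != length(time))
    stop("'time', 'deaths' and 'censored' must have equal length")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative")
  if (any(!is.finite(deaths)) || any(deaths < 0) ||
      any(deaths != round(deaths)))
    stop("'deaths' must be non-negative integers")
  if (any(!is.finite(censored)) || any(censored < 0) ||
      any(censored != round(censored)))
    stop("'censored' must be non-negative integers")

  ord <- order(time)
  time <- time[ord]; deaths <- deaths[ord]; censored <- censored[ord]

  if (anyDuplicated(time)) {
    message("merging rows with duplicate times in dataset '", label, "'")
    deaths <- as.vector(tapply(deaths, factor(time, levels = unique(time)),
                               sum))
    censored <- as.vector(tapply(censored,
                                 factor(time, levels = unique(time)), sum))
    time <- unique(time)
  }

  empty <- deaths + censored == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " row(s) with no deaths and no ",
            "censored subjects in dataset '", label, "'")
    time <- time[!empty]; deaths <- deaths[!empty]
    censored <- censored[!empty]
  }
  if (length(time) == 0L)
    stop("dataset '", label, "' has no usable records")

  structure(
    list(label = as.character(label), time = as.numeric(time),
         deaths = as.integer(deaths), censored = as.integer(censored),
         n_total = as.integer(sum(deaths) + sum(censored))),
    class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("Grouped survival dataset '", x$label, "': ", x$n_total,
      " subjects, ", sum(x$deaths), " deaths, ", sum(x$censored),
      " censored over ", length(x$time), " times\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.survival_dataset <- function(x, ...) {
  data.frame(time = x$time, deaths = x$deaths, censored = x$censored)
}

# Expand a grouped dataset to one (time, status) row per subject;
# status 1 = death, 0 = censored.
subject_level <- function(ds) {
  time <- rep(ds$time, ds$deaths + ds$censored)
  status <- unlist(lapply(seq_along(ds$time), function(i)
    rep(c(1L, 0L), c(ds$deaths[i], ds$censored[i]))), use.names = FALSE)
  data.frame(time = time, status = status)
}

# Rebuild a grouped dataset from subject-level rows.
from_subjects <- function(time, status, label = "unnamed") {
  tt <- sort(unique(time))
  d <- vapply(tt, function(t) sum(status == 1L & time == t), numeric(1))
  cns <- vapply(tt, function(t) sum(status == 0L & time == t), numeric(1))
  survival_dataset(tt, d, cns, label = label)
}

#' Construct a subject-level Cox regression dataset
#'
#' @param time positive observed times (death or censoring).
#' @param status event indicator, 1 = dead, 0 = censored.
#' @param covariates numeric matrix or data frame of risk factors, one row
#'   per subject, at least one column.
#' @param field_names optional character names for the columns, in the
#'   order time, status, then risk factors.
#' @return An object of class `cox_dataset`.
#' @export
cox_dataset <- function(time, status, covariates,
                        field_names = NULL) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (ncol(covariates) < 1L)
    stop("at least one risk-factor column is required")
  if (nrow(covariates) != length(time) || length(status) != length(time))
    stop("'time', 'status' and 'covariates' must agree in length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("observed times must be finite and positive")
  if (!all(status %in% c(0, 1)))
    stop("'status' must be 0 (censored) or 1 (dead)")
  if (any(!is.finite(covariates)))
    stop("risk factors must be finite numbers")
  if (is.null(field_names))
    field_names <- c("time", "status",
                     if (!is.null(colnames(covariates))) colnames(covariates)
                     else paste0("x", seq_len(ncol(covariates))))
  if (length(field_names) != 2L + ncol(covariates))
    stop("'field_names' must name time, status and every risk factor")
  colnames(covariates) <- field_names[-(1:2)]
  structure(list(field_names = field_names, time = as.numeric(time),
                 status = as.integer(status), covariates = covariates),
            class = "cox_dataset")
}

#' @export
print.cox_dataset <- function(x, ...) {
  cat("Cox dataset: ", length(x$time), " subjects, ", sum(x$status),
      " events, risk factors: ",
      paste(colnames(x$covariates), collapse = ", "), "\n", sep = "")
  invisible(x)
}
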