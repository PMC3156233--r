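#' Pairwise comparison report
#'
#' Runs the requested two-sample tests on every unordered pair of
#' datasets and applies a Bonferroni correction within each test family:
#' corrected p = min(1, p x number of pairs). A test that fails on a
#' pair records the error message in its row instead of aborting the
#' whole matrix; warnings are propagated into the report.
#'
#' @param datasets list of at least two [survival_dataset] objects.
#' @param methods character vector of method identifiers among
#'   `"logrank"`, `"weighted-logrank"`, `"fisher"`, `"ks"`, `"neyman"`,
#'   `"chow"`, `"f-test"`, `"ranksum"`, `"normalized-chow"`.
#' @param alpha significance level applied to the corrected p-values.
#' @param rho,gamma weights for `"weighted-logrank"`.
#' @param mortality_fraction quantile for `"fisher"`.
#' @param n_perm,seed permutation settings for `"ks"` and `"neyman"`.
#' @return A data frame of class `survassay_report` with one row per
#'   (method, pair): method, the two labels, statistic, p_value,
#'   p_corrected, significant, warnings, error.
#' @export
run_compare <- function(datasets, methods = "logrank", alpha = 0.05,
                        rho = 0, gamma = 0, mortality_fraction = 0.9,
                        n_perm = 2000, seed = NULL) {
  if (length(datasets) < 2L)
    stop("at least two datasets are needed for comparisons")
  known <- c("logrank", "weighted-logrank", "fisher", "ks", "neyman",
             "chow", "f-test", "ranksum", "normalized-chow")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  labels <- vapply(datasets, `[[`, character(1), "label")
  pairs <- combn(length(datasets), 2L)
  m <- ncol(pairs)

  run_one <- function(method, i, j) {
    ds1 <- datasets[[i]]; ds2 <- datasets[[j]]
    curves <- function() list(
      log_cumulative_hazard(km_estimate(ds1)),
      log_cumulative_hazard(km_estimate(ds2)))
    switch(method,
      "logrank" = logrank_test(ds1, ds2),
      "weighted-logrank" = weighted_logrank_test(ds1, ds2, rho, gamma),
      "fisher" = fisher_exact_at_mortality(ds1, ds2, mortality_fraction),
      "ks" = ks_test(ds1, ds2, n_perm = n_perm, seed = seed),
      "neyman" = neyman_smooth_test(ds1, ds2, n_perm = n_perm,
                                    seed = seed),
      "chow" = { h <- curves(); chow_test(h[[1L]], h[[2L]]) },
      "f-test" = survival_time_f_test(ds1, ds2),
      "ranksum" = partial_slopes_ranksum_test(ds1, ds2),
      "normalized-chow" = { h <- curves()
                            normalized_chow_test(h[[1L]], h[[2L]]) })
  }

  rows <- list()
  for (method in methods) {
    for (p in seq_len(m)) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      warns <- character(0)
      res <- withCallingHandlers(
        tryCatch(run_one(method, i, j), error = function(e)
          conditionMessage(e)),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (is.character(res)) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, group1 = labels[i], group2 = labels[j],
          statistic = NA_real_, p_value = NA_real_,
          p_corrected = NA_real_, significant = NA,
          warnings = paste(warns, collapse = "; "), error = res)
      } else {
        warns <- c(warns, res$warnings)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, group1 = labels[i], group2 = labels[j],
          statistic = res$statistic, p_value = res$p_value,
          p_corrected = min(1, res$p_value * m),
          significant = min(1, res$p_value * m) < alpha,
          warnings = paste(warns, collapse = "; "), error = "")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_pairs") <- m
  class(out) <- c("survassay_report", "data.frame")
  out
}

#' Format a p-value for reporting
#'
#' Renders p-values in scientific notation with two decimals. Values
#' below `floor` print as `"<1.0E-10"`, or as `"0.00E+00"` when
#' `compat = TRUE` (mirroring the rendering of legacy lifespan web
#' tools).
#'
#' @param p a p-value in `[0, 1]`.
#' @param floor reporting floor (default 1e-10).
#' @param compat render sub-floor values as `"0.00E+00"`.
#' @return A character scalar.
#' @examples
#' format_pvalue(0.113)           # "1.13E-01"
#' format_pvalue(3e-12)           # "<1.0E-10"
#' format_pvalue(3e-12, compat = TRUE)  # "0.00E+00"
#' @export
format_pvalue <- function(p, floor = 1e-10, compat = FALSE) {
  if (is.na(p)) return(NA_character_)
  if (p < 0 || p > 1) stop("p-value outside [0, 1]")
  if (p < floor) {
    if (compat) return("0.00E+00")
    return(sprintf("<%.1E", floor))
  }
  sprintf("%.2E", p)
}

#' Write a report as TSV or JSON
#'
#' @param report a data frame, e.g. from [run_compare()] or
#'   [cox_table()].
#' @param file output path.
#' @param format `"tsv"` or `"json"`.
#' @param compat_pvalues use the legacy `"0.00E+00"` rendering for
#'   p-values below 1e-10 in the TSV output.
#' @return The report, invisibly.
#' @export
write_report <- function(report, file, format = c("tsv", "json"),
                         compat_pvalues = FALSE) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(report), file, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    out <- as.data.frame(report)
    for (col in intersect(c("p_value", "p_corrected"), names(out)))
      out[[paste0(col, "_fmt")]] <- vapply(
        out[[col]], format_pvalue, character(1),
        compat = compat_pvalues)
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}

#' @export
print.survassay_report <- function(x, ...) {
  cat("Pairwise comparison report (", attr(x, "n_pairs"),
      " pairs, Bonferroni within method, alpha = ", attr(x, "alpha"),
      ")\n", sep = "")
  df <- as.data.frame(x)
  df$p_value <- vapply(df$p_value, format_pvalue, character(1))
  df$p_corrected <- vapply(df$p_corrected, format_pvalue, character(1))
  df$warnings <- ifelse(nchar(df$warnings) > 0, "yes", "")
  print(df, row.names = FALSE)
  invisible(x)
}
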