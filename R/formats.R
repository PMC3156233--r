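#' Parse grouped survival tables
#'
#' Reads the plain-text grouped lifespan format: each experiment is a block
#' headed by a line starting with "%" (the experiment identifier) followed
#' by tab-separated rows with at least three columns — observed time,
#' number of deaths, number censored. Lines beginning with "#" are treated
#' as comments, blank lines and trailing whitespace are ignored, and
#' columns beyond the third are ignored with a warning. Duplicate times
#' within a block are merged by summing counts.
#'
#' @param text character: the raw table, either one string or a vector of
#'   lines.
#' @return A list of [survival_dataset] objects, one per "%" block.
#' @examples
#' parse_survival_table("% A\n10\t1\t0\n20\t1\t1")
#' @seealso [read_survival_tables()] to read from a file,
#'   [write_survival_tables()] for the inverse.
#' @export
parse_survival_table <- function(text) {
  lines <- split_lines(text)
  if (length(lines) == 0L) stop("format error: empty input")
  if (!startsWith(lines[[1L]], "%"))
    stop("format error: expected a '%' experiment-identifier line ",
         "before the first data row")

  blocks <- split(seq_along(lines), cumsum(startsWith(lines, "%")))
  extra_cols <- FALSE
  out <- lapply(blocks, function(idx) {
    label <- trimws(sub("^%", "", lines[[idx[1L]]]))
    if (!nzchar(label)) label <- "unnamed"
    rows <- idx[-1L]
    if (length(rows) == 0L)
      stop("format error: block '", label, "' has no data rows")
    cells <- strsplit(lines[rows], "\t", fixed = TRUE)
    ncell <- lengths(cells)
    if (any(ncell < 3L))
      stop("format error: line ", rows[which(ncell < 3L)[1L]],
           " has fewer than 3 tab-separated columns")
    if (any(ncell > 3L)) extra_cols <<- TRUE
    vals <- lapply(seq_along(cells), function(i) {
      v <- suppressWarnings(as.numeric(trimws(cells[[i]][1:3])))
      if (any(is.na(v)))
        stop("value error: non-numeric cell on line ", rows[i])
      if (any(v < 0))
        stop("value error: negative value on line ", rows[i])
      if (any(v[2:3] != round(v[2:3])))
        stop("value error: non-integer count on line ", rows[i])
      v
    })
    m <- do.call(rbind, vals)
    survival_dataset(m[, 1L], m[, 2L], m[, 3L], label = label)
  })
  if (extra_cols)
    warning("columns beyond the third were ignored")
  out <- unname(out)
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

#' Read grouped survival tables from a file
#'
#' @param file path to a grouped lifespan table file.
#' @return A list of [survival_dataset] objects.
#' @export
read_survival_tables <- function(file) {
  parse_survival_table(readLines(file, warn = FALSE))
}

#' Serialize grouped survival datasets
#'
#' Writes one or more [survival_dataset] objects back to the grouped
#' lifespan text format. Round-trips with [parse_survival_table()].
#'
#' @param datasets a `survival_dataset` or a list of them.
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return The formatted lines, invisibly.
#' @export
write_survival_tables <- function(datasets, file = NULL) {
  if (inherits(datasets, "survival_dataset")) datasets <- list(datasets)
  lines <- unlist(lapply(datasets, function(ds) {
    c(paste0("% ", ds$label),
      sprintf("%s\t%d\t%d", format(ds$time, trim = TRUE, scientific = FALSE),
              ds$deaths, ds$censored))
  }), use.names = FALSE)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Parse a subject-level Cox regression table
#'
#' Reads the risk-factor table format: a "%" line naming the fields
#' (observed time, event status, then one name per risk factor) followed
#' by tab-separated numeric rows, one per subject. Every row must have
#' exactly as many cells as the header has names; status must be 0
#' (censored) or 1 (dead).
#'
#' @param text character: the raw table, one string or a vector of lines.
#' @return A [cox_dataset].
#' @examples
#' parse_cox_table("% time\tstatus\tsex\n5\t1\t0\n7\t0\t1")
#' @export
parse_cox_table <- function(text) {
  lines <- split_lines(text)
  if (length(lines) == 0L) stop("format error: empty input")
  if (!startsWith(lines[[1L]], "%"))
    stop("format error: expected a '%' field-name line")
  field_names <- trimws(strsplit(sub("^%", "", lines[[1L]]), "\t",
                                 fixed = TRUE)[[1L]])
  field_names <- field_names[nzchar(field_names) | seq_along(field_names) > 0]
  if (length(field_names) < 3L)
    stop("format error: header must name time, status and at least one ",
         "risk factor")
  if (length(lines) < 2L) stop("format error: no data rows")
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(cells) != length(field_names)))
    stop("format error: line ",
         1L + which(lengths(cells) != length(field_names))[1L],
         " does not match the header (ragged row)")
  m <- do.call(rbind, lapply(seq_along(cells), function(i) {
    v <- suppressWarnings(as.numeric(trimws(cells[[i]])))
    if (any(is.na(v)))
      stop("value error: non-numeric cell on line ", i + 1L)
    v
  }))
  if (!all(m[, 2L] %in% c(0, 1)))
    stop("value error: status must be 0 or 1 (line ",
         1L + which(!(m[, 2L] %in% c(0, 1)))[1L], ")")
  cox_dataset(m[, 1L], m[, 2L], m[, -(1:2), drop = FALSE],
              field_names = field_names)
}

#' Read a Cox regression table from a file
#' @param file path to a risk-factor table file.
#' @return A [cox_dataset].
#' @export
read_cox_table <- function(file) {
  parse_cox_table(readLines(file, warn = FALSE))
}

#' Serialize a Cox regression dataset
#' @param data a [cox_dataset].
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return The formatted lines, invisibly.
#' @export
write_cox_table <- function(data, file = NULL) {
  header <- paste0("% ", paste(data$field_names, collapse = "\t"))
  body <- apply(cbind(data$time, data$status, data$covariates), 1L,
                function(r) paste(format(r, trim = TRUE,
                                         scientific = FALSE),
                                  collapse = "\t"))
  lines <- c(header, body)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# Split raw text into trimmed, non-blank, non-comment lines.
split_lines <- function(text) {
  lines <- unlist(strsplit(text, "\r?\n"), use.names = FALSE)
  lines <- sub("[ \t]+$", "", lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
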