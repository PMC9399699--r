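#' Read an age-incidence time series from CSV
#'
#' Reads a two-column CSV of ages (years) and incidence rates. A single
#' header row is auto-detected (the file may or may not have one); the
#' dialect is comma-separated with a decimal point. Rows are re-sorted
#' by ascending age; duplicate ages and non-numeric cells are rejected
#' with an error naming the offending row. Zero-rate rows are kept —
#' they are removed later by [filter_series()].
#'
#' @param path Path to the CSV file.
#' @param col_age,col_rate Column indices (after any header) holding age
#'   and rate.
#' @param label Optional dataset label; defaults to the file name.
#' @return A tibble with columns `age` and `rate` and attribute `label`.
#' @seealso [filter_series()], [write_incidence_csv()]
#' @export
read_incidence_csv <- function(path, col_age = 1L, col_rate = 2L,
                               label = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < max(col_age, col_rate)) {
    stop("need at least ", max(col_age, col_rate), " columns in ", path,
         call. = FALSE)
  }
  first_numeric <- !anyNA(suppressWarnings(
    as.numeric(unlist(raw[1L, c(col_age, col_rate)]))
  ))
  body <- if (first_numeric) raw else raw[-1L, , drop = FALSE]
  offset <- if (first_numeric) 0L else 1L
  age <- suppressWarnings(as.numeric(body[[col_age]]))
  rate <- suppressWarnings(as.numeric(body[[col_rate]]))
  bad <- which(is.na(age) | is.na(rate))
  if (length(bad) > 0L) {
    stop("non-numeric cell in row ", bad[1L] + offset, " of ", path,
         call. = FALSE)
  }
  dup <- which(duplicated(age))
  if (length(dup) > 0L) {
    stop("duplicate age ", age[dup[1L]], " in row ", dup[1L] + offset,
         " of ", path, call. = FALSE)
  }
  ord <- order(age)
  out <- tibble::tibble(age = age[ord], rate = rate[ord])
  .check_series(out, allow_zero = TRUE)
  attr(out, "label") <- label %||% sub("\\.[^.]*$", "", basename(path))
  out
}

#' Write an age-incidence time series to CSV
#'
#' Writes `age,rate` with a header row and full double precision (17
#' significant digits), so that read/write round-trips reproduce the
#' series bit-identically.
#'
#' @param data A data frame with columns `age` and `rate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence_csv <- function(data, path) {
  .check_series(data, allow_zero = TRUE)
  lines <- c("age,rate",
             paste(sprintf("%.17g", data$age), sprintf("%.17g", data$rate),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Filter an incidence series for model fitting
#'
#' Removes data points with zero (or negative) incidence and points
#' below a minimum age. Ages where the registry recorded no cases carry
#' no information about the risk curve on the rate scale, and the
#' youngest age classes are excluded per dataset: 25 years for myeloma,
#' 12 for colon cancer, 10 for CML.
#'
#' @param data A data frame with columns `age` and `rate`.
#' @param min_age Minimum age (years) to retain.
#' @return A filtered tibble; errors if fewer than 2 points survive.
#'   The operation is idempotent.
#' @export
filter_series <- function(data, min_age = 0) {
  .check_series(data, allow_zero = TRUE)
  keep <- data$rate > 0 & data$age >= min_age
  out <- dplyr::filter(data, keep)
  if (nrow(out) < 2L) {
    stop("empty series: fewer than 2 points remain after filtering",
         call. = FALSE)
  }
  attr(out, "label") <- attr(data, "label")
  out
}

# shared validity checks for (age, rate) tables
.check_series <- function(data, allow_zero = FALSE) {
  if (!is.data.frame(data) || !all(c("age", "rate") %in% names(data))) {
    stop("expected a data frame with columns 'age' and 'rate'",
         call. = FALSE)
  }
  if (nrow(data) < 2L) stop("need at least 2 data points", call. = FALSE)
  if (any(!is.finite(data$age)) || any(!is.finite(data$rate))) {
    stop("non-finite age or rate", call. = FALSE)
  }
  if (any(data$age < 0)) stop("ages must be non-negative", call. = FALSE)
  if (is.unsorted(data$age, strictly = TRUE)) {
    stop("ages must be strictly increasing", call. = FALSE)
  }
  if (!allow_zero && any(data$rate <= 0)) {
    stop("rates must be positive (apply filter_series() first)",
         call. = FALSE)
  }
  invisible(data)
}

.series_label <- function(data) attr(data, "label") %||% "series"
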