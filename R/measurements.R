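#' Assemble a repeated-measurements series for two methods
#'
#' A measurement series holds the raw paired values of a gold-standard
#' (reference) method and an experimental (test) method, measured on the same
#' subjects at the same ordered time points. It is the input from which
#' consecutive-time differences -- the coordinates of the four-quadrant plot --
#' are derived.
#'
#' @param data A data frame in long layout with columns `subject`, `time`,
#'   `reference` and `test` (one row per subject and time point), or the
#'   long interchange layout with columns `subject`, `time`, `method`
#'   (`"reference"`/`"test"`) and `value`.
#' @return A tibble of class `measurement_series` with columns `subject`,
#'   `time` (integer index in stored order), `reference`, `test`.
#'   Rows are ordered by subject then time.
#' @details Times are kept in their stored order; no re-sorting by the time
#'   label's value is performed. Rows with missing values are rejected: the
#'   downstream model has no missing-data mechanism.
#' @examples
#' df <- data.frame(subject = rep(1:2, each = 3), time = rep(1:3, 2),
#'                  reference = c(1, 2, 3, 4, 3, 5), test = c(5, 5, 4, 4, 4, 6))
#' as_measurement_series(df)
#' @export
as_measurement_series <- function(data) {
  stopifnot(is.data.frame(data))
  if (all(c("method", "value") %in% names(data)) && !"reference" %in% names(data)) {
    bad <- setdiff(unique(data$method), c("reference", "test"))
    if (length(bad) > 0) {
      quadconc_abort(
        paste0("`method` must be 'reference' or 'test'; found: ",
               paste(bad, collapse = ", ")),
        "quadconc_error_parse")
    }
    data <- tidyr::pivot_wider(data, id_cols = c("subject", "time"),
                               names_from = "method", values_from = "value")
  }
  req <- c("subject", "time", "reference", "test")
  if (!all(req %in% names(data))) {
    quadconc_abort(
      paste0("measurement data needs columns ",
             paste(req, collapse = ", ")),
      "quadconc_error_parse")
  }
  out <- tibble::as_tibble(data[req])
  if (anyNA(out)) {
    quadconc_abort("missing values in measurement data; rows must be complete",
                   "quadconc_error_missing")
  }
  # time index in stored (not sorted-by-value) order
  time_levels <- unique(out$time)
  out$time <- match(out$time, time_levels)
  counts <- table(out$subject)
  if (length(unique(counts)) != 1) {
    quadconc_abort("all subjects must share the same set of time points",
                   "quadconc_error_shape")
  }
  if (unique(counts) < 2) {
    quadconc_abort("need at least two time points per subject to form differences",
                   "quadconc_error_config")
  }
  out <- dplyr::arrange(out, match(.data$subject, unique(out$subject)), .data$time)
  class(out) <- c("measurement_series", class(out))
  out
}

#' Read a two-method measurement CSV
#'
#' Auto-detects the layout from the header: the long interchange layout
#' (`subject_id`, `time`, `method`, `value`) or the wide layout
#' (`subject_id`, `reference_t1..`, `test_t1..`).
#'
#' @param path Path to a CSV file.
#' @return A [as_measurement_series()] tibble.
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df)[names(df) == "subject_id"] <- "subject"
  if (all(c("method", "value") %in% names(df))) {
    return(as_measurement_series(df))
  }
  ref_cols <- grep("^reference_t[0-9]+$", names(df), value = TRUE)
  test_cols <- grep("^test_t[0-9]+$", names(df), value = TRUE)
  if (length(ref_cols) == 0 || length(ref_cols) != length(test_cols)) {
    quadconc_abort("unrecognised CSV layout: need long (subject_id,time,method,value) or wide (reference_t*/test_t*) columns",
                   "quadconc_error_parse")
  }
  ord <- order(as.integer(sub("^reference_t", "", ref_cols)))
  ref_cols <- ref_cols[ord]
  test_cols <- paste0("test_t", sub("^reference_t", "", ref_cols))
  long <- tibble::tibble(
    subject = rep(df$subject, times = length(ref_cols)),
    time = rep(seq_along(ref_cols), each = nrow(df)),
    reference = unlist(df[ref_cols], use.names = FALSE),
    test = unlist(df[test_cols], use.names = FALSE)
  )
  as_measurement_series(long)
}

#' Write a measurement series to CSV (long interchange layout)
#'
#' @param series A `measurement_series` (or coercible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(series, path) {
  series <- as_measurement_series(series)
  long <- tidyr::pivot_longer(series, c("reference", "test"),
                              names_to = "method", values_to = "value")
  long <- dplyr::rename(long, subject_id = "subject")
  readr::write_csv(long[c("subject_id", "time", "method", "value")], path)
  invisible(path)
}

#' Consecutive-time differences: the four-quadrant plot coordinates
#'
#' For each subject, forms x_t = reference(t+1) - reference(t) and
#' y_t = test(t+1) - test(t), t = 1..T, where T + 1 is the number of stored
#' time points. Each (x_t, y_t) pair is one point of the four-quadrant plot.
#'
#' @param series A `measurement_series` or a data frame accepted by
#'   [as_measurement_series()]. Alternatively a data frame that already has
#'   columns `subject`, `t`, `x`, `y` is passed through unchanged.
#' @return A tibble of class `trend_differences` with columns `subject`,
#'   `t` (1..T) and the difference pair `x`, `y`.
#' @examples
#' df <- data.frame(subject = 1, time = 1:3, reference = c(1, 2, 3),
#'                  test = c(5, 5, 4))
#' trend_differences(df)   # x = (1, 1), y = (0, -1)
#' @export
trend_differences <- function(series) {
  if (is.data.frame(series) && all(c("subject", "t", "x", "y") %in% names(series))) {
    return(as_trend_differences(series))
  }
  series <- as_measurement_series(series)
  out <- series |>
    dplyr::group_by(.data$subject) |>
    dplyr::reframe(t = .data$time[-length(.data$time)],
                   x = diff(.data$reference),
                   y = diff(.data$test))
  as_trend_differences(out)
}

#' @rdname trend_differences
#' @param data A data frame with columns `subject`, `t`, `x`, `y`.
#' @export
as_trend_differences <- function(data) {
  req <- c("subject", "t", "x", "y")
  if (!all(req %in% names(data))) {
    quadconc_abort("difference data needs columns subject, t, x, y",
                   "quadconc_error_parse")
  }
  out <- tibble::as_tibble(data[req])
  if (anyNA(out)) {
    quadconc_abort("missing values in difference data", "quadconc_error_missing")
  }
  if (!inherits(out, "trend_differences")) {
    class(out) <- c("trend_differences", class(out))
  }
  out
}

# internal: n x T matrices (subjects in first-appearance order) from tidy diffs
diff_matrices <- function(diffs) {
  subjects <- unique(diffs$subject)
  tt <- sort(unique(diffs$t))
  i <- match(diffs$subject, subjects)
  j <- match(diffs$t, tt)
  x <- matrix(NA_real_, length(subjects), length(tt))
  y <- x
  x[cbind(i, j)] <- diffs$x
  y[cbind(i, j)] <- diffs$y
  if (anyNA(x) || anyNA(y)) {
    quadconc_abort("unbalanced difference table: every subject needs every t",
                   "quadconc_error_shape")
  }
  list(x = x, y = y, subjects = subjects, T = length(tt))
}

#' Classify four-quadrant points into quadrants and the exclusion zone
#'
#' Quadrant convention (boundaries on an axis go to the ">= 0" side):
#' A: x >= 0, y >= 0; B: x < 0, y < 0; C: x < 0, y >= 0; D: x >= 0, y < 0.
#' A point is an agreement iff it lies in A or B (both methods moved the same
#' direction). The exclusion flag is true iff -a <= x <= a and -a <= y <= a:
#' changes that small are treated as noise.
#'
#' @param diffs A `trend_differences` table (or data frame with
#'   `subject`, `t`, `x`, `y`).
#' @param a Exclusion-zone half-width, a nonnegative scalar.
#' @return The input tibble with added columns `quadrant` (factor A/B/C/D),
#'   `excluded` (logical) and `agreement` (logical).
#' @examples
#' d <- data.frame(subject = 1, t = 1:3, x = c(2, 0, 0.3), y = c(3, 0, -0.2))
#' classify_trends(d, a = 0.5)
#' @export
classify_trends <- function(diffs, a) {
  stopifnot(is.numeric(a), length(a) == 1, a >= 0)
  diffs <- as_trend_differences(diffs)
  diffs$quadrant <- quadrant_of(diffs$x, diffs$y)
  diffs$excluded <- abs(diffs$x) <= a & abs(diffs$y) <= a
  diffs$agreement <- diffs$quadrant %in% c("A", "B")
  diffs
}

# vectorised quadrant classification (partition of the plane)
quadrant_of <- function(x, y) {
  q <- ifelse(x >= 0,
              ifelse(y >= 0, "A", "D"),
              ifelse(y >= 0, "C", "B"))
  factor(q, levels = c("A", "B", "C", "D"))
}
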