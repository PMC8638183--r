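#' Conventional concordance rate of the four-quadrant plot
#'
#' The classical trending-agreement index: the fraction of pooled
#' four-quadrant points in the agreement quadrants, after removing points in
#' the central exclusion zone,
#' \deqn{CCR(a) = \frac{\#SA - \#AEz(a)}{nT - \#Ez(a)},}
#' where SA are the agreement points (x >= 0, y >= 0 or x < 0, y < 0), Ez(a)
#' the points with |x| <= a and |y| <= a, and AEz(a) the agreement points
#' inside the exclusion zone, with the positive cell taken closed
#' (0 <= x, y <= a) and the negative cell open (-a < x, y < 0). All n x T
#' points are pooled; subject identity is ignored -- this is precisely the
#' property that motivates the model-based rate in
#' [proposed_concordance()].
#'
#' The closed/open asymmetry of the AEz cells is honoured verbatim; for
#' continuous data the distinction is measure-zero.
#'
#' @inheritParams classify_trends
#' @return An object of class `ccr_result`: a list with `rate`,
#'   `n_agreement_outside` (#SA - #AEz), `n_total_outside` (nT - #Ez),
#'   `n_excluded` (#Ez), `n_points` and `a`. [tidy()] and [glance()] methods
#'   return one-row tibbles.
#' @examples
#' d <- data.frame(subject = 1:4, t = 1, x = c(2, -1, 1, 0.2),
#'                 y = c(3, -2, -1, 0.1))
#' conventional_concordance(d, a = 0.5)$rate  # 2/3
#' @export
conventional_concordance <- function(diffs, a) {
  diffs <- as_trend_differences(diffs)
  if (nrow(diffs) == 0) {
    quadconc_abort("no four-quadrant points", "quadconc_error_config")
  }
  ccr_from_xy(diffs$x, diffs$y, a)
}

# counting core on bare coordinate vectors (hot path for the simulation)
ccr_from_xy <- function(x, y, a) {
  stopifnot(is.numeric(a), length(a) == 1, a >= 0)
  agree <- (x >= 0 & y >= 0) | (x < 0 & y < 0)
  ez <- abs(x) <= a & abs(y) <= a
  aez <- (x >= 0 & x <= a & y >= 0 & y <= a) |
    (x > -a & x < 0 & y > -a & y < 0)
  n_sa <- sum(agree)
  n_ez <- sum(ez)
  n_aez <- sum(aez)
  denom <- length(x) - n_ez
  if (denom == 0) {
    quadconc_abort(
      "all four-quadrant points fall in the exclusion zone; CCR undefined",
      "quadconc_error_undefined_rate",
      n_excluded = n_ez, n_points = length(x))
  }
  structure(
    list(rate = (n_sa - n_aez) / denom,
         n_agreement_outside = n_sa - n_aez,
         n_total_outside = denom,
         n_excluded = n_ez,
         n_points = length(x),
         a = a),
    class = "ccr_result")
}

#' @export
print.ccr_result <- function(x, ...) {
  cat(sprintf("Conventional concordance rate (a = %g)\n", x$a))
  cat(sprintf("  rate = %.4f  (%d agreements / %d points outside the exclusion zone; %d excluded)\n",
              x$rate, x$n_agreement_outside, x$n_total_outside, x$n_excluded))
  invisible(x)
}

#' @export
tidy.ccr_result <- function(x, ...) {
  tibble::tibble(
    method = "ccr", rate = x$rate,
    n_agreement_outside = x$n_agreement_outside,
    n_total_outside = x$n_total_outside,
    n_excluded = x$n_excluded, a = x$a)
}

#' @export
glance.ccr_result <- function(x, ...) {
  tibble::tibble(rate = x$rate, n_points = x$n_points, a = x$a)
}
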