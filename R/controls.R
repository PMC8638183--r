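#' Per-time agreement counts among subjects never inside the exclusion zone
#'
#' The inputs of the two binomial control estimators. A subject is eligible
#' when none of its T four-quadrant points falls inside the exclusion zone
#' (the same conditioning as the model-based rate); `k[t]` counts eligible
#' subjects whose point at time t lies in an agreement quadrant, and
#' `n_dagger[t]` the eligible subjects. Under the default any-time
#' eligibility rule `n_dagger` is constant in t; `eligibility = "per_time"`
#' instead keeps a subject at the time points where it is outside the zone
#' (a sensitivity variant).
#'
#' @inheritParams classify_trends
#' @param eligibility `"any_time"` (default) or `"per_time"`.
#' @return A list of class `control_inputs` with `k`, `n_dagger` (length-T
#'   integer vectors), `T`, `a` and `eligibility`.
#' @export
count_control_inputs <- function(diffs, a, eligibility = c("any_time", "per_time")) {
  eligibility <- match.arg(eligibility)
  diffs <- as_trend_differences(diffs)
  m <- diff_matrices(diffs)
  control_inputs_from_xy(m$x, m$y, a, eligibility)
}

control_inputs_from_xy <- function(x, y, a, eligibility = "any_time") {
  stopifnot(is.numeric(a), length(a) == 1, a >= 0)
  agree <- (x >= 0 & y >= 0) | (x < 0 & y < 0)
  ez <- abs(x) <= a & abs(y) <= a
  if (eligibility == "any_time") {
    keep <- rowSums(ez) == 0            # outside the zone at every time
    k <- colSums(agree & keep)
    n_dagger <- rep(sum(keep), ncol(x))
  } else {
    k <- colSums(agree & !ez)
    n_dagger <- colSums(!ez)
  }
  if (all(n_dagger == 0)) {
    quadconc_abort("no eligible subjects outside the exclusion zone",
                   "quadconc_error_undefined_rate")
  }
  structure(list(k = as.integer(k), n_dagger = as.integer(n_dagger),
                 T = ncol(x), a = a, eligibility = eligibility),
            class = "control_inputs")
}

#' Binomial control estimators of "at least m of T" agreement
#'
#' Two binomial-model extensions of the conventional concordance rate to the
#' repeated-measurement question "does the trend agree at least m times out
#' of T?". `control1_rate` pools the agreement counts into a single success
#' probability p = sum(k) / sum(n_dagger) and returns the binomial tail
#' P(X >= m), X ~ Bin(T, p). `control2_rate` keeps a per-time probability
#' p_t = k_t / n_dagger_t and returns the Poisson-binomial tail
#' P(sum_t Bernoulli(p_t) >= m), computed by exact convolution (for T = 2,
#' m = 2 this is p1 p2; for m = 1 it is p1 p2 + p1 (1 - p2) + (1 - p1) p2).
#'
#' @param inputs A `control_inputs` object from [count_control_inputs()].
#' @param m Minimum number of agreeing time points, 1 <= m <= T.
#' @return A single probability.
#' @examples
#' ci <- structure(list(k = c(3L, 4L), n_dagger = c(5L, 5L), T = 2L,
#'                      a = 0.5, eligibility = "any_time"),
#'                 class = "control_inputs")
#' control1_rate(ci, m = 2)  # p = 0.7 -> 0.49
#' control2_rate(ci, m = 2)  # 0.6 * 0.8 = 0.48
#' @export
control1_rate <- function(inputs, m) {
  check_control_m(inputs, m)
  if (sum(inputs$n_dagger) == 0) {
    quadconc_abort("no eligible subjects", "quadconc_error_undefined_rate")
  }
  p <- sum(inputs$k) / sum(inputs$n_dagger)
  sum(stats::dbinom(m:inputs$T, inputs$T, p))
}

#' @rdname control1_rate
#' @export
control2_rate <- function(inputs, m) {
  check_control_m(inputs, m)
  if (any(inputs$n_dagger == 0)) {
    quadconc_abort("a time point has no eligible subjects",
                   "quadconc_error_undefined_rate")
  }
  p <- inputs$k / inputs$n_dagger
  sum(poisson_binomial_pmf(p)[(m + 1):(inputs$T + 1)])
}

check_control_m <- function(inputs, m) {
  stopifnot(inherits(inputs, "control_inputs"),
            length(m) == 1, m == as.integer(m), m >= 1, m <= inputs$T)
}

# exact pmf of a sum of independent Bernoulli(p_t), by convolution;
# returns P(S = 0..T)
poisson_binomial_pmf <- function(p) {
  pmf <- 1
  for (pt in p) pmf <- c(pmf * (1 - pt), 0) + c(0, pmf * pt)
  pmf
}

#' Control concordance estimate from difference pairs
#'
#' Convenience pipeline wrapper: counts the control inputs and evaluates one
#' of the two binomial control estimators.
#'
#' @inheritParams count_control_inputs
#' @inheritParams control1_rate
#' @param type `1` (pooled binomial) or `2` (per-time Poisson binomial).
#' @return A one-row tibble with `method`, `rate`, `m`, `a` and the counts.
#' @export
control_concordance <- function(diffs, a, m, type = 1,
                                eligibility = c("any_time", "per_time")) {
  stopifnot(type %in% c(1, 2))
  inputs <- count_control_inputs(diffs, a, eligibility)
  rate <- if (type == 1) control1_rate(inputs, m) else control2_rate(inputs, m)
  tibble::tibble(method = paste0("control", type), rate = rate, m = m, a = a,
                 n_eligible = max(inputs$n_dagger))
}
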