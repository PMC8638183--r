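#' Monte Carlo estimate of the model-based concordance rate
#'
#' Brute-force realization of the conditional probability that defines the
#' model-based rate: draw z ~ N(mean, sigma), classify each draw's T
#' difference pairs, and take the ratio
#' (draws outside the exclusion zone at every t with >= m agreements) /
#' (draws outside the exclusion zone at every t). Serves as the independent
#' cross-check of the analytic signed-rectangle path; it is not a user-facing
#' estimator.
#'
#' @inheritParams proposed_rate
#' @param n_draws Number of Monte Carlo draws (>= 1e4).
#' @param seed Integer seed; estimates are reproducible given the seed.
#' @return An object of class `mc_estimate`: list with `estimate`,
#'   `std_error` (binomial, from the conditional sample size), `n_draws`,
#'   `n_conditional` (draws surviving the conditioning event) and `seed`.
#' @export
mc_proposed_rate <- function(params, a, m, n_draws = 1e6, seed = 1L) {
  stopifnot(inherits(params, "mvn_params"), n_draws >= 1e4,
            is.numeric(a), a >= 0, m >= 1, m <= params$T)
  TT <- params$T
  z <- with_fixed_seed(seed, mvtnorm::rmvnorm(n_draws, mean = params$mean,
                                              sigma = params$sigma))
  x <- z[, 1:TT, drop = FALSE]
  y <- z[, TT + (1:TT), drop = FALSE]
  in_ez <- abs(x) <= a & abs(y) <= a
  outside <- rowSums(in_ez) == 0
  n_cond <- sum(outside)
  if (n_cond == 0) {
    quadconc_abort("no draws survived the exclusion-zone conditioning",
                   "quadconc_error_undefined_rate")
  }
  agree <- (x >= 0 & y >= 0) | (x < 0 & y < 0)
  hits <- rowSums(agree) >= m & outside
  est <- sum(hits) / n_cond
  structure(list(estimate = est,
                 std_error = sqrt(est * (1 - est) / n_cond),
                 n_draws = n_draws, n_conditional = n_cond,
                 seed = as.integer(seed)),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("Monte Carlo concordance rate: %.5f (SE %.5f, %d/%d conditional draws)\n",
              x$estimate, x$std_error, x$n_conditional, x$n_draws))
  invisible(x)
}
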