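#' Fit the multivariate normal model to the difference pairs
#'
#' Stacks each subject's difference pairs into the 2T-vector
#' z_i = (x_i1..x_iT, y_i1..y_iT) and estimates the mean vector by the sample
#' mean and the covariance matrix by the unbiased (n - 1) sample covariance.
#' All subjects contribute, including points inside the exclusion zone: the
#' exclusion zone enters the model-based rate only through the conditioning
#' event, not through data deletion.
#'
#' @inheritParams classify_trends
#' @return An object of class `mvn_params`: a list with `mean` (length 2T),
#'   `sigma` (2T x 2T), `T` and `n`.
#' @export
estimate_mvn_params <- function(diffs) {
  diffs <- as_trend_differences(diffs)
  m <- diff_matrices(diffs)
  z <- cbind(m$x, m$y)
  if (nrow(z) < 2) {
    quadconc_abort("need at least two subjects to estimate the covariance",
                   "quadconc_error_estimation")
  }
  mvn_params(colMeans(z), stats::cov(z), n = nrow(z))
}

#' @rdname estimate_mvn_params
#' @param mean Length-2T mean vector, coordinate order (X_1..X_T, Y_1..Y_T).
#' @param sigma 2T x 2T symmetric positive-semidefinite covariance matrix.
#' @param n Optional number of subjects the parameters were estimated from.
#' @export
mvn_params <- function(mean, sigma, n = NA_integer_) {
  mean <- as.numeric(mean)
  sigma <- as.matrix(sigma)
  d <- length(mean)
  if (d %% 2 != 0 || d < 2 || !all(dim(sigma) == d)) {
    quadconc_abort("mean must have even length 2T and sigma matching dimension",
                   "quadconc_error_config")
  }
  if (max(abs(sigma - t(sigma))) > 1e-10) {
    quadconc_abort("covariance matrix is not symmetric", "quadconc_error_config")
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    quadconc_abort("covariance matrix is not positive semidefinite",
                   "quadconc_error_config")
  }
  structure(list(mean = mean, sigma = (sigma + t(sigma)) / 2,
                 T = d %/% 2L, n = n),
            class = "mvn_params")
}

#' @export
print.mvn_params <- function(x, ...) {
  cat(sprintf("Multivariate normal model for %d difference pairs (dimension %d)\n",
              x$T, 2 * x$T))
  cat("mean:", signif(x$mean, 4), "\n")
  invisible(x)
}

# ridge-regularize a near-singular covariance; small samples (n ~ 10) can
# produce singular 2T x 2T estimates
regularize_covariance <- function(sigma) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  scale <- mean(diag(sigma))
  if (scale <= 0) scale <- 1
  floor_ev <- 1e-8 * scale
  if (min(ev) < floor_ev) {
    warn("near-singular covariance; adding a small ridge for integration",
         class = "quadconc_warning_regularization")
    sigma <- sigma + diag(floor_ev - min(ev) + floor_ev, nrow(sigma))
  }
  sigma
}

#' Multivariate normal rectangle probability
#'
#' P(lower < Z < upper) for Z ~ N(mean, sigma), the integration primitive of
#' the model-based concordance rate. Coordinates that are unconstrained
#' (-Inf, Inf) are marginalised out before integration. The backend is
#' mvtnorm's Genz-Bretz quasi-Monte-Carlo algorithm run under a locally
#' fixed seed, so repeated calls agree bit for bit while the caller's RNG
#' state is untouched.
#'
#' @param params An `mvn_params` object.
#' @param lower,upper Numeric bound vectors of length 2T (may contain
#'   `-Inf`/`Inf`).
#' @param abseps Absolute accuracy target of the integrator.
#' @param maxpts Integration point budget per call; larger is slower and
#'   more accurate.
#' @return The probability, with attribute `error` (the integrator's
#'   absolute error estimate).
#' @examples
#' p <- mvn_params(c(0, 0), matrix(c(1, 1/3, 1/3, 1), 2))
#' rectangle_probability(p, c(0, 0), c(Inf, Inf))  # 1/4 + asin(1/3)/(2*pi)
#' @export
rectangle_probability <- function(params, lower, upper, abseps = 1e-6,
                                  maxpts = 50000L) {
  stopifnot(inherits(params, "mvn_params"))
  d <- length(params$mean)
  stopifnot(length(lower) == d, length(upper) == d)
  if (any(lower > upper)) {
    quadconc_abort("lower bound exceeds upper bound", "quadconc_error_config")
  }
  sigma <- regularize_covariance(params$sigma)
  pmv_rect(lower, upper, params$mean, sigma, abseps, maxpts)
}

# integration core; assumes sigma already regularized
pmv_rect <- function(lower, upper, mean, sigma, abseps = 1e-6,
                     maxpts = 50000L) {
  keep <- !(lower == -Inf & upper == Inf)
  if (!any(keep)) {
    return(structure(1, error = 0))
  }
  lower <- lower[keep]; upper <- upper[keep]
  mean <- mean[keep]; sigma <- sigma[keep, keep, drop = FALSE]
  if (any(lower >= upper)) {
    return(structure(0, error = 0))  # degenerate (measure-zero) rectangle
  }
  p <- with_fixed_seed(271828L, mvtnorm::pmvnorm(
    lower, upper, mean = mean, sigma = sigma,
    algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = maxpts)))
  structure(max(0, min(1, as.numeric(p))), error = attr(p, "error"))
}

#' Signed rectangles for one agreement pattern
#'
#' Expands the event "agreement exactly at the flagged time points, and
#' outside the exclusion zone at every time point" into axis-aligned
#' rectangles with +/-1 weights, using, per time point t,
#' \deqn{1_{Q_1} + 1_{Q_2} - 1_{EzQ_1} - 1_{EzQ_2},}
#' where the two quadrants Q are the agreement quadrants (upper-right A,
#' lower-left B) when t is flagged, and the disagreement quadrants
#' (upper-left C, lower-right D) otherwise, and EzQ is the quadrant's cell
#' of the exclusion zone. The product over t yields up to 4^T signed
#' 2T-dimensional rectangles whose weighted probabilities sum to the
#' pattern's probability mass. Rectangles with a measure-zero side (a = 0
#' exclusion cells) are dropped. Coordinate order is (X_1..X_T, Y_1..Y_T).
#'
#' @param agrees Logical vector of length T: which time points agree.
#' @param a Exclusion-zone half-width.
#' @return A list with matrices `lower`, `upper` (rows = rectangles,
#'   columns = 2T coordinates) and the vector `weight`.
#' @export
agreement_rectangles <- function(agrees, a) {
  stopifnot(is.logical(agrees), length(agrees) >= 1, a >= 0)
  TT <- length(agrees)
  # per-time cell table: X-lower, X-upper, Y-lower, Y-upper, weight
  cells <- function(agree) {
    if (agree) {
      rbind(c(0, Inf, 0, Inf, 1),      # A
            c(-Inf, 0, -Inf, 0, 1),    # B
            c(0, a, 0, a, -1),         # EzA
            c(-a, 0, -a, 0, -1))       # EzB
    } else {
      rbind(c(-Inf, 0, 0, Inf, 1),     # C
            c(0, Inf, -Inf, 0, 1),     # D
            c(-a, 0, 0, a, -1),        # EzC
            c(0, a, -a, 0, -1))        # EzD
    }
  }
  choice <- expand.grid(rep(list(1:4), TT))
  k <- nrow(choice)
  lower <- matrix(0, k, 2 * TT)
  upper <- matrix(0, k, 2 * TT)
  weight <- rep(1, k)
  for (t in seq_len(TT)) {
    tab <- cells(agrees[t])
    idx <- choice[[t]]
    lower[, t] <- tab[idx, 1]
    upper[, t] <- tab[idx, 2]
    lower[, TT + t] <- tab[idx, 3]
    upper[, TT + t] <- tab[idx, 4]
    weight <- weight * tab[idx, 5]
  }
  # drop rectangles that are measure-zero (possible when a = 0)
  keep <- rowSums(upper <= lower) == 0
  list(lower = lower[keep, , drop = FALSE],
       upper = upper[keep, , drop = FALSE],
       weight = weight[keep])
}

# all agreement patterns (logical matrix, one row per pattern) with
# rowSums in [from, to]
agreement_patterns <- function(TT, from, to = TT) {
  pat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), TT)))
  colnames(pat) <- NULL
  pat[rowSums(pat) >= from & rowSums(pat) <= to, , drop = FALSE]
}

# signed probability mass of one agreement pattern (intersected with NEz)
pattern_mass <- function(agrees, a, mean, sigma, abseps = 1e-6,
                         maxpts = 50000L) {
  rects <- agreement_rectangles(agrees, a)
  total <- 0
  err <- 0
  for (r in seq_along(rects$weight)) {
    p <- pmv_rect(rects$lower[r, ], rects$upper[r, ], mean, sigma,
                  abseps, maxpts)
    total <- total + rects$weight[r] * p
    err <- err + attr(p, "error")
  }
  structure(total, error = err)
}

# P[union of per-time exclusion-zone events] by inclusion-exclusion over
# nonempty subsets of time points
exclusion_union_mass <- function(TT, a, mean, sigma, abseps = 1e-6,
                                 maxpts = 50000L) {
  total <- 0
  err <- 0
  subsets <- agreement_patterns(TT, 1)  # reuse: nonempty subsets of 1..T
  for (r in seq_len(nrow(subsets))) {
    s <- subsets[r, ]
    lower <- rep(-Inf, 2 * TT); upper <- rep(Inf, 2 * TT)
    lower[c(which(s), TT + which(s))] <- -a
    upper[c(which(s), TT + which(s))] <- a
    p <- pmv_rect(lower, upper, mean, sigma, abseps, maxpts)
    total <- total + (-1)^(sum(s) + 1) * p
    err <- err + attr(p, "error")
  }
  structure(total, error = err)
}

#' Model-based concordance rate from fitted normal parameters
#'
#' The conditional probability that the two methods' trends agree at least m
#' of T times, given that no time point's difference pair falls in the
#' exclusion zone, under Z ~ N(mean, sigma):
#' \deqn{P[\cup_{t=m}^{T} H_t \mid NEz(a)]
#'   = \frac{\sum_{t=m}^{T} P[H_t \cap NEz(a)]}{1 - P[\cup_s Ez_s(a)]},}
#' where H_t is the event of exactly t agreements. Numerator terms are
#' evaluated exactly by the signed-rectangle expansion of
#' [agreement_rectangles()]; the denominator by inclusion-exclusion over the
#' per-time exclusion events. Cost grows as O(8^T) rectangle integrals, so T
#' is capped (default 6).
#'
#' @param params An `mvn_params` object (2T-dimensional).
#' @param a Exclusion-zone half-width (>= 0).
#' @param m Minimum number of agreements, 1 <= m <= T.
#' @param per_t If `TRUE` (default) the numerator is accumulated per
#'   agreement count t = m..T and reported in `per_t_numerators`. If `FALSE`
#'   and the complementary set of patterns is smaller, the numerator is
#'   computed as denominator mass minus the below-m patterns (same value by
#'   the partition of unity, fewer integrals).
#' @inheritParams rectangle_probability
#' @param max_T Safety cap on T.
#' @param denominator_floor Smallest admissible denominator; below it the
#'   model mass is essentially all inside the exclusion zone and the rate is
#'   undefined.
#' @return An object of class `proposed_rate_result`: list with `rate`,
#'   `numerator`, `denominator`, `per_t_numerators` (named, or `NULL` when
#'   `per_t = FALSE` took the complement route), `integration_error`, `a`,
#'   `m`, `T`.
#' @examples
#' p <- mvn_params(rep(0, 4), diag(4))
#' proposed_rate(p, a = 0.5, m = 2)$rate  # 0.25 by symmetry
#' @export
proposed_rate <- function(params, a, m, per_t = TRUE,
                          abseps = 1e-6, maxpts = 50000L, max_T = 6L,
                          denominator_floor = 1e-10) {
  stopifnot(inherits(params, "mvn_params"),
            is.numeric(a), length(a) == 1, a >= 0,
            length(m) == 1, m == as.integer(m))
  TT <- params$T
  if (m < 1 || m > TT) {
    quadconc_abort("m must lie in 1..T", "quadconc_error_config")
  }
  if (TT > max_T) {
    quadconc_abort(sprintf("T = %d exceeds max_T = %d (cost grows as 8^T)", TT, max_T),
                   "quadconc_error_config")
  }
  sigma <- regularize_covariance(params$sigma)
  mean <- params$mean

  ez_mass <- exclusion_union_mass(TT, a, mean, sigma, abseps, maxpts)
  denominator <- 1 - as.numeric(ez_mass)
  err <- attr(ez_mass, "error")
  if (denominator < denominator_floor) {
    quadconc_abort(
      "fitted distribution is concentrated in the exclusion zone; rate undefined",
      "quadconc_error_undefined_rate")
  }

  n_above <- sum(choose(TT, m:TT))
  n_below <- 2^TT - n_above
  per_t_numerators <- NULL
  if (per_t || n_above <= n_below) {
    masses <- numeric(TT - m + 1)
    for (t in m:TT) {
      pats <- agreement_patterns(TT, t, t)
      tot <- 0
      for (r in seq_len(nrow(pats))) {
        pm <- pattern_mass(pats[r, ], a, mean, sigma, abseps, maxpts)
        tot <- tot + as.numeric(pm)
        err <- err + attr(pm, "error")
      }
      masses[t - m + 1] <- tot
    }
    per_t_numerators <- setNames(masses, paste0("t", m:TT))
    numerator <- sum(masses)
  } else {
    # complement route: numerator = P[NEz] - sum of below-m pattern masses
    numerator <- denominator
    pats <- agreement_patterns(TT, 0, m - 1)
    for (r in seq_len(nrow(pats))) {
      pm <- pattern_mass(pats[r, ], a, mean, sigma, abseps, maxpts)
      numerator <- numerator - as.numeric(pm)
      err <- err + attr(pm, "error")
    }
  }

  # signed-sum cancellation can leave tiny negatives
  tol <- max(err, 1e-9)
  if (numerator < 0) {
    if (numerator < -tol) {
      warn(sprintf("numerator clipped to 0 (was %.3e, beyond tolerance %.1e)",
                   numerator, tol),
           class = "quadconc_warning_clipping")
    }
    numerator <- 0
  }
  rate <- numerator / denominator
  if (rate > 1) {
    if (rate - 1 > tol) {
      warn(sprintf("rate clipped to 1 (was 1 + %.3e)", rate - 1),
           class = "quadconc_warning_clipping")
    }
    rate <- 1
  }
  structure(list(rate = rate, numerator = numerator, denominator = denominator,
                 per_t_numerators = per_t_numerators,
                 integration_error = err, a = a, m = as.integer(m), T = TT),
            class = "proposed_rate_result")
}

#' @export
print.proposed_rate_result <- function(x, ...) {
  cat(sprintf("Model-based concordance rate (T = %d, m = %d, a = %g)\n",
              x$T, x$m, x$a))
  cat(sprintf("  rate = %.4f  (numerator %.4f / denominator %.4f)\n",
              x$rate, x$numerator, x$denominator))
  invisible(x)
}

#' Model-based concordance rate from difference pairs
#'
#' Pipeline wrapper: fits the multivariate normal model with
#' [estimate_mvn_params()] (all points, including those inside the exclusion
#' zone) and evaluates [proposed_rate()].
#'
#' @inheritParams classify_trends
#' @inheritParams proposed_rate
#' @param ... Passed on to [proposed_rate()].
#' @return An object of class `proposed_concordance`: the
#'   `proposed_rate_result` plus the fitted `params`. `tidy()` returns the
#'   per-t numerator breakdown; `glance()` a one-row summary.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(subject = rep(1:20, each = 2), t = rep(1:2, 20),
#'                     x = rnorm(40, 1), y = rnorm(40, 1))
#' proposed_concordance(d, a = 0.5, m = 2)
#' @export
proposed_concordance <- function(diffs, a, m, ...) {
  params <- estimate_mvn_params(diffs)
  res <- proposed_rate(params, a = a, m = m, ...)
  res$params <- params
  class(res) <- c("proposed_concordance", class(res))
  res
}

#' @export
tidy.proposed_concordance <- function(x, ...) {
  if (is.null(x$per_t_numerators)) {
    return(tibble::tibble(term = "numerator", mass = x$numerator))
  }
  tibble::tibble(term = names(x$per_t_numerators),
                 n_agreements = x$m:x$T,
                 mass = unname(x$per_t_numerators),
                 conditional_probability = unname(x$per_t_numerators) / x$denominator)
}

#' @export
glance.proposed_concordance <- function(x, ...) {
  tibble::tibble(rate = x$rate, numerator = x$numerator,
                 denominator = x$denominator,
                 integration_error = x$integration_error,
                 T = x$T, m = x$m, a = x$a,
                 n_subjects = x$params$n)
}
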