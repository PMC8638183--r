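test_that("parameter estimation is the sample mean and unbiased covariance of
           the stacked difference vectors", {
  d <- data.frame(subject = rep(1:2, each = 2), t = rep(1:2, 2),
                  x = c(1, 1, 3, 3), y = c(1, 1, 3, 3))
  p <- estimate_mvn_params(d)
  expect_equal(p$mean, rep(2, 4))
  expect_equal(p$sigma, matrix(2, 4, 4))
  expect_equal(p$T, 2L)

  # identical subjects: zero covariance (regularized downstream)
  d0 <- data.frame(subject = rep(1:3, each = 2), t = rep(1:2, 3),
                   x = rep(c(1, 2), 3), y = rep(c(0.5, -1), 3))
  expect_equal(estimate_mvn_params(d0)$sigma, matrix(0, 4, 4))

  expect_error(estimate_mvn_params(d[d$subject == 1, ]),
               class = "quadconc_error_estimation")
})

test_that("estimation recovers known parameters from a large sample", {
  mu <- c(1.5, -0.5, 1, 0.5)
  sigma <- simulation_covariance(1 / 3, 1 / 3)
  n <- 1000
  z <- with_seed(42, mvtnorm::rmvnorm(n, mu, sigma))
  d <- data.frame(subject = rep(1:n, 2), t = rep(1:2, each = n),
                  x = c(z[, 1], z[, 2]), y = c(z[, 3], z[, 4]))
  p <- estimate_mvn_params(d)
  se <- sqrt(diag(sigma) / n)
  expect_true(all(abs(p$mean - mu) < 5 * se))
  expect_lt(max(abs(p$sigma - sigma)), 0.15)
})

test_that("rectangle probabilities match closed forms", {
  # bivariate orthant identity
  p2 <- mvn_params(c(0, 0), matrix(c(1, 1 / 3, 1 / 3, 1), 2))
  expect_equal(as.numeric(rectangle_probability(p2, c(0, 0), c(Inf, Inf))),
               1 / 4 + asin(1 / 3) / (2 * pi), tolerance = 1e-6)
  # independent coordinates: product form on the unit cube
  p4 <- mvn_params(rep(0, 4), diag(4))
  expect_equal(as.numeric(rectangle_probability(p4, rep(0, 4), rep(1, 4))),
               (pnorm(1) - pnorm(0))^4, tolerance = 1e-6)
  # normalization
  expect_equal(as.numeric(rectangle_probability(p4, rep(-Inf, 4), rep(Inf, 4))), 1)
  expect_error(rectangle_probability(p4, rep(1, 4), rep(0, 4)),
               class = "quadconc_error_config")
})

test_that("the general rectangle enumerator reproduces the hand-coded T = 2
           both-agree expansion term by term", {
  a <- 0.7
  got <- agreement_rectangles(c(TRUE, TRUE), a)
  expect_equal(length(got$weight), 16L)
  hand <- hand_rectangles_T2_agree_agree(a)
  expect_equal(length(hand), 16L)
  hand_lower <- t(vapply(hand, `[[`, numeric(4), "lower"))
  hand_upper <- t(vapply(hand, `[[`, numeric(4), "upper"))
  hand_weight <- vapply(hand, `[[`, numeric(1), "weight")
  expect_equal(rect_key(got$lower, got$upper, got$weight),
               rect_key(hand_lower, hand_upper, hand_weight))
})

test_that("enumerator base and degenerate cases", {
  # T = 1 agree: A, B with their exclusion cells subtracted
  r <- agreement_rectangles(TRUE, a = 0.5)
  expect_equal(sort(r$weight), c(-1, -1, 1, 1))
  expect_equal(length(r$weight), 4L)
  # a = 0: exclusion cells are measure-zero and dropped, 2^T quadrant boxes stay
  r0 <- agreement_rectangles(c(TRUE, FALSE), a = 0)
  expect_equal(length(r0$weight), 4L)
  expect_true(all(r0$weight == 1))
})

test_that("the model-based rate has the symmetric closed-form limits", {
  p <- mvn_params(rep(0, 4), diag(4))
  for (a in c(0, 0.5, 1)) {
    expect_equal(proposed_rate(p, a = a, m = 2)$rate, 0.25, tolerance = 2e-5)
    expect_equal(proposed_rate(p, a = a, m = 1)$rate, 0.75, tolerance = 2e-5)
  }
})

test_that("per-t and complement numerator routes agree", {
  for (seed in 1:4) {
    pp <- random_sim_params(seed)
    for (a in c(0, 0.5)) {
      r1 <- suppressWarnings(proposed_rate(pp, a = a, m = 1, per_t = TRUE))
      r2 <- suppressWarnings(proposed_rate(pp, a = a, m = 1, per_t = FALSE))
      expect_equal(r1$rate, r2$rate, tolerance = 1e-4)
      expect_null(r2$per_t_numerators)
      expect_equal(length(r1$per_t_numerators), 2L)
    }
  }
})

test_that("rate is monotone non-increasing in m and symmetric under method swap", {
  for (seed in 5:8) {
    pp <- random_sim_params(seed)
    r1 <- proposed_rate(pp, a = 0.5, m = 1)$rate
    r2 <- proposed_rate(pp, a = 0.5, m = 2)$rate
    expect_gte(r1, r2 - 1e-5)
    # swap the X and Y blocks
    TT <- pp$T
    idx <- c(TT + 1:TT, 1:TT)
    swapped <- mvn_params(pp$mean[idx], pp$sigma[idx, idx])
    expect_equal(proposed_rate(swapped, a = 0.5, m = 2)$rate, r2,
                 tolerance = 1e-4)
  }
})

test_that("partition of unity holds across T = 1, 2, 3", {
  for (TT in 1:3) {
    for (seed in 1:3) {
      mu <- with_seed(seed, rnorm(2 * TT, sd = 1))
      A <- with_seed(seed + 50, matrix(rnorm((2 * TT)^2), 2 * TT))
      sigma <- crossprod(A) / (2 * TT) + diag(0.3, 2 * TT)
      a <- c(0, 0.4, 0.8)[seed]
      total <- 0
      for (t in 0:TT) {
        pats <- agreement_patterns(TT, t, t)
        for (i in seq_len(nrow(pats))) {
          total <- total + as.numeric(
            quadconc:::pattern_mass(pats[i, ], a, mu, sigma,
                                    abseps = 1e-8, maxpts = 5e5))
        }
      }
      denom <- 1 - as.numeric(
        quadconc:::exclusion_union_mass(TT, a, mu, sigma,
                                        abseps = 1e-8, maxpts = 5e5))
      expect_lt(abs(total - denom), 1e-5)
    }
  }
})

test_that("rate is invariant under joint positive rescaling of data and a", {
  pp <- random_sim_params(11)
  c0 <- 2.9
  scaled <- mvn_params(pp$mean * c0, pp$sigma * c0^2)
  expect_equal(proposed_rate(scaled, a = 0.5 * c0, m = 2)$rate,
               proposed_rate(pp, a = 0.5, m = 2)$rate, tolerance = 1e-4)
})

test_that("degenerate inputs are surfaced as errors or regularized", {
  p <- mvn_params(rep(0, 4), diag(4))
  expect_error(proposed_rate(p, a = 0.5, m = 3), class = "quadconc_error_config")
  expect_error(proposed_rate(p, a = 0.5, m = 0), class = "quadconc_error_config")
  # distribution entirely inside the exclusion zone
  tiny <- mvn_params(rep(0, 4), diag(1e-18, 4))
  expect_error(suppressWarnings(proposed_rate(tiny, a = 1, m = 2)),
               class = "quadconc_error_undefined_rate")
  # singular covariance triggers the regularization warning, not an error
  d0 <- data.frame(subject = rep(1:3, each = 2), t = rep(1:2, 3),
                   x = rep(c(1, 2), 3), y = rep(c(0.5, -1), 3))
  p0 <- estimate_mvn_params(d0)
  expect_warning(r <- proposed_rate(p0, a = 0.1, m = 2),
                 class = "quadconc_warning_regularization")
  expect_true(r$rate >= 0 && r$rate <= 1)
})

test_that("the pipeline wrapper exposes tidy and glance summaries", {
  d <- with_seed(3, data.frame(subject = rep(1:25, each = 2), t = rep(1:2, 25),
                               x = rnorm(50, 1), y = rnorm(50, 1)))
  pc <- proposed_concordance(d, a = 0.5, m = 1)
  td <- tidy(pc)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$mass), pc$numerator)
  gl <- glance(pc)
  expect_equal(gl$rate, pc$rate)
  expect_equal(gl$n_subjects, 25L)
})
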