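# shared fixtures and independent oracles for the test suite

# toy four-point dataset used across CCR/CLI tests
toy_points <- function() {
  tibble::tibble(subject = 1:4, t = 1L,
                 x = c(2, -1, 1, 0.2), y = c(3, -2, -1, 0.1))
}

# random but realistic 4-d parameter set: estimated from a dataset drawn
# under the factorial design (so covariances are well-conditioned and the
# means span agree/disagree regimes)
random_sim_params <- function(seed) {
  grid <- simulation_grid()
  cfg <- grid[with_seed(seed, sample.int(nrow(grid), 1)), ]
  d <- generate_dataset(cfg, replicate = 1 + seed %% 7, master_seed = seed)
  estimate_mvn_params(d)
}

with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# brute-force recount of the control inputs by explicit subject enumeration
brute_control_inputs <- function(diffs, a) {
  subs <- unique(diffs$subject)
  tt <- sort(unique(diffs$t))
  eligible <- vapply(subs, function(s) {
    d <- diffs[diffs$subject == s, ]
    all(!(abs(d$x) <= a & abs(d$y) <= a))
  }, TRUE)
  k <- vapply(tt, function(t0) {
    sum(vapply(subs[eligible], function(s) {
      d <- diffs[diffs$subject == s & diffs$t == t0, ]
      (d$x >= 0 && d$y >= 0) || (d$x < 0 && d$y < 0)
    }, TRUE))
  }, 0L)
  list(k = as.integer(k), n_dagger = rep(sum(eligible), length(tt)))
}

# hand transcription of the published T = 2 both-agree signed sum:
# quadrant ranges F = {[0,Inf], [-Inf,0]}, exclusion ranges E = {[0,a],[-a,0]},
# X_t and Y_t constrained to the same interval at each time (agreement),
# with + for FF and EE blocks and - for the two mixed blocks
hand_rectangles_T2_agree_agree <- function(a) {
  f <- list(c(0, Inf), c(-Inf, 0))
  e <- list(c(0, a), c(-a, 0))
  out <- list()
  add <- function(v1, v2, w) {
    out[[length(out) + 1]] <<- list(
      lower = c(v1[1], v2[1], v1[1], v2[1]),
      upper = c(v1[2], v2[2], v1[2], v2[2]),
      weight = w)
  }
  for (set1 in list(list(s = f, w = 1), list(s = e, w = 1))) {
    for (v1 in set1$s) for (v2 in set1$s) add(v1, v2, set1$w)
  }
  for (v1 in f) for (v2 in e) add_mixed(out, v1, v2) -> out
  for (v1 in e) for (v2 in f) add_mixed(out, v1, v2) -> out
  out
}

add_mixed <- function(out, v1, v2) {
  out[[length(out) + 1]] <- list(
    lower = c(v1[1], v2[1], v1[1], v2[1]),
    upper = c(v1[2], v2[2], v1[2], v2[2]),
    weight = -1)
  out
}

# canonical sort key for comparing rectangle sets
rect_key <- function(lower, upper, weight) {
  k <- apply(cbind(lower, upper, weight), 1, paste, collapse = "|")
  sort(k)
}
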