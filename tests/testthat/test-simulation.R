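test_that("the factor grid reproduces the design bookkeeping", {
  grid <- simulation_grid()
  expect_equal(nrow(grid), 1440)
  cells <- grid_cell_count(grid)
  expect_equal(cells$n_cells[cells$m == 1], 2160)
  expect_equal(cells$n_cells[cells$m == 2], 2880)
  expect_equal(sum(cells$n_cells), 5040)
  expect_equal(nrow(grid) * 100, 144000)  # labelled datasets at full scale
})

test_that("mean patterns carry the published labels", {
  pats <- mean_patterns()
  expect_equal(nrow(pats), 30)
  # spot rows against the published table
  expect_equal(unlist(pats[1, 2:5], use.names = FALSE), c(-1.5, -1.5, 1.5, 1.5))
  expect_false(pats$label1[1]); expect_false(pats$label2[1])
  expect_false(pats$label1[3]); expect_true(pats$label2[3])
  expect_true(pats$label1[5]); expect_true(pats$label2[5])
  expect_true(pats$label1[11]); expect_true(pats$label2[11])
  expect_false(pats$label1[15]); expect_false(pats$label2[15])
  expect_true(pats$label1[23]); expect_true(pats$label2[23])
  # label1 implies label2 everywhere; magnitudes are 0.5 or 1.5
  expect_true(all(!pats$label1 | pats$label2))
  expect_true(all(abs(as.matrix(pats[, 2:5])) %in% c(0.5, 1.5)))
  # labels equal the sign-agreement definition
  for (i in seq_len(nrow(pats))) {
    lab <- true_label(unlist(pats[i, 2:5], use.names = FALSE))
    expect_equal(lab$label1, pats$label1[i])
    expect_equal(lab$label2, pats$label2[i])
  }
  expect_error(true_label(c(0, 1, 1, 1)), class = "quadconc_error_config")
})

test_that("the simulation covariance has the designed structure", {
  s <- simulation_covariance(2 / 3, 1 / 3)
  expect_equal(diag(s), rep(1, 4))
  expect_equal(s[1, 2], 2 / 3)
  expect_equal(s[3, 4], 2 / 3)
  expect_true(all(s[1:2, 3:4] == 1 / 3))
  expect_error(simulation_covariance(1.2, 1.1), class = "quadconc_error_config")
})

test_that("dataset generation is seeded, deterministic, and has the right
           moments", {
  grid <- simulation_grid()
  cfg <- grid[grid$pattern == 5 & grid$rho == 0 & grid$rho_xy == 0 &
                grid$a == 0.5 & grid$n_subjects == 40 & grid$m == 2, ]
  d1 <- generate_dataset(cfg, replicate = 1, master_seed = 11)
  d2 <- generate_dataset(cfg, replicate = 1, master_seed = 11)
  expect_identical(d1, d2)
  d3 <- generate_dataset(cfg, replicate = 2, master_seed = 11)
  expect_false(identical(d1, d3))
  expect_equal(nrow(d1), 80)  # 40 subjects x T = 2

  # pattern 5: all means 1.5; average many replicates
  means <- colMeans(do.call(rbind, lapply(1:25, function(r) {
    d <- generate_dataset(cfg, r, master_seed = 7)
    c(mean(d$x), mean(d$y))
  })))
  expect_true(all(abs(means - 1.5) < 5 / sqrt(40 * 25)))

  # rho = 2/3 shows up in the sample correlation of (X1, X2)
  cfg2 <- grid[grid$pattern == 5 & grid$rho == 2 / 3 & grid$rho_xy == 0 &
                 grid$a == 0.5 & grid$n_subjects == 40 & grid$m == 2, ]
  cors <- vapply(1:40, function(r) {
    d <- generate_dataset(cfg2, r, master_seed = 13)
    m <- quadconc:::diff_matrices(d)
    cor(m$x[, 1], m$x[, 2])
  }, 0)
  expect_lt(abs(mean(cors) - 2 / 3), 0.1)
})

test_that("the runner computes every applicable estimator per dataset and is
           reproducible", {
  grid <- simulation_grid()
  one_m2 <- grid[grid$pattern == 5 & grid$rho == 1 / 3 & grid$rho_xy == 0 &
                   grid$a == 0.5 & grid$n_subjects == 15 & grid$m == 2, ]
  est <- run_simulation(one_m2, n_replicates = 10, master_seed = 3)
  expect_equal(nrow(est), 40)  # 4 methods x 10 replicates
  expect_setequal(unique(est$method), c("proposal", "ccr", "control1", "control2"))

  one_m1 <- dplyr::mutate(one_m2, m = 1L)
  est1 <- run_simulation(one_m1, n_replicates = 2, master_seed = 3)
  expect_equal(nrow(est1), 6)  # 3 methods x 2 replicates
  expect_false("ccr" %in% est1$method)

  est_b <- run_simulation(one_m2, n_replicates = 10, master_seed = 3)
  expect_identical(est$rate, est_b$rate)
})

test_that("strong-agreement mean patterns score above strong-disagreement ones
           for every estimator", {
  grid <- simulation_grid()
  sub <- grid[grid$pattern %in% c(1, 5) & grid$rho == 1 / 3 &
                grid$rho_xy == 1 / 3 & grid$a == 0.5 &
                grid$n_subjects == 40 & grid$m == 2, ]
  est <- run_simulation(sub, n_replicates = 20, master_seed = 17)
  means <- est |>
    dplyr::summarise(mean_rate = mean(rate, na.rm = TRUE),
                     .by = c("pattern", "method"))
  wide <- tidyr::pivot_wider(means, names_from = "pattern",
                             values_from = "mean_rate", names_prefix = "p")
  expect_true(all(wide$p5 > wide$p1))
})

test_that("sharing datasets across m reuses draws while independent generation
           does not", {
  grid <- simulation_grid()
  pair <- grid[grid$pattern == 5 & grid$rho == 0 & grid$rho_xy == 0 &
                 grid$a == 0.5 & grid$n_subjects == 15, ]
  expect_equal(nrow(pair), 2)  # m = 1 and m = 2
  shared <- run_simulation(pair, n_replicates = 3, master_seed = 5,
                           share_across_m = TRUE)
  cc <- shared[shared$method == "control1" & shared$replicate == 1, ]
  expect_equal(cc$rate[cc$m == 1] >= cc$rate[cc$m == 2], TRUE)
  # under sharing, control1 at m = 1 and m = 2 derive from the same dataset:
  # identical pooled p, so rate(m=1) = 1 - (1-p)^2 and rate(m=2) = p^2 match
  p1 <- cc$rate[cc$m == 1]; p2 <- cc$rate[cc$m == 2]
  expect_equal(1 - (1 - sqrt(p2))^2, p1, tolerance = 1e-10)
})
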