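#' The 30 mean patterns of the simulation design
#'
#' Mean vectors (mu_x1, mu_x2, mu_y1, mu_y2) of the 4-dimensional normal
#' difference model, covering combinations of effect magnitude (0.5, 1.5) and
#' direction of change, together with the derived ground-truth labels:
#' `label1` (trends of the population means agree at both time points) and
#' `label2` (agree at least once).
#'
#' @return A 30-row tibble with columns `pattern`, `mu_x1`, `mu_x2`, `mu_y1`,
#'   `mu_y2`, `label1`, `label2`.
#' @export
mean_patterns <- function() {
  m <- matrix(c(
    -1.5, -1.5,  1.5,  1.5,
    -0.5, -0.5,  0.5,  0.5,
    -1.5,  1.5,  1.5,  1.5,
     0.5, -0.5,  0.5,  0.5,
     1.5,  1.5,  1.5,  1.5,
     0.5,  0.5,  0.5,  0.5,
    -0.5, -1.5,  0.5,  1.5,
     0.5, -1.5,  0.5,  1.5,
    -0.5,  1.5,  0.5,  1.5,
     0.5,  1.5,  0.5,  1.5,
    -1.5, -1.5, -1.5, -1.5,
    -0.5, -0.5, -0.5, -0.5,
    -1.5,  1.5, -1.5, -1.5,
     0.5, -0.5, -0.5, -0.5,
     1.5,  1.5, -1.5, -1.5,
     0.5,  0.5, -0.5, -0.5,
    -0.5, -1.5, -0.5, -1.5,
     0.5, -1.5, -0.5, -1.5,
    -0.5,  1.5, -0.5, -1.5,
     0.5,  1.5, -0.5, -1.5,
    -1.5, -1.5, -1.5,  1.5,
    -0.5, -0.5, -0.5,  0.5,
    -1.5,  1.5, -1.5,  1.5,
     0.5, -0.5, -0.5,  0.5,
     1.5,  1.5, -1.5,  1.5,
     0.5,  0.5, -0.5,  0.5,
    -0.5, -1.5, -0.5,  1.5,
     0.5, -1.5, -0.5,  1.5,
    -0.5,  1.5, -0.5,  1.5,
     0.5,  1.5, -0.5,  1.5), ncol = 4, byrow = TRUE)
  labels <- t(apply(m, 1, function(mu) unlist(true_label(mu))))
  tibble::tibble(pattern = 1:30,
                 mu_x1 = m[, 1], mu_x2 = m[, 2],
                 mu_y1 = m[, 3], mu_y2 = m[, 4],
                 label1 = labels[, 1], label2 = labels[, 2])
}

#' Ground-truth trend labels of a mean pattern
#'
#' For a mean vector (mu_x1..mu_xT, mu_y1..mu_yT), time point t counts as a
#' population-level agreement when sign(mu_xt) == sign(mu_yt). `label1` is
#' agreement at every time point, `label2` at least one.
#'
#' @param mu Numeric mean vector of even length 2T, no zero entries.
#' @return A list with logical `label1` and `label2`.
#' @export
true_label <- function(mu) {
  if (any(mu == 0)) {
    quadconc_abort("zero mean component: trend direction undefined",
                   "quadconc_error_config")
  }
  TT <- length(mu) %/% 2
  agree <- sign(mu[1:TT]) == sign(mu[TT + 1:TT])
  list(label1 = all(agree), label2 = any(agree))
}

#' Covariance matrix of the simulated 4-dimensional difference model
#'
#' Unit variances; within-method covariance `rho` between the two
#' consecutive-time differences of each method; between-method covariance
#' `rho_xy` in every cross cell.
#'
#' @param rho Within-method covariance (between X1 and X2, and Y1 and Y2).
#' @param rho_xy Between-method covariance (all four X-Y cells).
#' @return A 4 x 4 positive-definite covariance matrix, coordinate order
#'   (X1, X2, Y1, Y2).
#' @export
simulation_covariance <- function(rho, rho_xy) {
  s_within <- matrix(c(1, rho, rho, 1), 2)
  s_cross <- matrix(rho_xy, 2, 2)
  sigma <- rbind(cbind(s_within, s_cross), cbind(s_cross, s_within))
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    quadconc_abort("covariance settings give a non-positive-definite matrix",
                   "quadconc_error_config")
  }
  sigma
}

#' Full factorial grid of the simulation study
#'
#' Crosses the mean patterns with the covariance, exclusion-zone, sample-size
#' and minimum-agreement factors. With the default levels this yields 1440
#' data-generating configurations; counting the applicable estimators (four
#' at m = 2, three at m = 1 -- the conventional rate has no "m of T" notion)
#' gives 2880 + 2160 = 5040 method-by-configuration cells.
#'
#' @param patterns Mean-pattern indices (default 1:30, see [mean_patterns()]).
#' @param rho Within-method covariance levels.
#' @param rho_xy Between-method covariance levels.
#' @param a Exclusion-zone half-widths.
#' @param n_subjects Numbers of subjects.
#' @param m Minimum-agreement levels.
#' @return A tibble with one row per configuration (`config_id`, factor
#'   columns, mean components and labels).
#' @export
simulation_grid <- function(patterns = 1:30,
                            rho = c(0, 1/3, 2/3),
                            rho_xy = c(0, 1/3),
                            a = c(0.5, 1.0),
                            n_subjects = c(15L, 40L),
                            m = c(1L, 2L)) {
  pats <- mean_patterns()
  stopifnot(all(patterns %in% pats$pattern))
  grid <- tidyr::expand_grid(pattern = patterns, rho = rho, rho_xy = rho_xy,
                             a = a, n_subjects = as.integer(n_subjects),
                             m = as.integer(m))
  grid <- dplyr::left_join(grid, pats, by = "pattern")
  grid$config_id <- seq_len(nrow(grid))
  dplyr::relocate(grid, "config_id")
}

#' Count estimator-by-configuration cells of a simulation grid
#'
#' @param grid A tibble from [simulation_grid()].
#' @return A tibble with one row per m level (`m`, `n_configs`, `n_methods`,
#'   `n_cells`) -- 2160 cells at m = 1 and 2880 at m = 2 for the full grid.
#' @export
grid_cell_count <- function(grid) {
  grid |>
    dplyr::count(.data$m, name = "n_configs") |>
    dplyr::mutate(n_methods = ifelse(.data$m == 2, 4L, 3L),
                  n_cells = .data$n_configs * .data$n_methods)
}

# deterministic per-dataset seed (< 2^31) from (master, config, replicate)
dataset_seed <- function(master_seed, config_id, replicate) {
  (as.double(master_seed) * 2654435761 + config_id * 40503 + replicate) %%
    2147483563 + 1
}

#' Generate one simulated dataset of difference pairs
#'
#' Draws `n_subjects` i.i.d. 4-vectors (X1, X2, Y1, Y2) from
#' N(mu_Z, Sigma_Z): the consecutive-time differences are simulated directly,
#' not derived from raw three-point series. Seeding is a deterministic map
#' from (master_seed, config_id, replicate) so any single dataset can be
#' regenerated in isolation.
#'
#' @param config One row of [simulation_grid()] (or a list with `pattern`,
#'   `rho`, `rho_xy`, `n_subjects`, `mu_x1`, `mu_x2`, `mu_y1`, `mu_y2`,
#'   `config_id`).
#' @param replicate Replicate number (1-based).
#' @param master_seed Integer master seed of the whole study.
#' @return A `trend_differences` tibble with `n_subjects` subjects and T = 2.
#' @export
generate_dataset <- function(config, replicate, master_seed = 20211201L) {
  mu <- c(config$mu_x1, config$mu_x2, config$mu_y1, config$mu_y2)
  sigma <- simulation_covariance(config$rho, config$rho_xy)
  seed <- dataset_seed(master_seed, config$config_id, replicate)
  z <- with_fixed_seed(seed, mvtnorm::rmvnorm(config$n_subjects, mean = mu,
                                              sigma = sigma))
  as_trend_differences(tibble::tibble(
    subject = rep(seq_len(config$n_subjects), times = 2),
    t = rep(1:2, each = config$n_subjects),
    x = c(z[, 1], z[, 2]),
    y = c(z[, 3], z[, 4])))
}

# all estimators applicable at one m level
methods_for_m <- function(m) {
  if (m == 2) c("proposal", "ccr", "control1", "control2")
  else c("proposal", "control1", "control2")
}

#' Run the simulation study
#'
#' For every configuration and replicate, generates one dataset and computes
#' every applicable estimator on it (the same dataset is shared across
#' estimators within a cell): the model-based rate, the conventional rate
#' (m = 2 only), and the two binomial controls. Estimators that are undefined
#' on a dataset (e.g. every point inside the exclusion zone) are recorded as
#' `NA` with a note rather than raised.
#'
#' @param grid A tibble from [simulation_grid()] (possibly a subset).
#' @param n_replicates Datasets per configuration (the full design uses 100).
#' @param master_seed Integer master seed.
#' @param share_across_m If `TRUE`, configurations differing only in m reuse
#'   the same datasets (seed keyed on the factors excluding m). Default
#'   `FALSE`: independent datasets per configuration.
#' @param progress Print a progress line every `progress` configurations
#'   (0 = silent).
#' @return A tibble with one row per (configuration, replicate, method):
#'   factor columns, `replicate`, `method`, `rate` (NA when undefined) and
#'   the labels.
#' @export
run_simulation <- function(grid, n_replicates = 100, master_seed = 20211201L,
                           share_across_m = FALSE, progress = 0) {
  stopifnot(nrow(grid) > 0, n_replicates >= 1)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- grid[g, ]
    seed_id <- if (share_across_m) {
      # key on the data-generating factors only
      with(cfg, pattern * 100000 + round(rho * 300) * 1000 +
             round(rho_xy * 300) * 100 + a * 10 + n_subjects)
    } else {
      cfg$config_id
    }
    methods <- methods_for_m(cfg$m)
    rows <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      d <- generate_dataset(
        list(config_id = seed_id, pattern = cfg$pattern, rho = cfg$rho,
             rho_xy = cfg$rho_xy, n_subjects = cfg$n_subjects,
             mu_x1 = cfg$mu_x1, mu_x2 = cfg$mu_x2,
             mu_y1 = cfg$mu_y1, mu_y2 = cfg$mu_y2),
        r, master_seed)
      rows[[r]] <- estimate_all(d, cfg$a, cfg$m, methods)
    }
    res <- dplyr::bind_rows(rows)
    res$replicate <- rep(seq_len(n_replicates), each = length(methods))
    out[[g]] <- dplyr::bind_cols(
      cfg[rep(1, nrow(res)), c("config_id", "pattern", "rho", "rho_xy", "a",
                               "n_subjects", "m", "label1", "label2")],
      res)
    if (progress > 0 && g %% progress == 0) {
      message(sprintf("simulated %d / %d configurations", g, nrow(grid)))
    }
  }
  dplyr::bind_rows(out)
}

# all applicable estimators on one dataset; undefined -> NA + note
estimate_all <- function(diffs, a, m, methods) {
  mats <- diff_matrices(diffs)
  rate <- rep(NA_real_, length(methods))
  note <- rep(NA_character_, length(methods))
  inputs <- tryCatch(control_inputs_from_xy(mats$x, mats$y, a),
                     quadconc_error = function(e) e)
  for (i in seq_along(methods)) {
    res <- tryCatch({
      switch(methods[i],
        proposal = {
          z <- cbind(mats$x, mats$y)
          params <- mvn_params(colMeans(z), stats::cov(z), n = nrow(z))
          suppressWarnings(
            proposed_rate(params, a = a, m = m, per_t = FALSE,
                          maxpts = 8000L)$rate)
        },
        ccr = ccr_from_xy(diffs$x, diffs$y, a)$rate,
        control1 = {
          if (inherits(inputs, "condition")) stop(inputs)
          control1_rate(inputs, m)
        },
        control2 = {
          if (inherits(inputs, "condition")) stop(inputs)
          control2_rate(inputs, m)
        })
    }, quadconc_error = function(e) e)
    if (inherits(res, "condition")) {
      note[i] <- conditionMessage(res)
    } else {
      rate[i] <- res
    }
  }
  tibble::tibble(method = methods, rate = rate, note = note)
}
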