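#' ROC curve, AUC and Youden-index cutoff
#'
#' AUC is the Mann-Whitney rank statistic: the probability that a
#' positive-labelled score exceeds a negative-labelled one, ties counted
#' half. The ROC is traced over all distinct score thresholds with the
#' convention "predict positive when score >= threshold". The reported
#' cutoff maximizes the Youden index TPR - FPR; among maximizers the
#' smallest score is returned.
#'
#' @param scores Numeric vector of estimated concordance rates.
#' @param labels Logical (or 0/1) vector of true agreement labels.
#' @return An object of class `quadconc_roc`: list with `auc`, `cutoff`,
#'   `roc_points` (tibble `threshold`, `fpr`, `tpr`), `n_positive`,
#'   `n_negative`.
#' @examples
#' r <- roc_auc(c(0.2, 0.4, 0.6, 0.8), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc     # 1
#' r$cutoff  # 0.6
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    quadconc_abort("both labels must be present to form an ROC",
                   "quadconc_error_evaluation")
  }
  rk <- rank(scores)                     # midranks: ties count half
  auc <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(c) sum(labels & scores >= c), 0L)
  fp <- vapply(thr, function(c) sum(!labels & scores >= c), 0L)
  roc <- tibble::tibble(threshold = c(Inf, thr),
                        fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  youden <- roc$tpr - roc$fpr
  best <- which(youden == max(youden))
  cutoff <- min(roc$threshold[best])
  structure(list(auc = auc, cutoff = cutoff, roc_points = roc,
                 n_positive = n1, n_negative = n0),
            class = "quadconc_roc")
}

#' @export
print.quadconc_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f, Youden cutoff = %.4f (%d positive / %d negative)\n",
              x$auc, x$cutoff, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
tidy.quadconc_roc <- function(x, ...) x$roc_points

#' @export
glance.quadconc_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff,
                 n_positive = x$n_positive, n_negative = x$n_negative)
}

#' Correct-classification fraction at a cutoff
#'
#' The fraction of estimates on the correct side of a cutoff given their
#' label: positives count when rate >= cutoff, negatives when rate < cutoff.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision threshold (typically the Youden cutoff of the
#'   pooled ROC).
#' @return A single number in [0, 1].
#' @export
q_statistic <- function(scores, labels, cutoff) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  if (length(scores) == 0) {
    quadconc_abort("no scores", "quadconc_error_evaluation")
  }
  mean(ifelse(labels, scores >= cutoff, scores < cutoff))
}

# consecutive-time difference matrix (n x T, rownames = subjects) of a
# single-method series with columns subject, time, value
single_method_diffs <- function(df) {
  stopifnot(is.data.frame(df), all(c("subject", "time", "value") %in% names(df)))
  if (anyNA(df[c("subject", "time", "value")])) {
    quadconc_abort("missing values in measurement data", "quadconc_error_missing")
  }
  subjects <- unique(df$subject)
  times <- unique(df$time)
  if (length(times) < 2) {
    quadconc_abort("need at least two time points", "quadconc_error_config")
  }
  v <- matrix(NA_real_, length(subjects), length(times))
  v[cbind(match(df$subject, subjects), match(df$time, times))] <- df$value
  if (anyNA(v)) {
    quadconc_abort("every subject needs a value at every time point",
                   "quadconc_error_shape")
  }
  d <- v[, -1, drop = FALSE] - v[, -ncol(v), drop = FALSE]
  rownames(d) <- as.character(subjects)
  d
}

# label column relevant at an m level: both-times agreement for m = 2,
# at-least-once for m = 1
label_for_m <- function(estimates) {
  ifelse(estimates$m == 2, estimates$label1, estimates$label2)
}

#' Diagnosability tables of a simulation run
#'
#' Summarises a [run_simulation()] estimate table into the evaluation
#' surfaces of the simulation study: (i) overall AUC per estimator and m
#' (labels: both-times agreement at m = 2, at-least-once at m = 1), with the
#' pooled Youden cutoff; (ii) AUC per level of each non-mean factor
#' (`rho`, `rho_xy`, `a`, `n_subjects`); (iii) the per-mean-pattern
#' correct-classification fraction q at the pooled cutoffs (the mean factor
#' has a single label per level, so no per-level ROC exists). Undefined
#' estimates are dropped with a reported count.
#'
#' @param estimates Tibble from [run_simulation()].
#' @return A list of class `simulation_evaluation` with tibbles `overall`,
#'   `by_factor`, `q_by_pattern` and the count `n_undefined`.
#' @export
evaluate_simulation <- function(estimates) {
  req <- c("pattern", "rho", "rho_xy", "a", "n_subjects", "m", "method",
           "rate", "label1", "label2")
  stopifnot(all(req %in% names(estimates)))
  estimates$label <- label_for_m(estimates)
  n_undefined <- sum(is.na(estimates$rate))
  est <- estimates[!is.na(estimates$rate), ]

  overall <- est |>
    dplyr::group_by(.data$m, .data$method) |>
    dplyr::group_modify(function(d, key) {
      r <- roc_auc(d$rate, d$label)
      tibble::tibble(auc = r$auc, cutoff = r$cutoff, n = nrow(d))
    }) |>
    dplyr::ungroup()

  by_factor <- purrr::map_dfr(
    c("rho", "rho_xy", "a", "n_subjects"),
    function(f) {
      est |>
        dplyr::group_by(level = .data[[f]], .data$m, .data$method) |>
        dplyr::group_modify(function(d, key) {
          tibble::tibble(auc = roc_auc(d$rate, d$label)$auc, n = nrow(d))
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(factor = f, .before = 1)
    })

  q_by_pattern <- est |>
    dplyr::left_join(overall[c("m", "method", "cutoff")],
                     by = c("m", "method")) |>
    dplyr::group_by(.data$pattern, .data$m, .data$method) |>
    dplyr::summarise(
      q = q_statistic(.data$rate, .data$label, .data$cutoff[1]),
      n = dplyr::n(), .groups = "drop")

  structure(list(overall = overall, by_factor = by_factor,
                 q_by_pattern = q_by_pattern, n_undefined = n_undefined),
            class = "simulation_evaluation")
}

#' @export
print.simulation_evaluation <- function(x, ...) {
  cat("Simulation evaluation\n\nOverall AUC:\n")
  print(tidyr::pivot_wider(x$overall[c("m", "method", "auc")],
                           names_from = "method", values_from = "auc"))
  cat(sprintf("\n%d undefined estimates dropped.\n", x$n_undefined))
  invisible(x)
}

#' Bootstrap diagnosability protocol for a triple-method study
#'
#' The real-data protocol: three measurement series on the same subjects
#' (two human observers J and R using the reference method, one automatic
#' machine S) form three method pairs (J,R), (R,S), (J,S). Each bootstrap
#' iteration draws `subjects_per_draw` subjects with replacement, and for
#' every pair sets the exclusion-zone half-width to the `a_quantile` quantile
#' of the pooled absolute differences of both pair members, then computes
#' the four estimators at `m` of T. The (J,R) pair is labelled "agreement"
#' (same underlying method) and the two machine pairs "disagreement"; the
#' labelled rates yield one ROC/AUC per estimator.
#'
#' @param j,r,s Single-method series: data frames with columns `subject`,
#'   `time`, `value`, covering identical subjects and time points.
#' @param n_iterations Bootstrap iterations (the reference protocol uses
#'   1000).
#' @param subjects_per_draw Subjects drawn with replacement per iteration
#'   (reference protocol: 10).
#' @param seed Integer seed.
#' @param m Minimum agreements (reference protocol: 2).
#' @param a_quantile Quantile of pooled |x|, |y| defining the exclusion-zone
#'   half-width.
#' @param a_scope `"per_draw"` (default): the quantile is recomputed on each
#'   bootstrap draw; `"global"`: computed once per pair on the full data.
#' @return A list of class `sbp_bootstrap` with `estimates` (tibble:
#'   `iteration`, `pair`, `label`, `method`, `rate`), `auc` (tibble per
#'   method with AUC and Youden cutoff) and `n_undefined`.
#' @export
sbp_bootstrap <- function(j, r, s, n_iterations = 1000, subjects_per_draw = 10,
                          seed = 1L, m = 2, a_quantile = 0.1,
                          a_scope = c("per_draw", "global")) {
  a_scope <- match.arg(a_scope)
  mats <- lapply(list(j = j, r = r, s = s), single_method_diffs)
  subj <- rownames(mats$j)
  if (!identical(subj, rownames(mats$r)) || !identical(subj, rownames(mats$s))) {
    quadconc_abort("the three series must cover identical subjects in the same order",
                   "quadconc_error_shape")
  }
  pairs <- list("J-R" = c("j", "r"), "R-S" = c("r", "s"), "J-S" = c("j", "s"))
  labels <- c("J-R" = TRUE, "R-S" = FALSE, "J-S" = FALSE)
  methods <- methods_for_m(m)

  global_a <- vapply(pairs, function(p) {
    quantile(c(abs(mats[[p[1]]]), abs(mats[[p[2]]])), a_quantile,
             names = FALSE)
  }, 0)

  n <- nrow(mats$j)
  draws <- with_fixed_seed(seed, matrix(
    sample.int(n, n_iterations * subjects_per_draw, replace = TRUE),
    n_iterations, subjects_per_draw))
  out <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    idx <- draws[it, ]
    rows <- vector("list", length(pairs))
    for (pi in seq_along(pairs)) {
      p <- pairs[[pi]]
      x <- mats[[p[1]]][idx, , drop = FALSE]
      y <- mats[[p[2]]][idx, , drop = FALSE]
      a <- if (a_scope == "global") global_a[pi] else {
        quantile(c(abs(x), abs(y)), a_quantile, names = FALSE)
      }
      d <- tibble::tibble(subject = rep(seq_len(nrow(x)), ncol(x)),
                          t = rep(seq_len(ncol(x)), each = nrow(x)),
                          x = c(x), y = c(y))
      est <- estimate_all(as_trend_differences(d), a, m, methods)
      est$iteration <- it
      est$pair <- names(pairs)[pi]
      est$label <- labels[pi]
      rows[[pi]] <- est
    }
    out[[it]] <- dplyr::bind_rows(rows)
  }
  estimates <- dplyr::bind_rows(out)
  n_undefined <- sum(is.na(estimates$rate))
  auc <- estimates |>
    dplyr::filter(!is.na(.data$rate)) |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(function(d, key) {
      rr <- roc_auc(d$rate, d$label)
      tibble::tibble(auc = rr$auc, cutoff = rr$cutoff, n = nrow(d))
    }) |>
    dplyr::ungroup()
  structure(list(estimates = estimates[c("iteration", "pair", "label",
                                         "method", "rate", "note")],
                 auc = auc, n_undefined = n_undefined,
                 m = m, a_quantile = a_quantile, a_scope = a_scope,
                 seed = as.integer(seed)),
            class = "sbp_bootstrap")
}

#' @export
print.sbp_bootstrap <- function(x, ...) {
  cat(sprintf("Triple-method bootstrap (%d iterations, m = %d)\n",
              max(x$estimates$iteration), x$m))
  print(x$auc)
  invisible(x)
}
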