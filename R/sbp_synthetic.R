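#' Synthetic triple-method blood-pressure-like dataset
#'
#' Generates a stand-in for a three-method repeated blood-pressure study:
#' two human observers (J, R) reading the same reference instrument, and an
#' automatic machine (S). Each subject has a latent systolic trajectory
#' (random level plus independent per-time shifts); J and R add independent
#' observer noise to the same latent values, so their consecutive-time
#' trends are highly concordant and their four-quadrant points lie near the
#' 45-degree line. S follows the latent level with a bias, an attenuated
#' coupling to the latent per-time shifts, and larger noise, so its trends
#' disagree with the observers' far more often. This reproduces the
#' qualitative concordant/discordant contrast of such studies, not any real
#' dataset's values.
#'
#' @param n_subjects Number of subjects (default 85).
#' @param n_times Time points per subject (default 3).
#' @param subject_level_sd SD of the per-subject latent level (mmHg).
#' @param trend_sd SD of the latent per-time shifts (mmHg); these drive the
#'   consecutive-time differences.
#' @param observer_noise_sd SD of the independent observer noise on J and R.
#' @param machine_bias Additive bias of the machine.
#' @param machine_noise_sd SD of the machine noise.
#' @param trend_attenuation Multiplier (in [0, 1]) on the latent shifts in
#'   the machine's signal; smaller values weaken its trend coupling.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of class `sbp_synthetic` with tibbles `j`, `r`, `s`
#'   (columns `subject`, `time`, `value`) and the generating spec.
#' @examples
#' synth <- simulate_sbp_series(n_subjects = 20, seed = 7)
#' head(synth$j)
#' @export
simulate_sbp_series <- function(n_subjects = 85, n_times = 3,
                                subject_level_sd = 15, trend_sd = 8,
                                observer_noise_sd = 3, machine_bias = 5,
                                machine_noise_sd = 8, trend_attenuation = 0.4,
                                seed = 1L) {
  stopifnot(n_subjects >= 1, n_times >= 2,
            subject_level_sd > 0, trend_sd > 0, observer_noise_sd > 0,
            machine_noise_sd > 0, trend_attenuation >= 0, trend_attenuation <= 1)
  rng <- with_fixed_seed(seed, {
    list(level = rnorm(n_subjects, sd = subject_level_sd),
         shift = rnorm(n_subjects * n_times, sd = trend_sd),
         je = rnorm(n_subjects * n_times, sd = observer_noise_sd),
         re = rnorm(n_subjects * n_times, sd = observer_noise_sd),
         se = rnorm(n_subjects * n_times, sd = machine_noise_sd))
  })
  level <- 125 + rng$level
  shift <- matrix(rng$shift, n_subjects, n_times)
  latent <- level + shift
  jv <- latent + matrix(rng$je, n_subjects, n_times)
  rv <- latent + matrix(rng$re, n_subjects, n_times)
  sv <- level + machine_bias + trend_attenuation * shift +
    matrix(rng$se, n_subjects, n_times)
  as_long <- function(v) {
    tibble::tibble(subject = rep(seq_len(n_subjects), times = n_times),
                   time = rep(seq_len(n_times), each = n_subjects),
                   value = c(v))
  }
  structure(list(j = as_long(jv), r = as_long(rv), s = as_long(sv),
                 spec = list(n_subjects = n_subjects, n_times = n_times,
                             subject_level_sd = subject_level_sd,
                             trend_sd = trend_sd,
                             observer_noise_sd = observer_noise_sd,
                             machine_bias = machine_bias,
                             machine_noise_sd = machine_noise_sd,
                             trend_attenuation = trend_attenuation,
                             seed = as.integer(seed))),
            class = "sbp_synthetic")
}

#' Write a synthetic triple-method dataset to CSV
#'
#' One long-layout CSV with columns `subject_id`, `time`, `method`
#' (`J`/`R`/`S`) and `value`; [read_sbp_csv()] reads it back.
#'
#' @param synth An `sbp_synthetic` object (or a named list of `j`, `r`, `s`
#'   tibbles with `subject`, `time`, `value`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbp_csv <- function(synth, path) {
  long <- dplyr::bind_rows(
    dplyr::mutate(synth$j, method = "J"),
    dplyr::mutate(synth$r, method = "R"),
    dplyr::mutate(synth$s, method = "S"))
  long <- dplyr::rename(long, subject_id = "subject")
  readr::write_csv(long[c("subject_id", "time", "method", "value")], path)
  invisible(path)
}

#' @rdname write_sbp_csv
#' @details `read_sbp_csv()` also ingests a user-supplied export of a real
#'   triple-method dataset, provided it uses the same four columns.
#' @export
read_sbp_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df)[names(df) == "subject_id"] <- "subject"
  stopifnot(all(c("subject", "time", "method", "value") %in% names(df)))
  methods <- sort(unique(df$method))
  if (!identical(methods, c("J", "R", "S"))) {
    quadconc_abort("expected exactly the methods J, R, S",
                   "quadconc_error_parse")
  }
  split_one <- function(mm) {
    out <- df[df$method == mm, c("subject", "time", "value")]
    tibble::as_tibble(out)
  }
  list(j = split_one("J"), r = split_one("R"), s = split_one("S"))
}
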