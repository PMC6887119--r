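#' Specification for a simulated luciferase recording
#'
#' A continuous reporter-activity recording: flat baseline with Gaussian
#' noise before translation onset, then a linear rise saturating at a
#' plateau. The onset time is the ground-truth full-translation time (FTT).
#' The default 3-minute sampling interval matches typical plate-reader
#' recordings of in vitro translation reactions.
#'
#' @param onset_time Onset (min, >= 0): first time at which signal rises.
#' @param rise_rate Linear rise rate after onset (RLU/min, > 0).
#' @param plateau Saturation level above baseline (RLU, > 0).
#' @param baseline Baseline signal (RLU).
#' @param baseline_noise_sd Gaussian noise SD (RLU, >= 0).
#' @param sampling_interval Sampling interval (min, > 0). Default 3.
#' @param duration Recording duration (min); must exceed `onset_time`.
#' @param seed Integer seed.
#' @return Object of class `curve_sim_spec`.
#' @export
curve_sim_spec <- function(onset_time = 9.5,
                           rise_rate = 100,
                           plateau = 2000,
                           baseline = 50,
                           baseline_noise_sd = 0,
                           sampling_interval = 3,
                           duration = 90,
                           seed = 1L) {
  .assert_scalar_num(onset_time, "onset_time", lower = 0)
  .assert_scalar_num(rise_rate, "rise_rate", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(sampling_interval, "sampling_interval", lower = 0,
                     strict_lower = TRUE)
  .assert_scalar_num(baseline_noise_sd, "baseline_noise_sd", lower = 0)
  if (duration <= onset_time)
    stop("duration must exceed onset_time", call. = FALSE)
  structure(list(onset_time = onset_time, rise_rate = rise_rate,
                 plateau = plateau, baseline = baseline,
                 baseline_noise_sd = baseline_noise_sd,
                 sampling_interval = sampling_interval,
                 duration = duration, seed = as.integer(seed)),
            class = "curve_sim_spec")
}

#' Simulate a luciferase activity curve with known onset
#'
#' @param spec A [curve_sim_spec()].
#' @param id Curve identifier stored in metadata.
#' @return List with `curve` (a `luc_curve`: data frame `time_min`,
#'   `signal` plus metadata attributes) and `truth` (list with
#'   `onset_time`).
#' @seealso [estimate_ftt()]
#' @export
gen_luc_curve <- function(spec, id = "curve_1") {
  stopifnot(inherits(spec, "curve_sim_spec"))
  set.seed(spec$seed)
  t <- seq(0, spec$duration, by = spec$sampling_interval)
  rise <- pmax(0, t - spec$onset_time) * spec$rise_rate
  signal <- spec$baseline + pmin(rise, spec$plateau)
  if (spec$baseline_noise_sd > 0)
    signal <- signal + rnorm(length(t), 0, spec$baseline_noise_sd)
  list(curve = luc_curve(t, signal, id = id),
       truth = list(onset_time = spec$onset_time))
}

#' Construct a luciferase recording object
#'
#' @param time_min Strictly increasing times in minutes (>= 5 points).
#' @param signal Finite signal values (RLU), same length.
#' @param id,treatment Optional metadata strings.
#' @return A `luc_curve` data frame.
#' @export
luc_curve <- function(time_min, signal, id = NA_character_,
                      treatment = NA_character_) {
  if (length(time_min) < 5L) stop("need >= 5 time points", call. = FALSE)
  if (any(diff(time_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(signal) != length(time_min) || any(!is.finite(signal)))
    stop("signal must be finite, one value per time point", call. = FALSE)
  structure(data.frame(time_min = time_min, signal = signal),
            id = id, treatment = treatment,
            class = c("luc_curve", "data.frame"))
}

#' Simulate a median-effect dose-response table
#'
#' Affected fractions follow the median-effect relation
#' `fa / (1 - fa) = (d / Dm)^m` plus Gaussian noise (clamped to `[0, 1]`).
#' At `d = Dm` the noiseless effect is exactly 0.5 (the definition of the
#' median-effect dose); at `d = 0` it is 0.
#'
#' @param Dm Median-effect dose (> 0).
#' @param m Sigmoidicity exponent (> 0).
#' @param doses Non-negative dose vector.
#' @param noise_sd Gaussian noise SD on the affected fraction (default 0).
#' @param seed Integer seed.
#' @return Data frame `(dose, fa)` of class `dose_response`.
#' @seealso [median_effect_fit()]
#' @export
gen_dose_response <- function(Dm, m, doses, noise_sd = 0, seed = 1L) {
  .assert_scalar_num(Dm, "Dm", lower = 0, strict_lower = TRUE)
  .assert_scalar_num(m, "m", lower = 0, strict_lower = TRUE)
  if (any(doses < 0)) stop("negative dose", call. = FALSE)
  set.seed(as.integer(seed))
  r <- (doses / Dm)^m
  fa <- r / (1 + r)
  if (noise_sd > 0)
    fa <- pmin(1, pmax(0, fa + rnorm(length(fa), 0, noise_sd)))
  structure(data.frame(dose = doses, fa = fa),
            Dm = Dm, m = m, class = c("dose_response", "data.frame"))
}
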