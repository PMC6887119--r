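#' Estimate full-translation time (FTT) from a luciferase recording
#'
#' FTT is the time at which reporter activity first becomes detectable in a
#' continuous recording — the readout of how long the 48S complex takes to
#' locate the start codon plus elongation of the first active reporter.
#' The estimator: (1) a detection threshold is the mean + `sd_mult` * SD of
#' the first `baseline_n` points (the pre-signal baseline window); (2) the
#' candidate onset is the first time with at least two consecutive points
#' above threshold; (3) a least-squares line through the first `k`
#' above-threshold points is extrapolated to its x-intercept, which is
#' clamped to be no earlier than the last below-threshold time before
#' onset. Invariant under uniform signal scaling; equivariant under time
#' shifts.
#'
#' @param curve A [luc_curve()] (data frame `time_min`, `signal`).
#' @param baseline_n Points in the baseline window (default 3).
#' @param sd_mult SD multiplier for the threshold (default 3).
#' @param k Points in the linear-phase fit (default 4; fewer are used if
#'   fewer are available, minimum 2).
#' @return Object of class `ftt_estimate`: list with `ftt` (minutes, or
#'   `NA` when no translation is detected), `detected` (logical),
#'   `threshold`, `onset_time` (first above-threshold time), `slope`.
#' @examples
#' sim <- gen_luc_curve(curve_sim_spec(onset_time = 9.5,
#'                                     sampling_interval = 0.5))
#' estimate_ftt(sim$curve)$ftt
#' @export
estimate_ftt <- function(curve, baseline_n = 3L, sd_mult = 3, k = 4L) {
  stopifnot(is.data.frame(curve),
            all(c("time_min", "signal") %in% names(curve)))
  t <- curve$time_min; y <- curve$signal
  if (length(t) < 5L) stop("curve must have >= 5 points", call. = FALSE)
  if (baseline_n < 3L) stop("baseline window needs >= 3 points", call. = FALSE)
  base <- y[seq_len(baseline_n)]
  thr <- mean(base) + sd_mult * sd(base)
  above <- y > thr
  # onset: first index with >= 2 consecutive points above threshold
  run <- which(above & c(above[-1L], FALSE))
  no_detect <- structure(list(ftt = NA_real_, detected = FALSE,
                              threshold = thr, onset_time = NA_real_,
                              slope = NA_real_),
                         class = "ftt_estimate")
  if (!length(run)) return(no_detect)
  onset_i <- run[1L]
  fit_i <- which(above & seq_along(y) >= onset_i)
  fit_i <- head(fit_i, max(2L, k))
  if (length(fit_i) < 2L) return(no_detect)
  # x-intercept of the rise measured above the baseline level, so the
  # estimate is where the linear phase crosses the pre-signal baseline
  fit <- lm(I(y[fit_i] - mean(base)) ~ t[fit_i])
  a <- coef(fit)[[2L]]; b <- coef(fit)[[1L]]
  below_before <- which(!above & seq_along(y) < onset_i)
  floor_t <- if (length(below_before)) t[max(below_before)] else t[1L]
  ftt <- if (is.finite(a) && a > 0) max(-b / a, floor_t) else t[onset_i]
  structure(list(ftt = ftt, detected = TRUE, threshold = thr,
                 onset_time = t[onset_i], slope = a),
            class = "ftt_estimate")
}

#' @export
print.ftt_estimate <- function(x, ...) {
  if (x$detected)
    cat(sprintf("FTT = %.2f min (onset %.2f min, threshold %.3g)\n",
                x$ftt, x$onset_time, x$threshold))
  else cat("no detectable translation\n")
  invisible(x)
}

#' Slope of FTT versus scanning length
#'
#' Estimates FTT for a set of recordings with known 5' UTR lengths and
#' fits FTT ~ length by least squares. FTT increases linearly with 5' UTR
#' length because scanning a longer leader takes proportionally longer;
#' the slope estimates the per-nucleotide scanning time.
#'
#' @param curves List of [luc_curve()]s.
#' @param lengths 5' UTR length (nt) per curve; >= 3 distinct values.
#' @param ... Passed to [estimate_ftt()].
#' @return List with `slope` (min/nt), `intercept` (min), `ftt` (per-curve
#'   estimates).
#' @export
ftt_linearity <- function(curves, lengths, ...) {
  if (length(curves) != length(lengths))
    stop("one length per curve required", call. = FALSE)
  if (length(unique(lengths)) < 3L)
    stop(">= 3 distinct lengths required", call. = FALSE)
  ftt <- vapply(curves, function(cv) estimate_ftt(cv, ...)$ftt, numeric(1))
  if (anyNA(ftt)) stop("undetected translation in >= 1 curve", call. = FALSE)
  fit <- lm(ftt ~ lengths)
  list(slope = coef(fit)[[2L]], intercept = coef(fit)[[1L]], ftt = ftt)
}

#' Endpoint fold inhibition
#'
#' @param signal_control,signal_treated Positive endpoint signals.
#' @return `signal_control / signal_treated` (vectorized).
#' @export
endpoint_fold_inhibition <- function(signal_control, signal_treated) {
  if (any(signal_control <= 0) || any(signal_treated <= 0))
    stop("signals must be > 0", call. = FALSE)
  signal_control / signal_treated
}

#' Fit the median-effect model to a dose-response table
#'
#' Least-squares fit of the linearized median-effect equation
#' `log(fa / (1 - fa)) = m log(d) - m log(Dm)`. Points with `fa` outside
#' the open interval (0, 1) or `d <= 0` carry no information on the log-log
#' line and are excluded with a warning; at least 3 usable points are
#' required.
#'
#' @param doses Dose vector.
#' @param affected_fractions Affected fraction `fa` per dose.
#' @return Object of class `median_effect_fit`: list with `Dm`, `m`,
#'   `residual` (residual sum of squares on the linearized scale),
#'   `n_used`.
#' @seealso [combination_index()], [gen_dose_response()]
#' @export
median_effect_fit <- function(doses, affected_fractions) {
  ok <- doses > 0 & affected_fractions > 0 & affected_fractions < 1
  if (any(!ok))
    warning(sum(!ok), " point(s) with d <= 0 or fa outside (0,1) excluded")
  d <- doses[ok]; fa <- affected_fractions[ok]
  if (length(d) < 3L) stop("< 3 usable dose points", call. = FALSE)
  yy <- log(fa / (1 - fa)); xx <- log(d)
  fit <- lm(yy ~ xx)
  m <- coef(fit)[[2L]]
  if (!is.finite(m) || m <= 0)
    stop("median-effect fit produced non-positive slope m", call. = FALSE)
  Dm <- exp(-coef(fit)[[1L]] / m)
  structure(list(Dm = Dm, m = m, residual = sum(resid(fit)^2),
                 n_used = length(d)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median-effect fit: Dm = %.4g, m = %.4g (n = %d, rss = %.3g)\n",
              x$Dm, x$m, x$n_used, x$residual))
  invisible(x)
}

#' Chou-Talalay combination index
#'
#' For a combination (d1, d2) producing affected fraction `fa`, the dose of
#' each agent alone producing that effect is
#' `D_i = Dm_i (fa / (1 - fa))^(1 / m_i)`; the combination index is
#' `CI = d1/D1 + d2/D2` (mutually exclusive form). CI < 1 indicates
#' synergy, CI = 1 additivity, CI > 1 antagonism. The mutually
#' non-exclusive variant adds the cross term `d1 d2 / (D1 D2)`.
#'
#' @param d1,d2 Doses of the two agents in the combination (>= 0).
#' @param fit1,fit2 [median_effect_fit()]s for each agent alone.
#' @param fa_combined Affected fraction of the combination, in (0, 1).
#' @param cross_term Include the non-exclusive cross term (default FALSE).
#' @return Object of class `synergy_result`: list with `d1`, `d2`, `D1`,
#'   `D2`, `CI`, `interpretation`.
#' @export
combination_index <- function(d1, d2, fit1, fit2, fa_combined,
                              cross_term = FALSE) {
  stopifnot(inherits(fit1, "median_effect_fit"),
            inherits(fit2, "median_effect_fit"))
  if (!(fa_combined > 0 && fa_combined < 1))
    stop("fa_combined must be inside (0, 1)", call. = FALSE)
  if (d1 < 0 || d2 < 0) stop("doses must be >= 0", call. = FALSE)
  r <- fa_combined / (1 - fa_combined)
  D1 <- fit1$Dm * r^(1 / fit1$m)
  D2 <- fit2$Dm * r^(1 / fit2$m)
  ci <- d1 / D1 + d2 / D2
  if (cross_term) ci <- ci + (d1 * d2) / (D1 * D2)
  interp <- if (abs(ci - 1) < 1e-9) "additivity" else
    if (ci < 1) "synergy" else "antagonism"
  structure(list(d1 = d1, d2 = d2, D1 = D1, D2 = D2, CI = ci,
                 interpretation = interp),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("CI = %.4g (%s); D1 = %.4g, D2 = %.4g\n",
              x$CI, x$interpretation, x$D1, x$D2))
  invisible(x)
}

#' Read a TSV of luciferase recordings into a list of curves
#'
#' Expects a `time_min` column plus one signal column per sample.
#'
#' @param path TSV path.
#' @return Named list of [luc_curve()]s.
#' @export
read_luc_curves <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  stopifnot("time_min" %in% names(df))
  cols <- setdiff(names(df), "time_min")
  setNames(lapply(cols, function(cl) luc_curve(df$time_min, df[[cl]],
                                               id = cl)), cols)
}
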