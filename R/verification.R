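# Predicted-vs-observed verification statistics: fold-error ratios with the
# conventional 0.5-2 acceptance band, and the absolute average fold error
# AAFE = 10^(mean |log10(predicted/observed)|) with the 1-2 band.

#' Trapezoidal area under the concentration-time curve
#'
#' Linear trapezoid on the series grid over `[t0_h, t1_h]`, with linear
#' interpolation at the window edges when they fall between grid points.
#'
#' @param series A `concentration_series`.
#' @param t0_h,t1_h Window (h); defaults to the full span.
#' @param unit "h" for ug*h/mL or "day" for ug*day/mL.
#' @return AUC in the requested unit.
#' @export
auc <- function(series, t0_h = min(series$time_h), t1_h = max(series$time_h),
                unit = c("h", "day")) {
  unit <- match.arg(unit)
  if (t0_h > t1_h) stop("t0_h must be <= t1_h", call. = FALSE)
  if (t0_h < min(series$time_h) || t1_h > max(series$time_h)) {
    stop("AUC window outside the series span", call. = FALSE)
  }
  if (t0_h == t1_h) return(0)
  t <- series$time_h
  y <- series$conc_ug_mL
  keep <- t > t0_h & t < t1_h
  tt <- c(t0_h, t[keep], t1_h)
  yy <- c(stats::approx(t, y, t0_h)$y, y[keep], stats::approx(t, y, t1_h)$y)
  a <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  if (unit == "day") a / 24 else a
}

#' Predicted/observed ratio
#'
#' @param predicted,observed Positive scalars (vectorized).
#' @return predicted / observed.
#' @export
ratio <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed values must be positive", call. = FALSE)
  predicted / observed
}

#' Absolute average fold error
#'
#' `AAFE = 10 ^ ((1/N) * sum(|log10(predicted_i / observed_i)|))`. Always
#' >= 1; equals `max(r, 1/r)` for a single pair with ratio r; symmetric in
#' its arguments.
#'
#' @param predicted,observed Equal-length positive vectors.
#' @return AAFE (dimensionless).
#' @export
aafe <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1) {
    stop("predicted and observed must be equal-length, non-empty", call. = FALSE)
  }
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("AAFE requires positive values", call. = FALSE)
  }
  10^(mean(abs(log10(predicted / observed))))
}

#' AAFE of a predicted profile against observed timepoints
#'
#' The predicted series is linearly interpolated at the observed timepoints,
#' then [aafe()] is applied.
#'
#' @param pred_series Predicted `concentration_series`.
#' @param obs_series Observed `concentration_series` (sparse).
#' @return Profile AAFE.
#' @export
profile_aafe <- function(pred_series, obs_series) {
  if (min(obs_series$time_h) < min(pred_series$time_h) ||
      max(obs_series$time_h) > max(pred_series$time_h)) {
    stop("observed timepoints outside the predicted span", call. = FALSE)
  }
  pred <- stats::approx(pred_series$time_h, pred_series$conc_ug_mL,
                        xout = obs_series$time_h)$y
  aafe(pred, obs_series$conc_ug_mL)
}

#' Pharmacokinetic summary metrics of a simulated series
#'
#' @param series A `concentration_series`.
#' @param interval_h Dosing interval (h), needed for first-dose and
#'   steady-state metrics under multiple dosing.
#' @param dose_times_h Dose times (h).
#' @param c_at_h Times (h) at which point concentrations are reported.
#' @param auc_windows Named list of `c(t0, t1, unit)` AUC windows, e.g.
#'   `list(AUC_0_28d = c(0, 672, "day"))`.
#' @return Named list: `cmax`, and under multiple dosing `cmax_first`,
#'   `cmax_ss`, `cmin_ss` (peak and trough of the final complete dosing
#'   interval), point concentrations `C_<t>h` and requested AUCs.
#' @export
pk_summary <- function(series, interval_h = NA_real_, dose_times_h = 0,
                       c_at_h = numeric(0), auc_windows = list()) {
  out <- list(cmax = max(series$conc_ug_mL))
  n_doses <- length(dose_times_h)
  if (n_doses > 1 && !is.na(interval_h)) {
    first <- series$time_h <= dose_times_h[2]
    out$cmax_first <- max(series$conc_ug_mL[first])
    t_last <- max(dose_times_h)
    final <- series$time_h >= t_last & series$time_h <= t_last + interval_h
    out$cmax_ss <- max(series$conc_ug_mL[final])
    out$cmin_ss <- min(series$conc_ug_mL[final])
  }
  for (tt in c_at_h) {
    out[[sprintf("C_%gh", tt)]] <-
      stats::approx(series$time_h, series$conc_ug_mL, xout = tt)$y
  }
  for (nmw in names(auc_windows)) {
    w <- auc_windows[[nmw]]
    out[[nmw]] <- auc(series, as.numeric(w[1]), as.numeric(w[2]),
                      unit = if (length(w) >= 3) w[3] else "h")
  }
  out
}

#' Verification report against observed metrics
#'
#' For each matched metric, computes the predicted/observed ratio and the
#' single-pair AAFE, and flags the conventional pass criteria: ratio within
#' [0.5, 2] and AAFE within [1, 2] (closed intervals; comparisons use full
#' precision, display rounding is left to the caller).
#'
#' @param predicted Named numeric vector (or list) of predicted metrics.
#' @param observed Named numeric vector (or list) of observed metrics; names
#'   must match `predicted`.
#' @param ratio_band,aafe_band Closed acceptance intervals.
#' @return Object of class `verification_report`: a data.frame with columns
#'   metric, observed, predicted, ratio, aafe, pass_ratio, pass_aafe.
#' @export
verify <- function(predicted, observed,
                   ratio_band = c(0.5, 2), aafe_band = c(1, 2)) {
  predicted <- unlist(predicted)
  observed <- unlist(observed)
  metrics <- intersect(names(observed), names(predicted))
  if (!length(metrics)) stop("no matched metric names", call. = FALSE)
  r <- ratio(predicted[metrics], observed[metrics])
  a <- vapply(metrics, function(m) aafe(predicted[m], observed[m]), numeric(1))
  rep <- data.frame(
    metric = metrics,
    observed = unname(observed[metrics]),
    predicted = unname(predicted[metrics]),
    ratio = unname(r),
    aafe = unname(a),
    pass_ratio = unname(r >= ratio_band[1] & r <= ratio_band[2]),
    pass_aafe = unname(a >= aafe_band[1] & a <= aafe_band[2]),
    row.names = NULL
  )
  class(rep) <- c("verification_report", "data.frame")
  rep
}
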