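# Cohort simulation and once-weekly regimen prediction against
# protein-adjusted IC90 efficacy targets.

#' Efficacy target thresholds
#'
#' Defaults are the cabotegravir prophylaxis targets: 4 x PA-IC90 =
#' 0.664 ug/mL and 8 x PA-IC90 = 1.33 ug/mL.
#'
#' @param four_ic90_ug_mL,eight_ic90_ug_mL Thresholds (ug/mL).
#' @return Object of class `target_spec`.
#' @export
target_spec <- function(four_ic90_ug_mL = 0.664, eight_ic90_ug_mL = 1.33) {
  stopifnot(four_ic90_ug_mL > 0, eight_ic90_ug_mL > four_ic90_ug_mL)
  structure(
    list(four_ic90_ug_mL = four_ic90_ug_mL,
         eight_ic90_ug_mL = eight_ic90_ug_mL),
    class = "target_spec"
  )
}

#' Simulate a regimen across a virtual cohort
#'
#' Runs [simulate_subject()] for every subject on the common output grid and
#' aggregates the pointwise mean and standard deviation of the plasma
#' concentration. Deterministic for a fixed cohort (all randomness lives in
#' cohort generation).
#'
#' @param cohort A `cohort`.
#' @param drug A `drug_parameters`.
#' @param reg A [regimen()].
#' @param design A [map_design()] (patch route).
#' @param solver See [solver_options()].
#' @param keep_subjects Keep the per-subject concentration matrix.
#' @return Object of class `cohort_result`: `time_h`, `mean_ug_mL`,
#'   `sd_ug_mL`, per-subject `summaries` (list of [pk_summary()] outputs),
#'   the regimen, and optionally `conc_matrix` (subjects x times).
#' @export
simulate_cohort <- function(cohort, drug, reg, design = map_design(),
                            solver = solver_options(),
                            keep_subjects = FALSE) {
  stopifnot(inherits(cohort, "cohort"), length(cohort) >= 1)
  failures <- character(0)
  series_list <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    series_list[[i]] <- tryCatch(
      simulate_subject(cohort[[i]], drug, reg, design, solver),
      error = function(e) {
        failures <<- c(failures, sprintf("subject %d: %s", i, conditionMessage(e)))
        NULL
      }
    )
  }
  if (length(failures)) {
    stop("cohort simulation failed for ", length(failures), " subject(s):\n",
         paste(failures, collapse = "\n"), call. = FALSE)
  }
  time_h <- series_list[[1]]$time_h
  conc <- do.call(rbind, lapply(series_list, function(s) s$conc_ug_mL))
  mean_c <- colMeans(conc)
  sd_c <- if (nrow(conc) > 1) apply(conc, 2, stats::sd) else rep(0, ncol(conc))
  summaries <- lapply(series_list, function(s) {
    pk_summary(s, interval_h = reg$interval_h, dose_times_h = reg$dose_times_h)
  })
  out <- list(
    time_h = time_h, mean_ug_mL = mean_c, sd_ug_mL = sd_c,
    summaries = summaries, regimen = reg, n_subjects = length(cohort)
  )
  if (keep_subjects) out$conc_matrix <- conc
  class(out) <- "cohort_result"
  out
}

#' Mean concentration curve of a cohort result
#'
#' @param result A `cohort_result`.
#' @return A `concentration_series` of the cohort mean.
#' @export
mean_series <- function(result) {
  stopifnot(inherits(result, "cohort_result"))
  concentration_series(result$time_h, result$mean_ug_mL)
}

#' Target attainment of a cohort simulation
#'
#' Evaluated on the cohort mean curve: the steady-state trough (minimum over
#' the final complete dosing interval), its ratio to each threshold, the
#' first day the mean curve exceeds each threshold (daily resolution), and
#' whether it stays above the threshold from that crossing to the horizon.
#'
#' @param result A `cohort_result` from a multi-dose regimen.
#' @param targets A [target_spec()].
#' @return data.frame with one row per threshold: threshold_ug_mL, cmin_ss,
#'   cmin_ss_ratio, first_day_above (NA when never attained),
#'   sustained_above.
#' @export
target_attainment <- function(result, targets = target_spec()) {
  stopifnot(inherits(result, "cohort_result"), inherits(targets, "target_spec"))
  reg <- result$regimen
  if (reg$n_doses < 2) {
    stop("steady-state metrics need at least two dosing intervals", call. = FALSE)
  }
  ms <- mean_series(result)
  t_last <- max(reg$dose_times_h)
  final <- ms$time_h >= t_last & ms$time_h <= t_last + reg$interval_h
  cmin_ss <- min(ms$conc_ug_mL[final])
  thresholds <- c(four_ic90 = targets$four_ic90_ug_mL,
                  eight_ic90 = targets$eight_ic90_ug_mL)
  rows <- lapply(names(thresholds), function(nmt) {
    thr <- thresholds[[nmt]]
    day <- ms$time_h / 24
    above <- ms$conc_ug_mL > thr
    first_day <- if (any(above)) ceiling(min(ms$time_h[above]) / 24) else NA_real_
    sustained <- if (any(above)) all(above[ms$time_h >= min(ms$time_h[above])]) else FALSE
    data.frame(
      target = nmt, threshold_ug_mL = thr, cmin_ss_ug_mL = cmin_ss,
      cmin_ss_ratio = cmin_ss / thr, first_day_above = first_day,
      sustained_above = sustained
    )
  })
  do.call(rbind, rows)
}

#' Compare once-weekly patch doses
#'
#' Runs [simulate_cohort()] for each dose (patch area from the dose loading)
#' and tabulates the target-attainment summary per dose.
#'
#' @param doses_mg Vector of patch doses (mg).
#' @param cohort,drug,design,solver As in [simulate_cohort()].
#' @param interval_h,n_doses,horizon_h,grid_h Regimen shared across doses.
#' @param targets A [target_spec()].
#' @return data.frame with one row per dose x threshold (columns of
#'   [target_attainment()] plus dose_mg and patch_area_cm2); empty
#'   data.frame for an empty dose list.
#' @export
dose_ladder <- function(doses_mg, cohort, drug, design = map_design(),
                        interval_h = 168, n_doses = 26, horizon_h = 4380,
                        grid_h = 1, targets = target_spec(),
                        solver = solver_options()) {
  if (!length(doses_mg)) return(data.frame())
  rows <- lapply(doses_mg, function(d) {
    reg <- regimen("map", dose_mg = d, interval_h = interval_h,
                   n_doses = n_doses, horizon_h = horizon_h, grid_h = grid_h)
    res <- simulate_cohort(cohort, drug, reg, design, solver)
    att <- target_attainment(res, targets)
    att$dose_mg <- d
    att$patch_area_cm2 <- patch_area_for_dose(d, design$dose_loading_mg_cm2)$area_cm2
    att
  })
  do.call(rbind, rows)
}
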