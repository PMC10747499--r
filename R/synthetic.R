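# Synthetic observed data: noisy sparse PK profiles with known truth, plus
# the printed observed/predicted verification metrics shipped as plain-text
# fixtures. Full observed concentration-time curves exist only as published
# figures, so profile-level testing uses synthetic curves generated here;
# the fixtures carry only printed table values.

#' Measurement noise model
#'
#' Combined proportional + additive error:
#' `C_obs = C * (1 + eps_prop) + eps_add`, truncated at zero, with
#' `eps_prop ~ N(0, cv^2)` and `eps_add ~ N(0, sd_add^2)`. Values below the
#' optional lower limit of quantification are flagged.
#'
#' @param cv Proportional coefficient of variation (default 0.15, an assumed
#'   assay variability).
#' @param sd_add_ug_mL Additive SD (ug/mL).
#' @param lloq_ug_mL Optional LLOQ (ug/mL).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.15, sd_add_ug_mL = 0.01, lloq_ug_mL = NULL) {
  stopifnot(cv >= 0, sd_add_ug_mL >= 0)
  structure(list(cv = cv, sd_add_ug_mL = sd_add_ug_mL,
                 lloq_ug_mL = lloq_ug_mL),
            class = "noise_model")
}

#' Generate a synthetic observed profile
#'
#' Evaluates the noise-free truth at the sampling schedule and applies the
#' noise model. Deterministic for a fixed seed.
#'
#' @param truth An [empirical_model()], a function `times_h -> conc`, or a
#'   `concentration_series` (interpolated at the schedule).
#' @param schedule_h Sampling times (h), non-empty.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return data.frame with `time_h`, `conc_ug_mL` and `below_lloq`.
#' @export
synth_profile <- function(truth, schedule_h, noise = noise_model(), seed = 1) {
  if (!length(schedule_h)) stop("schedule must be non-empty", call. = FALSE)
  schedule_h <- sort(schedule_h)
  clean <- if (inherits(truth, "empirical_model")) {
    predict_empirical(truth, schedule_h)
  } else if (is.function(truth)) {
    truth(schedule_h)
  } else if (inherits(truth, "concentration_series")) {
    stats::approx(truth$time_h, truth$conc_ug_mL, xout = schedule_h, rule = 2)$y
  } else {
    stop("truth must be an empirical_model, function or concentration_series",
         call. = FALSE)
  }
  noisy <- with_seed(seed, {
    clean * (1 + stats::rnorm(length(clean), 0, noise$cv)) +
      stats::rnorm(length(clean), 0, noise$sd_add_ug_mL)
  })
  noisy <- pmax(noisy, 0)
  below <- if (is.null(noise$lloq_ug_mL)) rep(FALSE, length(noisy)) else noisy < noise$lloq_ug_mL
  data.frame(time_h = schedule_h, conc_ug_mL = noisy, below_lloq = below)
}

#' Synthetic rat patch study bundle
#'
#' Emulates the two rat patch studies used for model qualification: a single
#' 11.72 mg dose and a once-weekly 11.72 mg regimen, each observed in six
#' animals on sparse schedules (single dose: days 1-28; weekly: pre-dose and
#' 24 h post-dose samples plus day 42). The generating truth is a
#' two-compartment depot model with the rat patch release rate
#' K_NP = 3.43e-3 1/h and disposition constants chosen to reproduce the
#' observed concentration scale (Cmax ~ 18 ug/mL, AUC_0-28d ~ 290
#' ug*day/mL).
#'
#' @param seed Integer seed.
#' @param noise A [noise_model()]; set `cv = 0, sd_add_ug_mL = 0` for
#'   noise-free truth recovery.
#' @param n_animals Animals per study.
#' @return List with `truth` (the generating [empirical_model()]s),
#'   `single` and `weekly` pooled data.frames (columns animal, time_h,
#'   conc_ug_mL, below_lloq), and the schedules.
#' @export
make_rat_map_study <- function(seed = 1, noise = noise_model(),
                               n_animals = 6) {
  dose_ug <- 11.72 * 1000
  truth_single <- empirical_model(
    "two_compartment", ka_h = 3.43e-3, cl_L_h = 0.0015, v_L = 0.1,
    q_L_h = 0.001, v2_L = 0.05, dose_ug = dose_ug, dose_times_h = 0
  )
  weekly_times <- (0:5) * 168
  truth_weekly <- empirical_model(
    "two_compartment", ka_h = 3.43e-3, cl_L_h = 0.0015, v_L = 0.1,
    q_L_h = 0.001, v2_L = 0.05, dose_ug = dose_ug,
    dose_times_h = weekly_times
  )
  sched_single <- 24 * c(1, 2, 3, 7, 10, 14, 21, 28)
  sched_weekly <- sort(unique(c(
    24,
    weekly_times[-1],      # pre-dose troughs
    weekly_times[-1] + 24, # 24 h post dose
    42 * 24
  )))
  pool <- function(truth, sched, offset) {
    do.call(rbind, lapply(seq_len(n_animals), function(a) {
      df <- synth_profile(truth, sched, noise, seed = seed + offset + a)
      cbind(animal = a, df)
    }))
  }
  list(
    truth = list(single = truth_single, weekly = truth_weekly),
    single = pool(truth_single, sched_single, 0),
    weekly = pool(truth_weekly, sched_weekly, 1000),
    schedules = list(single_h = sched_single, weekly_h = sched_weekly),
    noise = noise, seed = seed
  )
}

#' Load a packaged verification fixture
#'
#' Printed observed and predicted summary metrics for the four verification
#' studies, with their printed ratio/AAFE values, as shipped plain-text
#' tables.
#'
#' @param name One of "rat_im_observed", "rat_map_single_observed",
#'   "rat_map_weekly_observed", "human_im_observed", or "study_designs".
#' @return data.frame (read-only fixture).
#' @export
load_fixture <- function(name) {
  known <- c("rat_im_observed", "rat_map_single_observed",
             "rat_map_weekly_observed", "human_im_observed", "study_designs")
  if (!name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (name == "study_designs") {
    path <- system.file("extdata", "study_designs.csv", package = "mappk",
                        mustWork = TRUE)
    return(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  path <- system.file("extdata", "observed_metrics.csv", package = "mappk",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  study <- sub("_observed$", "", name)
  out <- tab[tab$study == study, , drop = FALSE]
  rownames(out) <- NULL
  out
}
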