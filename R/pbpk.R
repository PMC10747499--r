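# Whole-body PBPK engine.
#
# Internal canonical units: amounts ug, volumes mL, flows mL/h, times h,
# concentrations ug/mL. The full system (intradermal patch compartments,
# intramuscular depot, blood-flow-limited organs, venous clearance) is
# linear and time-invariant between doses, so it is assembled once as a
# rate matrix A with dx/dt = A x. Every transfer appears once as a loss and
# once as a gain, hence colSums(A) = 0 apart from the elimination bookkeeping
# state, and total mass (states + eliminated) is conserved exactly.

PERFUSED_ORGANS <- c(
  "adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
  "muscle", "skin", "spleen", "rest"
)

pbpk_state_names <- function() {
  c(
    "nd_sc", "nd_ve", "nd_de",
    "rd_sc", "rd_ve", "rd_de",
    "pd_sc", "pd_ve", "pd_de",
    "depot_im",
    PERFUSED_ORGANS, "lung", "art", "ven", "elim"
  )
}

#' Assemble the PBPK rate matrix for one subject
#'
#' Builds the constant first-order rate matrix of the coupled system:
#' per skin layer x (sc/ve/de), nanoparticle drug ND_x releases at `knp_h`
#' into needle-released drug RD_x, which partitions into the skin layer PD_x
#' at rate `pc_x/w * SA_MN,x / V_MN,x`; penetrating drug moves
#' unidirectionally sc -> ve -> de at `kskin / (PC_upper/lower * V_layer)`;
#' the dermis exchanges with blood as `+Q_DE*C_art - Q_DE*(PD_DE/V_DE)*
#' (R/TP_skin)`. The intramuscular depot releases into venous blood at
#' `knp_h`. Systemic disposition is blood-flow limited with well-stirred
#' organs (`dA_t/dt = Q_t*C_art - Q_t*A_t*R/(V_t*Kp_t)`), lung in series
#' carrying cardiac output, and clearance CL/F acting on the venous blood
#' concentration. Plasma concentration = venous blood concentration / R.
#'
#' @param subject A `subject`.
#' @param drug A `drug_parameters` with the route's `clf_L_h`, `knp_h` and
#'   (for patches) `kskin_cm3_h` set.
#' @param route "im" or "map".
#' @param geom A `layer_geometry` (required for `route = "map"`).
#' @param partition Optional precomputed [tissue_plasma_partition()] result;
#'   computed from the subject (with its `vd_correction`) when NULL.
#' @return List with the rate matrix `A` (states x states), `state_names`,
#'   `V_ven_mL`, `dose_fraction` (per-layer, map route) and `R`.
#' @export
pbpk_system <- function(subject, drug, route = c("im", "map"),
                        geom = NULL, partition = NULL) {
  route <- match.arg(route)
  stopifnot(inherits(subject, "subject"), inherits(drug, "drug_parameters"))
  if (is.na(drug$clf_L_h) || is.na(drug$knp_h)) {
    stop("drug must have clf_L_h and knp_h set for simulation", call. = FALSE)
  }
  if (route == "map") {
    if (is.null(geom)) stop("map route requires a layer_geometry", call. = FALSE)
    if (is.na(drug$kskin_cm3_h)) {
      stop("map route requires drug$kskin_cm3_h", call. = FALSE)
    }
  }
  if (is.null(partition)) {
    partition <- tissue_plasma_partition(
      drug, volumes_L = subject$organ_volumes_L,
      vd_correction = subject$vd_correction
    )
  }
  tp <- partition$tp
  missing_tp <- setdiff(c(PERFUSED_ORGANS, "lung"), names(tp))
  if (length(missing_tp)) {
    stop("missing tissue:plasma coefficient for: ",
         paste(missing_tp, collapse = ", "), call. = FALSE)
  }

  nm <- pbpk_state_names()
  n <- length(nm)
  A <- matrix(0, n, n, dimnames = list(nm, nm))
  R <- drug$R
  V_mL <- subject$organ_volumes_L * 1000
  Q_mL_h <- subject$blood_flows_L_h * 1000
  CO <- subject$cardiac_output_L_h * 1000
  CL <- drug$clf_L_h * 1000
  V_blood <- unname(V_mL["blood"])
  V_art <- V_blood / 3
  V_ven <- V_blood * 2 / 3

  # perfused organs in parallel between arterial and venous blood
  for (t in PERFUSED_ORGANS) {
    k_out <- Q_mL_h[t] * R / (V_mL[t] * tp[t])
    A[t, "art"] <- A[t, "art"] + Q_mL_h[t] / V_art
    A["art", "art"] <- A["art", "art"] - Q_mL_h[t] / V_art
    A[t, t] <- A[t, t] - k_out
    A["ven", t] <- A["ven", t] + k_out
  }
  # lung in series carrying total cardiac output
  A["lung", "ven"] <- A["lung", "ven"] + CO / V_ven
  A["ven", "ven"] <- A["ven", "ven"] - CO / V_ven
  k_lung <- CO * R / (V_mL["lung"] * tp["lung"])
  A["lung", "lung"] <- A["lung", "lung"] - k_lung
  A["art", "lung"] <- A["art", "lung"] + k_lung
  # clearance on venous blood concentration
  A["ven", "ven"] <- A["ven", "ven"] - CL / V_ven
  A["elim", "ven"] <- A["elim", "ven"] + CL / V_ven

  knp <- drug$knp_h
  if (route == "im") {
    A["depot_im", "depot_im"] <- -knp
    A["ven", "depot_im"] <- knp
    dose_fraction <- NULL
  } else {
    layers <- c("sc", "ve", "de")
    for (x in layers) {
      ndx <- paste0("nd_", x); rdx <- paste0("rd_", x); pdx <- paste0("pd_", x)
      A[ndx, ndx] <- -knp
      A[rdx, ndx] <- knp
      pc_w <- switch(x, sc = drug$pc_sc_w, ve = drug$pc_ve_w, de = drug$pc_de_w)
      v_mn <- geom$V_MN_mL[x]
      k_rel <- if (v_mn > 0) pc_w * geom$SA_MN_cm2[x] / v_mn else 0
      A[rdx, rdx] <- A[rdx, rdx] - k_rel
      A[pdx, rdx] <- k_rel
    }
    kskin <- drug$kskin_cm3_h
    k_sc_ve <- kskin / (drug$pc_sc_ve * geom$V_layer_mL["sc"])
    k_ve_de <- kskin / (drug$pc_ve_de * geom$V_layer_mL["ve"])
    A["pd_sc", "pd_sc"] <- A["pd_sc", "pd_sc"] - k_sc_ve
    A["pd_ve", "pd_sc"] <- A["pd_ve", "pd_sc"] + k_sc_ve
    A["pd_ve", "pd_ve"] <- A["pd_ve", "pd_ve"] - k_ve_de
    A["pd_de", "pd_ve"] <- A["pd_de", "pd_ve"] + k_ve_de
    # dermal blood exchange over the patch-covered dermis
    Q_de <- subject$dermal_perfusion_mL_h_cm2 * geom$patch_area_cm2
    A["pd_de", "art"] <- A["pd_de", "art"] + Q_de / V_art
    A["art", "art"] <- A["art", "art"] - Q_de / V_art
    k_de_out <- Q_de * R / (tp["skin"] * geom$V_layer_mL["de"])
    A["pd_de", "pd_de"] <- A["pd_de", "pd_de"] - k_de_out
    A["ven", "pd_de"] <- A["ven", "pd_de"] + k_de_out
    dose_fraction <- geom$dose_fraction
  }

  list(A = A, state_names = nm, V_ven_mL = V_ven, R = R,
       dose_fraction = dose_fraction, route = route)
}

#' Time derivative of the full patch-route PBPK state
#'
#' Convenience wrappers over [pbpk_system()] returning `d(state)/dt` for a
#' named state vector; used for testing and for coupling external solvers.
#'
#' @param state Named numeric vector over [pbpk_state_names()] (missing
#'   names are treated as zero).
#' @param drug,subject,geom See [pbpk_system()].
#' @return Named numeric derivative vector (ug/h).
#' @export
map_rhs <- function(state, drug, geom, subject) {
  sys <- pbpk_system(subject, drug, route = "map", geom = geom)
  full <- stats::setNames(numeric(length(sys$state_names)), sys$state_names)
  full[names(state)] <- state
  drop(sys$A %*% full)
}

#' @rdname map_rhs
#' @export
im_rhs <- function(state, drug, subject) {
  sys <- pbpk_system(subject, drug, route = "im")
  full <- stats::setNames(numeric(length(sys$state_names)), sys$state_names)
  full[names(state)] <- state
  drop(sys$A %*% full)
}

#' @rdname map_rhs
#' @export
systemic_rhs <- function(state, drug, subject) {
  # systemic disposition only: the depot/patch blocks are zero when their
  # states are zero, so the im-route matrix restricted to systemic states
  # is the systemic model
  im_rhs(state, drug, subject)
}

#' Dosing regimen
#'
#' @param route "im" or "map".
#' @param dose_mg Dose per administration (mg).
#' @param interval_h Dosing interval (h); ignored when `n_doses = 1`.
#' @param n_doses Number of administrations.
#' @param horizon_h Simulation horizon (h). Defaults to
#'   `n_doses * interval_h` for multiple dosing.
#' @param grid_h Output grid step (h).
#' @return Object of class `regimen`.
#' @export
regimen <- function(route = c("im", "map"), dose_mg, interval_h = NA_real_,
                    n_doses = 1, horizon_h = NULL, grid_h = 0.5) {
  route <- match.arg(route)
  stopifnot(dose_mg > 0, n_doses >= 1, grid_h > 0)
  if (n_doses > 1 && (is.na(interval_h) || interval_h <= 0)) {
    stop("multiple dosing requires a positive interval_h", call. = FALSE)
  }
  if (is.null(horizon_h)) {
    horizon_h <- if (n_doses > 1) n_doses * interval_h else 672
  }
  dose_times <- if (n_doses > 1) (0:(n_doses - 1)) * interval_h else 0
  if (horizon_h < max(dose_times)) {
    stop("horizon_h must cover all dose times", call. = FALSE)
  }
  structure(
    list(route = route, dose_mg = dose_mg, interval_h = interval_h,
         n_doses = n_doses, horizon_h = horizon_h, grid_h = grid_h,
         dose_times_h = dose_times),
    class = "regimen"
  )
}

#' Solver options
#'
#' @param method deSolve integration method (stiff-capable default).
#' @param rtol Relative tolerance.
#' @param atol Absolute tolerance (ug).
#' @return List of solver settings.
#' @export
solver_options <- function(method = "lsoda", rtol = 1e-8, atol = 1e-9) {
  list(method = method, rtol = rtol, atol = atol)
}

#' Simulate a dosing regimen in one subject
#'
#' Integrates the coupled patch/depot + whole-body system with event-based
#' dosing (each administration adds the dose to the depot states; residual
#' drug from earlier patches is retained). The system's constant rate matrix
#' is supplied to the stiff solver together with its analytic Jacobian.
#'
#' @param subject A `subject`.
#' @param drug A `drug_parameters`.
#' @param reg A [regimen()].
#' @param design A [map_design()] (patch route only).
#' @param solver See [solver_options()].
#' @param return_states Return all compartment trajectories alongside the
#'   plasma concentration.
#' @return A `concentration_series` data.frame with `time_h` and
#'   `conc_ug_mL` (plasma), plus attributes `dose_ug_total` and, when
#'   `return_states`, a `states` matrix.
#' @export
simulate_subject <- function(subject, drug, reg, design = map_design(),
                             solver = solver_options(),
                             return_states = FALSE) {
  stopifnot(inherits(reg, "regimen"))
  geom <- NULL
  if (reg$route == "map") {
    area <- patch_area_for_dose(reg$dose_mg, design$dose_loading_mg_cm2)$area_cm2
    geom <- layer_partition(design, subject$skin_thicknesses_um, area)
  }
  sys <- pbpk_system(subject, drug, route = reg$route, geom = geom)
  nm <- sys$state_names
  dose_ug <- reg$dose_mg * 1000

  y0 <- stats::setNames(numeric(length(nm)), nm)
  add_dose <- function() {
    if (reg$route == "im") {
      data.frame(var = "depot_im", value = dose_ug)
    } else {
      data.frame(
        var = c("nd_sc", "nd_ve", "nd_de"),
        value = dose_ug * unname(sys$dose_fraction[c("sc", "ve", "de")])
      )
    }
  }
  d0 <- add_dose()
  y0[d0$var] <- d0$value

  times <- sort(unique(c(seq(0, reg$horizon_h, by = reg$grid_h),
                         reg$horizon_h, reg$dose_times_h)))
  events <- NULL
  later <- reg$dose_times_h[reg$dose_times_h > 0]
  if (length(later)) {
    ev <- do.call(rbind, lapply(later, function(tt) {
      d <- add_dose(); d$time <- tt; d
    }))
    ev$method <- "add"
    events <- list(data = ev[, c("var", "time", "value", "method")])
  }

  Amat <- sys$A
  rhs <- function(t, y, p) list(as.vector(Amat %*% y))
  jac <- function(t, y, p) Amat
  sol <- deSolve::ode(
    y = y0, times = times, func = rhs, parms = NULL,
    jacfunc = jac, jactype = "fullusr",
    method = solver$method, rtol = solver$rtol, atol = solver$atol,
    events = events
  )
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol))) {
    stop("ODE integration failed near t = ",
         max(sol[stats::complete.cases(sol), "time"]), " h", call. = FALSE)
  }
  conc <- sol[, "ven"] / sys$V_ven_mL / sys$R # plasma = blood / R
  out <- concentration_series(sol[, "time"], conc)
  attr(out, "dose_ug_total") <- dose_ug * reg$n_doses
  if (return_states) attr(out, "states") <- sol[, nm, drop = FALSE]
  out
}

#' Concentration-time series
#'
#' @param time_h Strictly increasing times (h).
#' @param conc_ug_mL Non-negative plasma concentrations (ug/mL).
#' @return data.frame of class `concentration_series`.
#' @export
concentration_series <- function(time_h, conc_ug_mL) {
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(conc_ug_mL < -1e-9)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  structure(
    data.frame(time_h = time_h, conc_ug_mL = pmax(conc_ug_mL, 0)),
    class = c("concentration_series", "data.frame")
  )
}
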