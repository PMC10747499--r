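# Empirical compartmental models with first-order depot input, used to
# estimate the nanoparticle release rate (ka = K_NP), disposition constants
# and CL/F from sparse concentration-time data before they enter the PBPK
# model.
#
# Identifiability note: the first-order-depot model is invariant under
# exchanging ka with an elimination exponent (flip-flop twin). Long-acting
# depots are absorption-rate limited, so fits are canonicalized to the
# branch with ka <= ke (one-compartment: the exact reparameterization
# (ka, CL, V) -> (CL/V, CL, CL/ka) leaves the curve unchanged).

#' Empirical model specification
#'
#' One- or two-compartment disposition with first-order input from a dosing
#' depot. Parameters are apparent (per bioavailability): `cl_L_h` = CL/F,
#' `v_L` = V/F, and for the two-compartment model the inter-compartment
#' clearance `q_L_h` = Q/F and peripheral volume `v2_L` = V2/F.
#'
#' @param kind "one_compartment" or "two_compartment".
#' @param ka_h Depot first-order input rate (1/h).
#' @param cl_L_h Apparent clearance (L/h).
#' @param v_L Apparent central volume (L).
#' @param q_L_h Apparent inter-compartment clearance (L/h, two-compartment).
#' @param v2_L Apparent peripheral volume (L, two-compartment).
#' @param dose_ug Dose per administration (ug).
#' @param dose_times_h Administration times (h).
#' @return Object of class `empirical_model`.
#' @export
empirical_model <- function(kind = c("one_compartment", "two_compartment"),
                            ka_h, cl_L_h, v_L, q_L_h = NA_real_,
                            v2_L = NA_real_, dose_ug, dose_times_h = 0) {
  kind <- match.arg(kind)
  stopifnot(ka_h > 0, cl_L_h > 0, v_L > 0, dose_ug >= 0,
            all(dose_times_h >= 0))
  if (kind == "two_compartment" && (is.na(q_L_h) || is.na(v2_L) ||
                                    q_L_h <= 0 || v2_L <= 0)) {
    stop("two-compartment model requires positive q_L_h and v2_L",
         call. = FALSE)
  }
  structure(
    list(kind = kind, ka_h = ka_h, cl_L_h = cl_L_h, v_L = v_L,
         q_L_h = q_L_h, v2_L = v2_L, dose_ug = dose_ug,
         dose_times_h = sort(dose_times_h)),
    class = "empirical_model"
  )
}

# single-dose unit response (dose = D ug at t = 0), t vector >= 0
one_cmt_conc <- function(t, ka, cl_mL_h, v_mL, dose_ug) {
  ke <- cl_mL_h / v_mL
  pos <- t >= 0
  out <- numeric(length(t))
  tt <- t[pos]
  if (abs(ka - ke) < 1e-10 * max(ka, ke)) {
    out[pos] <- dose_ug * ka * tt * exp(-ka * tt) / v_mL
  } else {
    out[pos] <- ka * dose_ug / (v_mL * (ka - ke)) * (exp(-ke * tt) - exp(-ka * tt))
  }
  out
}

two_cmt_conc <- function(t, ka, cl_mL_h, v1_mL, q_mL_h, v2_mL, dose_ug) {
  k10 <- cl_mL_h / v1_mL
  k12 <- q_mL_h / v1_mL
  k21 <- q_mL_h / v2_mL
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  # avoid exact coincidence of rate constants (macro solution poles)
  eps <- 1e-9 * max(ka, alpha, beta)
  if (abs(ka - alpha) < eps) ka <- ka * (1 + 1e-8)
  if (abs(ka - beta) < eps) ka <- ka * (1 + 2e-8)
  if (abs(alpha - beta) < eps) alpha <- alpha * (1 + 1e-8)
  pos <- t >= 0
  tt <- t[pos]
  cA <- (k21 - alpha) / ((ka - alpha) * (beta - alpha))
  cB <- (k21 - beta) / ((ka - beta) * (alpha - beta))
  cK <- (k21 - ka) / ((alpha - ka) * (beta - ka))
  out <- numeric(length(t))
  out[pos] <- ka * dose_ug / v1_mL *
    (cA * exp(-alpha * tt) + cB * exp(-beta * tt) + cK * exp(-ka * tt))
  out
}

#' Predict concentrations from an empirical model
#'
#' Closed-form solution (Bateman equation for one compartment, biexponential
#' macro-constant solution for two compartments), multi-dose by
#' superposition. Concentrations are in ug/mL.
#'
#' @param spec An [empirical_model()].
#' @param times_h Non-negative times (h).
#' @return Numeric concentrations (ug/mL).
#' @export
predict_empirical <- function(spec, times_h) {
  stopifnot(inherits(spec, "empirical_model"))
  if (any(times_h < 0)) stop("times must be non-negative", call. = FALSE)
  cl <- spec$cl_L_h * 1000
  v <- spec$v_L * 1000
  conc <- numeric(length(times_h))
  for (td in spec$dose_times_h) {
    conc <- conc + if (spec$kind == "one_compartment") {
      one_cmt_conc(times_h - td, spec$ka_h, cl, v, spec$dose_ug)
    } else {
      two_cmt_conc(times_h - td, spec$ka_h, cl, v,
                   spec$q_L_h * 1000, spec$v2_L * 1000, spec$dose_ug)
    }
  }
  conc
}

# Map a fitted parameter set to its flip-flop canonical twin (ka = slowest
# exponential rate). The depot model's concentration curve is invariant
# under exchanging ka with a disposition exponent, so this is an exact
# reparameterization: predictions and RSS are unchanged.
flipflop_canonical <- function(est, kind) {
  if (kind == "one_compartment") {
    ke <- est["cl_L_h"] / est["v_L"]
    if (est["ka_h"] <= ke) return(est)
    return(c(ka_h = unname(ke), cl_L_h = unname(est["cl_L_h"]),
             v_L = unname(est["cl_L_h"] / est["ka_h"])))
  }
  # two-compartment: rates are {alpha, beta, ka}; coefficients of the three
  # exponentials determine the canonical (k21, k10, k12, V1) uniquely
  ka <- est[["ka_h"]]
  k10 <- est[["cl_L_h"]] / est[["v_L"]]
  k12 <- est[["q_L_h"]] / est[["v_L"]]
  k21 <- est[["q_L_h"]] / est[["v2_L"]]
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  lam <- sort(c(alpha, beta, ka))
  if (min(diff(lam)) < 1e-9 * lam[3]) return(est) # degenerate: leave as-is
  if (abs(ka - lam[1]) < 1e-12 * lam[1]) return(est) # already canonical
  # exponential coefficients of the fitted curve, keyed by rate
  phi <- ka / est[["v_L"]] # per unit dose; units cancel in the ratios
  coef_at <- function(r, others) {
    phi * (k21 - r) / prod(others - r)
  }
  cvals <- vapply(lam, function(r) {
    others <- setdiff(c(alpha, beta, ka), r)
    coef_at(r, others)
  }, numeric(1))
  l1 <- lam[1]; l2 <- lam[2]; l3 <- lam[3]
  g <- (cvals[3] / cvals[2]) * ((l1 - l3) * (l2 - l3)) / ((l1 - l2) * (l3 - l2))
  k21n <- (l3 - g * l2) / (1 - g)
  if (!is.finite(k21n) || k21n <= l2 || k21n >= l3) return(est)
  k10n <- l2 * l3 / k21n
  k12n <- l2 + l3 - k10n - k21n
  if (k12n <= 0) return(est)
  phin <- cvals[1] * (l3 - l1) * (l2 - l1) / (k21n - l1)
  v1n <- l1 / phin
  if (!is.finite(v1n) || v1n <= 0) return(est)
  c(ka_h = l1, cl_L_h = k10n * v1n, v_L = v1n,
    q_L_h = k12n * v1n, v2_L = k12n * v1n / k21n)
}

default_bounds <- function(kind) {
  lower <- c(ka_h = 1e-5, cl_L_h = 1e-5, v_L = 1e-4)
  upper <- c(ka_h = 1, cl_L_h = 1e3, v_L = 1e4)
  if (kind == "two_compartment") {
    lower <- c(lower, q_L_h = 1e-6, v2_L = 1e-4)
    upper <- c(upper, q_L_h = 1e3, v2_L = 1e4)
  }
  list(lower = lower, upper = upper)
}

#' Fit an empirical model by nonlinear least squares
#'
#' Levenberg-Marquardt least squares (the `lsqnonlin` analogue) on
#' untransformed concentrations by default (`log_scale = TRUE` fits log
#' concentrations). Parameters are optimized on the log scale to enforce
#' positivity, with box bounds. A seeded multi-start (log-uniform over the
#' bounds, plus the supplied init) guards against local minima; the
#' best-RSS convergent start wins.
#'
#' @param observed A `concentration_series` (or data.frame with `time_h`,
#'   `conc_ug_mL`).
#' @param kind Model kind, see [empirical_model()].
#' @param dose_ug,dose_times_h Dosing actually given.
#' @param init Optional named vector of starting values (natural units).
#' @param lower,upper Named bounds (natural units).
#' @param n_starts Number of random multi-starts.
#' @param seed Seed for start sampling.
#' @param log_scale Fit on log-concentration scale.
#' @return Object of class `fit_result`: `estimates`, `rss`, `converged`,
#'   `residuals`, `model` (the fitted [empirical_model()]), `n_starts`,
#'   `seed`.
#' @export
fit_empirical <- function(observed, kind = c("one_compartment", "two_compartment"),
                          dose_ug, dose_times_h = 0, init = NULL,
                          lower = NULL, upper = NULL, n_starts = 10,
                          seed = 1, log_scale = FALSE) {
  kind <- match.arg(kind)
  obs_t <- observed$time_h
  obs_c <- observed$conc_ug_mL
  b <- default_bounds(kind)
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  par_names <- names(b$lower)
  if (length(obs_t) < length(par_names)) {
    stop("need at least as many observations as parameters", call. = FALSE)
  }
  if (all(obs_c <= 0)) {
    stop("degenerate data: no positive concentrations to fit", call. = FALSE)
  }
  if (log_scale && any(obs_c <= 0)) {
    stop("log-scale fitting requires positive observations", call. = FALSE)
  }

  make_spec <- function(p) {
    do.call(empirical_model, c(
      list(kind = kind, dose_ug = dose_ug, dose_times_h = dose_times_h),
      as.list(p)
    ))
  }
  resid_fn <- function(lp) {
    p <- stats::setNames(exp(lp), par_names)
    pred <- predict_empirical(make_spec(p), obs_t)
    if (log_scale) log(pmax(pred, 1e-12)) - log(obs_c) else pred - obs_c
  }

  starts <- with_seed(seed, {
    m <- matrix(
      stats::runif(n_starts * length(par_names),
                   rep(log(b$lower), each = n_starts),
                   rep(log(b$upper), each = n_starts)),
      nrow = n_starts, dimnames = list(NULL, par_names)
    )
    m
  })
  if (!is.null(init)) starts <- rbind(log(init[par_names]), starts)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], fn = resid_fn,
        lower = log(b$lower), upper = log(b$upper),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    # strict improvement only: flip-flop twins tie in RSS, and earlier
    # starts (the supplied init first) should win ties
    if (is.null(best) || rss < best$rss * (1 - 1e-9)) {
      best <- list(fit = fit, rss = rss, start = unname(starts[i, ]))
    }
  }
  if (is.null(best)) {
    stop("fit failed to converge from all starts", call. = FALSE)
  }
  est <- stats::setNames(exp(best$fit$par), par_names)
  est <- flipflop_canonical(est, kind)
  at_bound <- est <= b$lower * (1 + 1e-6) | est >= b$upper * (1 - 1e-6)
  structure(
    list(
      estimates = est, rss = best$rss,
      converged = best$fit$info %in% 1:4,
      at_bound = at_bound,
      residuals = best$fit$fvec,
      model = make_spec(est),
      n_starts = nrow(starts), seed = seed, log_scale = log_scale
    ),
    class = "fit_result"
  )
}

#' Estimate PBPK parameters by curve-fitting the full model
#'
#' Wraps [simulate_subject()] as the regression function: the chosen free
#' parameters (any of `clf_L_h`, `knp_h`, `kskin_cm3_h`, `vd_correction`)
#' are adjusted by Levenberg-Marquardt least squares against an observed
#' concentration series; all other inputs are held at their configured
#' values. Predicted concentrations are linearly interpolated at the
#' observation times.
#'
#' @param subject,drug,reg,design As in [simulate_subject()].
#' @param observed Observed `concentration_series`.
#' @param free Character vector of parameter names to estimate.
#' @param init Named starting values (natural units); defaults to the
#'   current configured values.
#' @param lower,upper Named bounds (natural units).
#' @param n_starts,seed Multi-start control (first start is `init`).
#' @param solver Solver options; a coarser tolerance than the default is
#'   adequate inside the optimizer.
#' @return A `fit_result` with `estimates` on natural units.
#' @export
estimate_clf_by_curvefit <- function(subject, drug, reg, observed,
                                     free = "clf_L_h", init = NULL,
                                     lower = NULL, upper = NULL,
                                     design = map_design(), n_starts = 3,
                                     seed = 1,
                                     solver = solver_options(rtol = 1e-6, atol = 1e-6)) {
  allowed <- c("clf_L_h", "knp_h", "kskin_cm3_h", "vd_correction")
  if (!all(free %in% allowed)) {
    stop("free parameters must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  def_lower <- c(clf_L_h = 1e-4, knp_h = 1e-5, kskin_cm3_h = 1e-6,
                 vd_correction = 1e-4)
  def_upper <- c(clf_L_h = 1e3, knp_h = 1, kskin_cm3_h = 10,
                 vd_correction = 100)
  lo <- def_lower[free]; hi <- def_upper[free]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  cur <- c(clf_L_h = drug$clf_L_h, knp_h = drug$knp_h,
           kskin_cm3_h = drug$kskin_cm3_h,
           vd_correction = subject$vd_correction)
  start0 <- cur[free]
  if (!is.null(init)) start0[names(init)] <- init
  start0 <- pmin(pmax(start0, lo), hi)
  if (any(is.na(start0))) {
    stop("no starting value available for: ",
         paste(free[is.na(start0)], collapse = ", "), call. = FALSE)
  }

  obs_t <- observed$time_h
  obs_c <- observed$conc_ug_mL
  apply_par <- function(p) {
    d <- drug; s <- subject
    for (nmp in names(p)) {
      if (nmp == "vd_correction") s$vd_correction <- p[[nmp]] else d[[nmp]] <- p[[nmp]]
    }
    list(drug = d, subject = s)
  }
  resid_fn <- function(lp) {
    p <- stats::setNames(exp(lp), free)
    ds <- apply_par(p)
    sim <- simulate_subject(ds$subject, ds$drug, reg, design, solver = solver)
    pred <- stats::approx(sim$time_h, sim$conc_ug_mL, xout = obs_t, rule = 2)$y
    pred - obs_c
  }

  starts <- rbind(log(start0))
  if (n_starts > 1) {
    extra <- with_seed(seed, matrix(
      stats::runif((n_starts - 1) * length(free),
                   rep(log(lo), each = n_starts - 1),
                   rep(log(hi), each = n_starts - 1)),
      nrow = n_starts - 1, dimnames = list(NULL, free)
    ))
    starts <- rbind(starts, extra)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], fn = resid_fn, lower = log(lo), upper = log(hi),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("curve fit failed from all starts", call. = FALSE)
  est <- stats::setNames(exp(best$fit$par), free)
  structure(
    list(
      estimates = est, rss = best$rss,
      converged = best$fit$info %in% 1:4,
      at_bound = est <= lo * (1 + 1e-6) | est >= hi * (1 - 1e-6),
      residuals = best$fit$fvec, n_starts = nrow(starts), seed = seed
    ),
    class = "fit_result"
  )
}
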