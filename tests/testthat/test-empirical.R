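test_that("one-compartment prediction matches Bateman identities", {
  spec <- empirical_model("one_compartment", ka_h = 0.05, cl_L_h = 2,
                          v_L = 40, dose_ug = 1e5)
  ka <- 0.05; ke <- 2 / 40
  # ka == ke analytic limit: C = D*ka*t*exp(-ka t)/V
  tt <- c(0, 1, 5, 20, 100)
  expect_equal(predict_empirical(spec, tt),
               1e5 * ka * tt * exp(-ka * tt) / 40e3, tolerance = 1e-6)
  # Cmax time identity for ka != ke
  spec2 <- empirical_model("one_compartment", ka_h = 0.01, cl_L_h = 2,
                           v_L = 40, dose_ug = 1e5)
  tmax <- log(0.01 / 0.05) / (0.01 - 0.05)
  grid <- seq(0, 400, by = 0.01)
  cgrid <- predict_empirical(spec2, grid)
  expect_equal(grid[which.max(cgrid)], tmax, tolerance = 1e-3)
  # depot input: C(0) = 0
  expect_equal(predict_empirical(spec2, 0), 0)
  expect_error(predict_empirical(spec2, -1), "non-negative")
})

test_that("closed forms agree with an independent ODE integration", {
  # oracle: integrate the depot/compartment ODEs directly
  ode_oracle <- function(spec, times) {
    cl <- spec$cl_L_h * 1000; v <- spec$v_L * 1000
    if (spec$kind == "one_compartment") {
      rhs <- function(t, y, p) {
        list(c(-spec$ka_h * y[1], spec$ka_h * y[1] - cl / v * y[2]))
      }
      y0 <- c(spec$dose_ug, 0)
      sol <- deSolve::ode(y0, times, rhs, NULL, rtol = 1e-11, atol = 1e-12)
      sol[, 3] / v
    } else {
      q <- spec$q_L_h * 1000; v2 <- spec$v2_L * 1000
      rhs <- function(t, y, p) {
        c1 <- y[2] / v; c2 <- y[3] / v2
        list(c(-spec$ka_h * y[1],
               spec$ka_h * y[1] - cl * c1 - q * (c1 - c2),
               q * (c1 - c2)))
      }
      y0 <- c(spec$dose_ug, 0, 0)
      sol <- deSolve::ode(y0, times, rhs, NULL, rtol = 1e-11, atol = 1e-12)
      sol[, 3] / v
    }
  }
  times <- seq(0, 1000, by = 10)
  s1 <- empirical_model("one_compartment", ka_h = 3.43e-3, cl_L_h = 0.01,
                        v_L = 0.5, dose_ug = 11720)
  s2 <- empirical_model("two_compartment", ka_h = 3.43e-3, cl_L_h = 0.0015,
                        v_L = 0.1, q_L_h = 0.001, v2_L = 0.05, dose_ug = 11720)
  for (s in list(s1, s2)) {
    pred <- predict_empirical(s, times)
    orac <- ode_oracle(s, times)
    expect_lt(max(abs(pred - orac)) / max(orac), 1e-8)
  }
})

test_that("noise-free parameters are recovered to 0.1%", {
  times <- 24 * c(0.5, 1, 2, 3, 5, 7, 10, 14, 18, 21, 24, 28)
  truth1 <- empirical_model("one_compartment", ka_h = 3.43e-3, cl_L_h = 0.01,
                            v_L = 0.5, dose_ug = 11720)
  obs1 <- data.frame(time_h = times,
                     conc_ug_mL = predict_empirical(truth1, times))
  fit1 <- fit_empirical(obs1, "one_compartment", dose_ug = 11720, seed = 1)
  expect_lt(abs(fit1$estimates["ka_h"] - 3.43e-3) / 3.43e-3, 1e-3)
  expect_lt(abs(fit1$estimates["cl_L_h"] - 0.01) / 0.01, 1e-3)
  expect_lt(abs(fit1$estimates["v_L"] - 0.5) / 0.5, 1e-3)

  truth2 <- empirical_model("two_compartment", ka_h = 3.43e-3, cl_L_h = 0.0015,
                            v_L = 0.1, q_L_h = 0.001, v2_L = 0.05,
                            dose_ug = 11720)
  obs2 <- data.frame(time_h = times,
                     conc_ug_mL = predict_empirical(truth2, times))
  init2 <- c(ka_h = 2 * 3.43e-3, cl_L_h = 0.0015 / 2, v_L = 0.2,
             q_L_h = 0.002, v2_L = 0.025)
  fit2 <- fit_empirical(obs2, "two_compartment", dose_ug = 11720,
                        init = init2, seed = 1)
  for (p in names(init2)) {
    expect_lt(abs(fit2$estimates[p] - truth2[[p]]) / truth2[[p]], 1e-3)
  }
  # RSS at the fit is no worse than at the generating truth
  expect_lte(fit2$rss, sum((predict_empirical(truth2, times) -
                              obs2$conc_ug_mL)^2) + 1e-12)
})

test_that("degenerate all-zero data never fits silently", {
  obs <- data.frame(time_h = 24 * (1:8), conc_ug_mL = rep(0, 8))
  expect_error(fit_empirical(obs, "one_compartment", dose_ug = 100),
               "degenerate")
})

test_that("PBPK curve-fit recovers a known clearance", {
  subj <- ref_rat(vd_correction = 5)
  drug <- cabotegravir("im_rat") # CL/F = 0.6 L/h
  reg <- regimen("im", 2.5, horizon_h = 672, grid_h = 2)
  sim <- simulate_subject(subj, drug, reg)
  times <- 24 * c(1, 2, 4, 7, 10, 14, 21, 28)
  obs <- concentration_series(
    times, approx(sim$time_h, sim$conc_ug_mL, xout = times)$y
  )
  drug_start <- drug
  drug_start$clf_L_h <- 0.2 # start away from the truth
  fit <- estimate_clf_by_curvefit(subj, drug_start, reg, obs,
                                  free = "clf_L_h", n_starts = 1)
  expect_lt(abs(fit$estimates["clf_L_h"] - 0.6) / 0.6, 0.01)
})

test_that("1-D clearance profile is unimodal around the optimum", {
  subj <- ref_rat(vd_correction = 5)
  drug <- cabotegravir("im_rat")
  reg <- regimen("im", 2.5, horizon_h = 400, grid_h = 4)
  sim <- simulate_subject(subj, drug, reg)
  times <- 24 * c(1, 3, 7, 14)
  obs_c <- approx(sim$time_h, sim$conc_ug_mL, xout = times)$y
  rss_at <- function(cl) {
    d <- drug; d$clf_L_h <- cl
    s <- simulate_subject(subj, d, reg)
    sum((approx(s$time_h, s$conc_ug_mL, xout = times)$y - obs_c)^2)
  }
  grid <- c(0.15, 0.3, 0.6, 1.2, 2.4)
  rss <- vapply(grid, rss_at, numeric(1))
  expect_equal(which.min(rss), 3L)
  expect_true(all(diff(rss[1:3]) < 0) && all(diff(rss[3:5]) > 0))
})

test_that("derived human patch clearance follows from IM clearance", {
  expect_equal(clf_map_from_im(0.197, 0.20), 0.985)
})
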