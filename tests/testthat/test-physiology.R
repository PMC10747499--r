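test_that("rat cohorts are reproducible, truncated and weight-scaled", {
  c1 <- generate_rat_cohort(100, 0.241, 0.016, seed = 7)
  c2 <- generate_rat_cohort(100, 0.241, 0.016, seed = 7)
  expect_identical(cohort_table(c1), cohort_table(c2))
  w <- sapply(c1, `[[`, "body_weight_kg")
  expect_lt(abs(mean(w) - 0.241), 0.005)
  expect_true(all(abs(w - 0.241) <= 3 * 0.016 + 1e-12))
  # zero-variance cohort
  c0 <- generate_rat_cohort(1, 0.241, 0, seed = 1)
  expect_equal(c0[[1]]$body_weight_kg, 0.241)
  expect_error(generate_rat_cohort(0, 0.241, 0.016, seed = 1), "positive")
})

test_that("rat organ volumes and flows scale linearly with body weight", {
  s1 <- make_subject("rat", body_weight_kg = 0.2)
  s2 <- make_subject("rat", body_weight_kg = 0.4)
  expect_equal(s2$organ_volumes_L, 2 * s1$organ_volumes_L)
  expect_equal(s2$blood_flows_L_h, 2 * s1$blood_flows_L_h)
  expect_equal(s2$cardiac_output_L_h, 2 * s1$cardiac_output_L_h)
})

test_that("human cohorts allocate sex deterministically and close mass balance", {
  co <- generate_human_cohort(100, female_fraction = 0.5, seed = 1)
  sexes <- sapply(co, `[[`, "sex")
  expect_equal(sum(sexes == "female"), 50)
  ages <- sapply(co, `[[`, "age_years")
  expect_true(all(ages >= 18 & ages <= 60))
  for (s in co[c(1, 50, 100)]) {
    expect_true(all(s$organ_volumes_L > 0))
    expect_equal(sum(s$organ_masses_kg), s$body_weight_kg, tolerance = 1e-12)
    # organ blood flows (lung excluded, carried in series) within cardiac output
    expect_lte(sum(s$blood_flows_L_h), s$cardiac_output_L_h * (1 + 1e-12))
  }
  # degenerate age range
  co2 <- generate_human_cohort(2, age_range = c(30, 30), seed = 3)
  expect_equal(sapply(co2, `[[`, "age_years"), c(30, 30))
  expect_error(generate_human_cohort(2, age_range = c(40, 30), seed = 1),
               "interval")
  # reproducibility
  expect_identical(cohort_table(generate_human_cohort(10, seed = 5)),
                   cohort_table(generate_human_cohort(10, seed = 5)))
})

test_that("species skin thicknesses match the model defaults", {
  expect_equal(unname(ref_rat()$skin_thicknesses_um), c(18, 32, 2040))
  expect_equal(unname(ref_human()$skin_thicknesses_um), c(17, 47, 2906))
})

test_that("identical tissue and plasma composition with fu = 1 gives Kp 1", {
  comp <- tissue_composition()
  pl <- comp[comp$tissue == "plasma", c("water", "nlipid", "plipid")]
  comp[, c("water", "nlipid", "plipid")] <-
    pl[rep(1, nrow(comp)), ]
  drug <- drug_parameters(protein_binding_pct = 0)
  ps <- tissue_plasma_partition(drug, comp)
  expect_equal(unname(ps$tp), rep(1, length(ps$tp)), tolerance = 1e-12)
})

test_that("partition coefficients match an independent hand computation", {
  drug <- cabotegravir("map_human")
  ps <- tissue_plasma_partition(drug)
  # independent arithmetic: P = 10^(1.115*1.04 - 1.35), fu = 0.002,
  # fu_t = 1/(1 + 0.5*(0.998/0.002)), plasma term from the composition table
  P <- 10^(1.115 * 1.04 - 1.35)
  den <- P * (0.0035 + 0.3 * 0.00225) + (0.96 + 0.7 * 0.00225)
  kp_muscle <- (P * (0.0238 + 0.3 * 0.0072) + (0.76 + 0.7 * 0.0072)) / den *
    0.002 * (1 + 0.5 * (0.998 / 0.002))
  kp_kidney <- (P * (0.0207 + 0.3 * 0.0162) + (0.783 + 0.7 * 0.0162)) / den *
    0.002 * (1 + 0.5 * (0.998 / 0.002))
  kp_adipose <- (P * (0.79 + 0.3 * 0.002) + (0.18 + 0.7 * 0.002)) / den * 0.002
  expect_equal(unname(ps$tp["muscle"]), kp_muscle, tolerance = 1e-12)
  expect_equal(unname(ps$tp["kidney"]), kp_kidney, tolerance = 1e-12)
  expect_equal(unname(ps$tp["adipose"]), kp_adipose, tolerance = 1e-12)
})

test_that("Kp is monotone in lipid fraction and scales with the correction", {
  drug <- drug_parameters()
  comp <- tissue_composition()
  kps <- sapply(c(0.01, 0.05, 0.1, 0.2), function(nl) {
    comp$nlipid[comp$tissue == "muscle"] <- nl
    tissue_plasma_partition(drug, comp)$tp["muscle"]
  })
  expect_true(all(diff(kps) > 0))
  p1 <- tissue_plasma_partition(drug, vd_correction = 1)
  p2 <- tissue_plasma_partition(drug, vd_correction = 0.01)
  expect_equal(p2$tp, p1$tp * 0.01)
})

test_that("vdss collapses to plasma volume when partitioning vanishes", {
  drug <- drug_parameters()
  s <- ref_human()
  p0 <- tissue_plasma_partition(drug, volumes_L = s$organ_volumes_L,
                                vd_correction = 0)
  expect_equal(p0$vdss_L, unname(s$organ_volumes_L["blood"]) * 0.55)
  p1 <- tissue_plasma_partition(drug, volumes_L = s$organ_volumes_L)
  expect_gt(p1$vdss_L, p0$vdss_L)
})
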