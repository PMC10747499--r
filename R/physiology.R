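#' Default physiology configuration
#'
#' Reference tables used to build virtual subjects: organ mass fractions of
#' body weight, organ densities, blood-flow fractions of cardiac output,
#' cardiac-output allometry, anthropometric regression constants, species
#' skin-layer thicknesses and the default dermal per-area perfusion. Every
#' constant can be overridden by passing a modified copy of this list to the
#' cohort generators.
#'
#' Organ masses are closed on body weight: the residual carcass compartment
#' (`rest`) absorbs the remainder, so the organ masses of every generated
#' subject sum exactly to body weight. Flow fractions (lung excluded; the
#' lung carries total cardiac output in series) sum to 1.
#'
#' @return A nested list of physiological constants.
#' @export
physiology_defaults <- function() {
  organs <- c(
    "adipose", "bone", "brain", "gut", "heart", "kidney",
    "liver", "lung", "muscle", "skin", "spleen", "blood", "rest"
  )
  rat_mass_frac <- c(
    adipose = 0.070, bone = 0.073, brain = 0.0057, gut = 0.027,
    heart = 0.0033, kidney = 0.0073, liver = 0.0366, lung = 0.0050,
    muscle = 0.404, skin = 0.190, spleen = 0.0020, blood = 0.054
  )
  rat_mass_frac <- c(rat_mass_frac, rest = 1 - sum(rat_mass_frac))
  rat_flow_frac <- c(
    adipose = 0.070, bone = 0.122, brain = 0.020, gut = 0.131,
    heart = 0.049, kidney = 0.141, liver = 0.021, muscle = 0.278,
    skin = 0.058, spleen = 0.010
  )
  rat_flow_frac <- c(rat_flow_frac, rest = 1 - sum(rat_flow_frac))

  human_mass_frac_male <- c(
    adipose = 0.213, bone = 0.143, brain = 0.020, gut = 0.017,
    heart = 0.0047, kidney = 0.0044, liver = 0.026, lung = 0.0076,
    muscle = 0.400, skin = 0.037, spleen = 0.0026, blood = 0.076
  )
  human_mass_frac_male <- c(human_mass_frac_male, rest = 1 - sum(human_mass_frac_male))
  human_mass_frac_female <- c(
    adipose = 0.320, bone = 0.120, brain = 0.021, gut = 0.017,
    heart = 0.0042, kidney = 0.0044, liver = 0.024, lung = 0.0066,
    muscle = 0.290, skin = 0.037, spleen = 0.0024, blood = 0.068
  )
  human_mass_frac_female <- c(human_mass_frac_female, rest = 1 - sum(human_mass_frac_female))
  human_flow_frac <- c(
    adipose = 0.050, bone = 0.050, brain = 0.120, gut = 0.150,
    heart = 0.040, kidney = 0.190, liver = 0.065, muscle = 0.170,
    skin = 0.050, spleen = 0.030
  )
  human_flow_frac <- c(human_flow_frac, rest = 1 - sum(human_flow_frac))

  list(
    organs = organs,
    density_g_mL = c(
      adipose = 0.92, bone = 1.30, brain = 1.04, gut = 1.04, heart = 1.03,
      kidney = 1.05, liver = 1.05, lung = 1.05, muscle = 1.04, skin = 1.10,
      spleen = 1.05, blood = 1.06, rest = 1.00
    ),
    rat = list(
      reference_weight_kg = 0.25,
      mass_frac = rat_mass_frac,
      flow_frac = rat_flow_frac,
      # Reference cardiac output scaled linearly with body weight
      cardiac_output_L_h_per_kg = 4.44 / 0.25,
      skin_thicknesses_um = c(sc = 18, ve = 32, de = 2040)
    ),
    human = list(
      mass_frac = list(
        male = human_mass_frac_male,
        female = human_mass_frac_female
      ),
      flow_frac = human_flow_frac,
      cardiac_output_allometry = list(coef_L_h = 14.1, exponent = 0.75),
      anthropometry = list(
        male = list(height_mean_cm = 175.6, height_sd_cm = 7.1,
                    bmi_meanlog = log(26.6), bmi_sdlog = 0.16),
        female = list(height_mean_cm = 162.1, height_sd_cm = 6.6,
                      bmi_meanlog = log(26.5), bmi_sdlog = 0.19),
        bmi_bounds = c(16, 45)
      ),
      skin_thicknesses_um = c(sc = 17, ve = 47, de = 2906)
    ),
    plasma_fraction_of_blood = 0.55,
    dermal_perfusion_mL_h_cm2 = 1.0
  )
}

#' Construct a virtual subject
#'
#' Low-level constructor; most users will call [generate_rat_cohort()] or
#' [generate_human_cohort()].
#'
#' @param species "rat" or "human".
#' @param sex "male", "female" or "n/a".
#' @param age_years Age (years).
#' @param body_weight_kg Body weight (kg).
#' @param height_cm Height (cm, humans).
#' @param config Physiology configuration, see [physiology_defaults()].
#' @param vd_correction Multiplier applied to all tissue:plasma partition
#'   coefficients when the volume of distribution is evaluated for this
#'   subject (an empirical per-route correction).
#' @return An object of class `subject` with organ volumes (L), blood flows
#'   (L/h), cardiac output (L/h), skin thicknesses (um) and anthropometrics.
#' @export
make_subject <- function(species, sex = "n/a", age_years = NA_real_,
                         body_weight_kg, height_cm = NA_real_,
                         config = physiology_defaults(), vd_correction = 1) {
  species <- match.arg(species, c("rat", "human"))
  stopifnot(body_weight_kg > 0, vd_correction > 0)
  if (species == "rat") {
    mass_frac <- config$rat$mass_frac
    flow_frac <- config$rat$flow_frac
    co <- config$rat$cardiac_output_L_h_per_kg * body_weight_kg
    thick <- config$rat$skin_thicknesses_um
  } else {
    sex <- match.arg(sex, c("male", "female"))
    mass_frac <- config$human$mass_frac[[sex]]
    flow_frac <- config$human$flow_frac
    al <- config$human$cardiac_output_allometry
    co <- al$coef_L_h * body_weight_kg^al$exponent
    thick <- config$human$skin_thicknesses_um
  }
  masses_kg <- mass_frac * body_weight_kg
  volumes_L <- masses_kg / config$density_g_mL[names(masses_kg)]
  flows_L_h <- flow_frac * co

  subj <- list(
    species = species, sex = sex, age_years = age_years,
    body_weight_kg = body_weight_kg, height_cm = height_cm,
    organ_masses_kg = masses_kg,
    organ_volumes_L = volumes_L,
    blood_flows_L_h = flows_L_h,
    cardiac_output_L_h = co,
    skin_thicknesses_um = thick,
    plasma_volume_L = unname(volumes_L["blood"]) * config$plasma_fraction_of_blood,
    dermal_perfusion_mL_h_cm2 = config$dermal_perfusion_mL_h_cm2,
    vd_correction = vd_correction
  )
  if (!is.na(height_cm)) {
    subj$bmi <- body_weight_kg / (height_cm / 100)^2
    subj$bsa_m2 <- 0.007184 * body_weight_kg^0.425 * height_cm^0.725
  }
  class(subj) <- "subject"
  subj
}

# Run code under a temporary RNG state so generators are deterministic per
# seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a virtual rat cohort
#'
#' Body weights are drawn from a normal distribution truncated at +/- 3 SD;
#' organ volumes and blood flows scale linearly with body weight from the
#' reference rat.
#'
#' @param n Number of rats.
#' @param weight_mean_kg,weight_sd_kg Cohort weight mean and SD (kg).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param vd_correction Per-route volume-of-distribution correction factor.
#' @param config See [physiology_defaults()].
#' @return List of `subject` objects (class `cohort`).
#' @export
generate_rat_cohort <- function(n, weight_mean_kg, weight_sd_kg, seed,
                                vd_correction = 1,
                                config = physiology_defaults()) {
  if (n < 1 || weight_mean_kg <= 0 || weight_sd_kg < 0) {
    stop("n and weight_mean_kg must be positive; weight_sd_kg non-negative",
         call. = FALSE)
  }
  weights <- with_seed(seed, rnorm_trunc(
    n, weight_mean_kg, weight_sd_kg,
    weight_mean_kg - 3 * weight_sd_kg, weight_mean_kg + 3 * weight_sd_kg
  ))
  weights <- pmax(weights, 1e-6)
  cohort <- lapply(weights, function(w) {
    make_subject("rat", body_weight_kg = w, config = config,
                 vd_correction = vd_correction)
  })
  class(cohort) <- "cohort"
  cohort
}

#' Generate a virtual human cohort
#'
#' Sex is allocated deterministically (`round(female_fraction * n)` females,
#' the rest males); ages are uniform on `age_range`; height is normal and
#' BMI log-normal per sex with configurable constants; weight =
#' BMI * (height/100)^2; organ masses follow the configured body-weight
#' fractions (with a residual carcass term closing mass balance) divided by
#' organ density to give volumes.
#'
#' @param n Cohort size.
#' @param female_fraction Proportion of females.
#' @param age_range Length-2 vector of ages in years.
#' @param seed Integer seed.
#' @param vd_correction Per-route volume-of-distribution correction factor.
#' @param config See [physiology_defaults()].
#' @return List of `subject` objects (class `cohort`).
#' @export
generate_human_cohort <- function(n, female_fraction = 0.5,
                                  age_range = c(18, 60), seed,
                                  vd_correction = 1,
                                  config = physiology_defaults()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (female_fraction < 0 || female_fraction > 1) {
    stop("female_fraction must be in [0, 1]", call. = FALSE)
  }
  if (length(age_range) != 2 || age_range[2] < age_range[1]) {
    stop("age_range must be a non-empty [lo, hi] interval", call. = FALSE)
  }
  n_female <- round(female_fraction * n)
  sexes <- c(rep("female", n_female), rep("male", n - n_female))
  anth <- config$human$anthropometry
  cohort <- with_seed(seed, {
    ages <- stats::runif(n, age_range[1], age_range[2])
    lapply(seq_len(n), function(i) {
      a <- anth[[sexes[i]]]
      h <- stats::rnorm(1, a$height_mean_cm, a$height_sd_cm)
      bmi <- exp(stats::rnorm(1, a$bmi_meanlog, a$bmi_sdlog))
      bmi <- min(max(bmi, anth$bmi_bounds[1]), anth$bmi_bounds[2])
      w <- bmi * (h / 100)^2
      make_subject("human", sex = sexes[i], age_years = ages[i],
                   body_weight_kg = w, height_cm = h, config = config,
                   vd_correction = vd_correction)
    })
  })
  class(cohort) <- "cohort"
  cohort
}

#' Cohort as a data frame
#'
#' One row per subject: anthropometrics plus organ volumes and blood flows
#' in wide format, suitable for CSV export.
#'
#' @param cohort A `cohort`.
#' @return A data.frame.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    base <- data.frame(
      id = i, species = s$species, sex = s$sex, age_years = s$age_years,
      body_weight_kg = s$body_weight_kg, height_cm = s$height_cm,
      cardiac_output_L_h = s$cardiac_output_L_h,
      vd_correction = s$vd_correction
    )
    vols <- as.data.frame(as.list(s$organ_volumes_L))
    names(vols) <- paste0("V_", names(s$organ_volumes_L), "_L")
    flows <- as.data.frame(as.list(s$blood_flows_L_h))
    names(flows) <- paste0("Q_", names(s$blood_flows_L_h), "_L_h")
    cbind(base, vols, flows)
  })
  do.call(rbind, rows)
}

#' Default tissue composition table
#'
#' Fractional water, neutral-lipid and phospholipid content per tissue, plus
#' the plasma reference row, as used by the composition-based partition
#' method. Values are the standard reported mammalian compositions; the same
#' table is used for rat and human.
#'
#' @return data.frame with columns tissue, water, nlipid, plipid.
#' @export
tissue_composition <- function() {
  tab <- data.frame(
    tissue = c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
               "lung", "muscle", "skin", "spleen", "rest", "plasma"),
    water  = c(0.18, 0.439, 0.77, 0.718, 0.758, 0.783, 0.751,
               0.811, 0.760, 0.718, 0.788, 0.760, 0.96),
    nlipid = c(0.790, 0.074, 0.051, 0.0487, 0.0115, 0.0207, 0.0348,
               0.0030, 0.0238, 0.0284, 0.0201, 0.0238, 0.0035),
    plipid = c(0.002, 0.0011, 0.0565, 0.0163, 0.0166, 0.0162, 0.0252,
               0.0090, 0.0072, 0.0111, 0.0198, 0.0072, 0.00225)
  )
  stopifnot(all(tab$water + tab$nlipid + tab$plipid <= 1))
  tab
}

#' Tissue:plasma partition coefficients and volume of distribution
#'
#' Composition-based partitioning: the vegetable-oil:buffer partition
#' coefficient is obtained from LogP as
#' `log10 P_vo:w = 1.115 * logP - 1.35`; for a compound zwitterionic over a
#' wide pH range (here essentially un-ionized at pH 7.4, pKa 10.04 / -0.7)
#' no further ionization adjustment is applied. Per tissue,
#' `Kp = [P * (f_nl + 0.3 f_pl) + (f_w + 0.7 f_pl)]_tissue /
#'       [P * (f_nl + 0.3 f_pl) + (f_w + 0.7 f_pl)]_plasma * fu_p / fu_t`
#' with `fu_t = 1 / (1 + 0.5 * (1 - fu_p) / fu_p)`; for adipose `fu_t = 1`.
#' The subject's `vd_correction` multiplies every Kp at use site.
#'
#' @param drug A `drug_parameters` object (needs `logP`, `fu`).
#' @param comp Tissue composition table from [tissue_composition()].
#' @param volumes_L Optional named organ volumes (L) including `blood`; when
#'   supplied, `vdss_L = V_plasma + sum(V_t * Kp_t)` is also returned
#'   (plasma volume from the blood volume and the configured plasma
#'   fraction).
#' @param vd_correction Multiplier applied to all Kp (default 1).
#' @param plasma_fraction_of_blood Used only for `vdss_L`.
#' @return List with `tp` (named Kp vector, includes `skin`) and optionally
#'   `vdss_L`.
#' @export
tissue_plasma_partition <- function(drug, comp = tissue_composition(),
                                    volumes_L = NULL, vd_correction = 1,
                                    plasma_fraction_of_blood = 0.55) {
  stopifnot(inherits(drug, "drug_parameters"))
  fu <- drug$fu
  if (fu <= 0 || fu > 1) stop("fraction unbound must be in (0, 1]", call. = FALSE)
  P <- 10^(1.115 * drug$logP - 1.35)
  pl <- comp[comp$tissue == "plasma", ]
  if (nrow(pl) != 1) stop("composition table must contain a plasma row", call. = FALSE)
  tis <- comp[comp$tissue != "plasma", ]
  fu_t <- 1 / (1 + 0.5 * (1 - fu) / fu)
  num <- P * (tis$nlipid + 0.3 * tis$plipid) + (tis$water + 0.7 * tis$plipid)
  den <- P * (pl$nlipid + 0.3 * pl$plipid) + (pl$water + 0.7 * pl$plipid)
  kp <- num / den * ifelse(tis$tissue == "adipose", fu, fu / fu_t)
  names(kp) <- tis$tissue
  kp <- kp * vd_correction
  out <- list(tp = kp)
  if (!is.null(volumes_L)) {
    tnames <- intersect(names(volumes_L), names(kp))
    if (!("blood" %in% names(volumes_L))) {
      stop("volumes_L must include 'blood' to compute vdss", call. = FALSE)
    }
    vp <- unname(volumes_L["blood"]) * plasma_fraction_of_blood
    out$vdss_L <- vp + sum(volumes_L[tnames] * kp[tnames])
    out$plasma_volume_L <- vp
  }
  out
}
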