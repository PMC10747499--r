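#' Drug physicochemical and pharmacokinetic parameters
#'
#' Container for the compound-specific constants used across the model:
#' physicochemistry (molecular weight, LogP, pKa, plasma protein binding,
#' polar surface area, blood:plasma ratio), skin permeability/partition
#' coefficients (QSPR-derived, taken as configuration constants), and the
#' route-specific kinetic constants — nanoparticle release rate `knp_h`
#' (1/h), trans-skin volumetric rate `kskin_cm3_h` (cm3/h) and apparent
#' clearance `clf_L_h` (L/h).
#'
#' @param molecular_weight g/mol.
#' @param hbd Hydrogen-bond donor count.
#' @param logP Octanol:water log partition coefficient.
#' @param pKa Numeric vector of dissociation constants.
#' @param protein_binding_pct Plasma protein binding (%); fraction unbound is
#'   `1 - protein_binding_pct/100`.
#' @param psa_A2 Polar surface area (squared Angstrom).
#' @param R Blood-to-plasma concentration ratio.
#' @param bioavailability Fractional bioavailability of the patch route
#'   relative to intramuscular dosing.
#' @param clf_L_h Apparent clearance CL/F (L/h) for the simulated route.
#' @param knp_h Nanoparticle release rate constant (1/h).
#' @param kskin_cm3_h Trans-skin volumetric rate constant (cm3/h); required
#'   for patch simulations.
#' @param pc_sc_w,pc_ve_w,pc_de_w Permeability coefficients between each
#'   skin layer and water (cm/h).
#' @param pc_sc_ve,pc_ve_de Partition coefficients between adjacent layers.
#' @return Object of class `drug_parameters`.
#' @export
drug_parameters <- function(molecular_weight = 405.358,
                            hbd = 2,
                            logP = 1.04,
                            pKa = c(10.04, -0.7),
                            protein_binding_pct = 99.8,
                            psa_A2 = 99.18,
                            R = 0.5,
                            bioavailability = 0.20,
                            clf_L_h = NA_real_,
                            knp_h = NA_real_,
                            kskin_cm3_h = NA_real_,
                            pc_sc_w = 0.304,
                            pc_ve_w = 0.106,
                            pc_de_w = 0.106,
                            pc_sc_ve = 3.993,
                            pc_ve_de = 1) {
  stopifnot(
    molecular_weight > 0, logP > -10, protein_binding_pct >= 0,
    protein_binding_pct < 100, R > 0, R <= 2,
    pc_sc_w > 0, pc_ve_w > 0, pc_de_w > 0, pc_sc_ve > 0, pc_ve_de > 0
  )
  structure(
    list(
      molecular_weight = molecular_weight, hbd = hbd, logP = logP, pKa = pKa,
      protein_binding_pct = protein_binding_pct,
      fu = 1 - protein_binding_pct / 100,
      psa_A2 = psa_A2, R = R, bioavailability = bioavailability,
      clf_L_h = clf_L_h, knp_h = knp_h, kskin_cm3_h = kskin_cm3_h,
      pc_sc_w = pc_sc_w, pc_ve_w = pc_ve_w, pc_de_w = pc_de_w,
      pc_sc_ve = pc_sc_ve, pc_ve_de = pc_ve_de
    ),
    class = "drug_parameters"
  )
}

#' Cabotegravir parameter sets per species and route
#'
#' Returns [drug_parameters()] pre-filled with the cabotegravir constants
#' plus the route/species-specific estimated kinetics:
#' \itemize{
#'   \item `im_rat`: K_NP 3e-3 1/h, CL/F 0.6 L/h, Vd correction 5
#'   \item `map_rat`: K_NP 3.43e-3 1/h, K_SKIN 1.73e-3 cm3/h,
#'         CL/F 0.01 L/h, Vd correction 0.05
#'   \item `im_human`: K_NP 4.54e-4 1/h, CL/F 0.197 L/h, Vd correction 0.01
#'   \item `map_human`: K_NP 3.43e-3 1/h, K_SKIN 1.73e-3 cm3/h,
#'         CL/F 0.197/0.20 = 0.985 L/h, Vd correction 0.01
#' }
#' The recommended per-route volume-of-distribution correction factor is
#' attached as the `vd_correction` element (it belongs to the subject, not
#' the drug; pass it to the cohort generators).
#'
#' @param route One of "im_rat", "map_rat", "im_human", "map_human".
#' @return A `drug_parameters` object with an extra `vd_correction` element.
#' @export
cabotegravir <- function(route = c("im_rat", "map_rat", "im_human", "map_human")) {
  route <- match.arg(route)
  base <- drug_parameters()
  set <- switch(route,
    im_rat = list(clf_L_h = 0.6, knp_h = 3e-3, vd = 5),
    map_rat = list(clf_L_h = 0.01, knp_h = 3.43e-3, kskin_cm3_h = 1.73e-3, vd = 0.05),
    im_human = list(clf_L_h = 0.197, knp_h = 4.54e-4, vd = 0.01),
    map_human = list(clf_L_h = 0.197 / 0.20, knp_h = 3.43e-3,
                     kskin_cm3_h = 1.73e-3, vd = 0.01)
  )
  base$clf_L_h <- set$clf_L_h
  base$knp_h <- set$knp_h
  if (!is.null(set$kskin_cm3_h)) base$kskin_cm3_h <- set$kskin_cm3_h
  base$vd_correction <- set$vd
  base
}

#' Apparent clearance of the patch route from the intramuscular route
#'
#' `CL/F_MAP = CL/F_IM / F_MAP`: the patch bioavailability is folded into
#' the apparent clearance, so no separate bioavailability factor is applied
#' in patch simulations.
#'
#' @param clf_im_L_h Intramuscular apparent clearance (L/h).
#' @param bioavailability Patch bioavailability relative to IM (fraction).
#' @return CL/F for the patch route (L/h).
#' @export
clf_map_from_im <- function(clf_im_L_h, bioavailability = 0.20) {
  stopifnot(clf_im_L_h > 0, bioavailability > 0, bioavailability <= 1)
  clf_im_L_h / bioavailability
}
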