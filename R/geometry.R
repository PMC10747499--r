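#' Microarray-patch (MAP) design
#'
#' Describes a dissolving bilayer microneedle array: right rectangular
#' pyramid needles on a drug-free cuboidal base. Defaults correspond to the
#' bilayer cabotegravir MAP platform: a 0.49 cm2 baseplate carrying a
#' 16 x 16 array of 600 um tall pyramidal needles (300 x 300 um footprint,
#' 100 um interspacing) on a 250 um drug-free base, inserted to 97% of the
#' tip height, with a drug loading of 5.86 mg per cm2 of patch.
#'
#' @param baseplate_area_cm2 Area of one baseplate unit (cm2).
#' @param needles_per_baseplate Number of needles on one baseplate.
#' @param needle_height_um Pyramid tip height (um).
#' @param needle_width_um,needle_length_um Footprint of the pyramid base (um).
#' @param interspacing_um Edge-to-edge needle spacing (um); recorded for
#'   completeness, not used in the kinetics.
#' @param base_height_um Height of the drug-free cuboidal base (um).
#' @param insertion_fraction Fraction of the tip height inserted into skin.
#' @param dose_loading_mg_cm2 Drug loading per unit patch area (mg/cm2).
#' @return An object of class `map_design`.
#' @export
map_design <- function(baseplate_area_cm2 = 0.49,
                       needles_per_baseplate = 256,
                       needle_height_um = 600,
                       needle_width_um = 300,
                       needle_length_um = 300,
                       interspacing_um = 100,
                       base_height_um = 250,
                       insertion_fraction = 0.97,
                       dose_loading_mg_cm2 = 5.86) {
  stopifnot(
    baseplate_area_cm2 > 0, needles_per_baseplate >= 1,
    needle_height_um > 0, needle_width_um > 0, needle_length_um > 0,
    base_height_um >= 0, dose_loading_mg_cm2 > 0
  )
  if (insertion_fraction <= 0 || insertion_fraction > 1) {
    stop("insertion_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      baseplate_area_cm2 = baseplate_area_cm2,
      needles_per_baseplate = needles_per_baseplate,
      needle_height_um = needle_height_um,
      needle_width_um = needle_width_um,
      needle_length_um = needle_length_um,
      interspacing_um = interspacing_um,
      base_height_um = base_height_um,
      insertion_fraction = insertion_fraction,
      dose_loading_mg_cm2 = dose_loading_mg_cm2
    ),
    class = "map_design"
  )
}

#' Volume of a pyramidal needle segment measured from the tip
#'
#' For a right rectangular pyramid (apex = needle tip), returns the volume of
#' the segment lying within distance `s_um` of the tip. Cross-sections scale
#' linearly from the apex, so V(s) = w*l*s^3 / (3*h^2).
#'
#' @param s_um Distance from the tip (um); may be a vector.
#' @param design A `map_design`.
#' @return Volume(s) in um3.
#' @export
pyramid_volume_from_tip <- function(s_um, design) {
  stopifnot(inherits(design, "map_design"))
  h <- design$needle_height_um
  if (any(s_um < 0 | s_um > h)) {
    stop("s_um must lie in [0, needle_height_um]", call. = FALSE)
  }
  design$needle_width_um * design$needle_length_um * s_um^3 / (3 * h^2)
}

#' Lateral surface area of a pyramidal needle segment measured from the tip
#'
#' Lateral (slant-face) area of the apex segment within distance `s_um` of
#' the tip. Faces are similar triangles, so area scales as (s/h)^2 of the
#' full lateral area w*sqrt(h^2+(l/2)^2) + l*sqrt(h^2+(w/2)^2).
#'
#' @inheritParams pyramid_volume_from_tip
#' @return Lateral area(s) in um2.
#' @export
pyramid_lateral_area_from_tip <- function(s_um, design) {
  stopifnot(inherits(design, "map_design"))
  h <- design$needle_height_um
  w <- design$needle_width_um
  l <- design$needle_length_um
  if (any(s_um < 0 | s_um > h)) {
    stop("s_um must lie in [0, needle_height_um]", call. = FALSE)
  }
  full <- w * sqrt(h^2 + (l / 2)^2) + l * sqrt(h^2 + (w / 2)^2)
  full * (s_um / h)^2
}

#' Partition the inserted needle volume across skin layers
#'
#' The inserted tip (depth coordinate 0 at the skin surface, apex at
#' insertion depth = insertion_fraction * needle_height) is sliced at the
#' stratum corneum / viable epidermis / dermis boundaries. Per layer it
#' returns the needle volume, lateral needle surface area, and the fraction
#' of the delivered dose (volume-proportional, normalized over the inserted
#' volume). Layer boundaries are half-open [top, bottom).
#'
#' @param design A `map_design`.
#' @param thicknesses_um Numeric length-3 vector: stratum corneum, viable
#'   epidermis, dermis thickness (um).
#' @param patch_area_cm2 Total patch area (cm2); needle count is scaled as
#'   `patch_area / baseplate_area * needles_per_baseplate` (fractional
#'   baseplates allowed).
#' @return An object of class `layer_geometry`: a list with per-layer vectors
#'   (named sc/ve/de) `V_MN_mL`, `SA_MN_cm2`, `dose_fraction`, plus
#'   `V_layer_mL` (skin compartment volumes under the patch), the needle
#'   count and the insertion depth.
#' @export
layer_partition <- function(design, thicknesses_um, patch_area_cm2 = design$baseplate_area_cm2) {
  stopifnot(inherits(design, "map_design"), length(thicknesses_um) == 3)
  if (any(thicknesses_um <= 0)) {
    stop("skin layer thicknesses must all be positive", call. = FALSE)
  }
  depth_ins <- design$insertion_fraction * design$needle_height_um
  if (depth_ins > sum(thicknesses_um)) {
    stop("insertion depth exceeds total skin thickness", call. = FALSE)
  }
  bounds <- cumsum(c(0, thicknesses_um)) # depths of layer boundaries
  layers <- c("sc", "ve", "de")

  n_needles <- patch_area_cm2 / design$baseplate_area_cm2 * design$needles_per_baseplate
  v_ins <- pyramid_volume_from_tip(depth_ins, design)

  V_um3 <- SA_um2 <- numeric(3)
  for (i in 1:3) {
    # layer occupies depths [bounds[i], bounds[i+1]); needle tip coordinate
    # s = depth_ins - depth, clipped to the inserted segment [0, depth_ins]
    s_hi <- min(max(depth_ins - bounds[i], 0), depth_ins)
    s_lo <- min(max(depth_ins - bounds[i + 1], 0), depth_ins)
    V_um3[i] <- pyramid_volume_from_tip(s_hi, design) - pyramid_volume_from_tip(s_lo, design)
    SA_um2[i] <- pyramid_lateral_area_from_tip(s_hi, design) - pyramid_lateral_area_from_tip(s_lo, design)
  }
  names(V_um3) <- names(SA_um2) <- layers

  out <- list(
    V_MN_mL = V_um3 * n_needles * 1e-12, # 1 um3 = 1e-12 mL
    SA_MN_cm2 = SA_um2 * n_needles * 1e-8, # 1 um2 = 1e-8 cm2
    dose_fraction = V_um3 / v_ins,
    V_layer_mL = skin_compartment_volumes(patch_area_cm2, thicknesses_um),
    n_needles = n_needles,
    insertion_depth_um = depth_ins,
    patch_area_cm2 = patch_area_cm2,
    thicknesses_um = thicknesses_um
  )
  class(out) <- "layer_geometry"
  out
}

#' Patch area required for a nominal dose
#'
#' @param dose_mg Nominal dose (mg).
#' @param dose_loading_mg_cm2 Drug loading (mg/cm2).
#' @param design Optional `map_design` used to also report the effective
#'   (possibly fractional) needle count.
#' @return A list with `area_cm2` and, when `design` is given, `n_needles`.
#' @export
patch_area_for_dose <- function(dose_mg, dose_loading_mg_cm2 = 5.86, design = NULL) {
  if (dose_mg <= 0 || dose_loading_mg_cm2 <= 0) {
    stop("dose and dose loading must be positive", call. = FALSE)
  }
  area <- dose_mg / dose_loading_mg_cm2
  out <- list(area_cm2 = area)
  if (!is.null(design)) {
    out$n_needles <- area / design$baseplate_area_cm2 * design$needles_per_baseplate
  }
  out
}

#' Skin compartment volumes under the patch
#'
#' Volume of each skin layer beneath the patch footprint,
#' `patch_area * thickness`. Needle volume is not subtracted by default (it
#' is < 0.5% of the dermis volume at these designs).
#'
#' @param patch_area_cm2 Patch area (cm2).
#' @param thicknesses_um Length-3 vector of layer thicknesses (um).
#' @param subtract_needle_mL Optional length-3 vector of needle volumes to
#'   subtract (mL).
#' @return Named numeric vector (sc, ve, de) of volumes in mL.
#' @export
skin_compartment_volumes <- function(patch_area_cm2, thicknesses_um,
                                     subtract_needle_mL = c(0, 0, 0)) {
  stopifnot(patch_area_cm2 > 0, all(thicknesses_um > 0))
  v <- patch_area_cm2 * thicknesses_um * 1e-4 - subtract_needle_mL # um -> cm
  if (any(v <= 0)) stop("non-positive skin compartment volume", call. = FALSE)
  names(v) <- c("sc", "ve", "de")
  v
}
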