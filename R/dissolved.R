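#' Convert a % w/v solubility to molarity
#'
#' Interprets `percent` as grams of solute per 100 cm^3 of solution (% w/v),
#' i.e. `percent * 10` g dm^-3, and divides by the molar mass:
#' molarity = percent * 10 / M. This is the reading under which the
#' equilibrium solubility of amorphous silica, 0.012%, corresponds to
#' 0.002 mol dm^-3 with M = 60.08 g mol^-1.
#'
#' @param percent Solubility, % w/v (>= 0).
#' @param molar_mass Molar mass, g mol^-1 (> 0).
#' @return Concentration, mol dm^-3.
#' @examples
#' percent_wv_to_molar(0.012)  # ~0.002 mol dm^-3 for SiO2
#' @export
percent_wv_to_molar <- function(percent, molar_mass = model_constants()$silica_molar_mass) {
  if (!is.numeric(percent) || any(percent < 0)) {
    stop("percent must be non-negative", call. = FALSE)
  }
  if (!is.numeric(molar_mass) || any(molar_mass <= 0)) {
    stop("molar_mass must be positive", call. = FALSE)
  }
  percent * 10 / molar_mass
}

#' Inverse of [percent_wv_to_molar()]
#' @param molar Concentration, mol dm^-3.
#' @param molar_mass Molar mass, g mol^-1.
#' @return Solubility, % w/v.
#' @export
molar_to_percent_wv <- function(molar, molar_mass = model_constants()$silica_molar_mass) {
  if (!is.numeric(molar) || any(molar < 0)) stop("molar must be non-negative", call. = FALSE)
  molar * molar_mass / 10
}

#' Footprint of a dissolved SiO2 tetrahedron
#'
#' Dissolved SiO2 species (Si(OH)4 and its anion) are tetrahedrally
#' coordinated; close-packed flat on the lipid surface, each occupies the
#' tetrahedron's equilateral base, area (sqrt(3)/4) d^2 for O-O distance d.
#'
#' @param oo_distance O-O distance, nm (default 0.26).
#' @return Area, nm^2 (~0.0293 for the default distance).
#' @export
tetrahedron_base_area <- function(oo_distance = 0.26) {
  if (!is.numeric(oo_distance) || any(oo_distance <= 0)) {
    stop("oo_distance must be positive", call. = FALSE)
  }
  (sqrt(3) / 4) * oo_distance^2
}

#' Reactive area of dissolved SiO2
#'
#' Total area covered when every dissolved SiO2 tetrahedron in `moles` of
#' solute close-packs flat on the DOPC surface:
#' area = moles * N_A * footprint, with footprint converted nm^2 -> cm^2
#' (factor 1e-14).
#'
#' @param moles Amount of dissolved SiO2, mol (>= 0).
#' @param footprint_nm2 Per-molecule footprint, nm^2 (>= 0).
#' @param const A [model_constants()] object (supplies the Avogadro-scale
#'   count).
#' @return Area, cm^2.
#' @examples
#' dissolved_reactive_area(0.002, 0.03)  # ~3.6e5 cm^2
#' @export
dissolved_reactive_area <- function(moles, footprint_nm2 = tetrahedron_base_area(),
                                    const = model_constants()) {
  if (!is.numeric(moles) || any(moles < 0)) stop("moles must be non-negative", call. = FALSE)
  if (!is.numeric(footprint_nm2) || any(footprint_nm2 < 0)) {
    stop("footprint must be non-negative", call. = FALSE)
  }
  moles * const$molecules_per_mol * footprint_nm2 * 1e-14
}

#' Particulate-versus-dissolved competition ratio
#'
#' Ratio of the reactive area of the particulate silica to that of the
#' dissolved species; both compete for the same DOPC surface, so a ratio
#' above 1 means the surface is predominantly occupied by particles.
#'
#' @param particulate_area Reactive area of the particulate silica, cm^2.
#' @param dissolved_area Reactive area of the dissolved species, cm^2 (> 0).
#' @return List: `ratio`, `particulate_dominated` (logical, ratio > 1).
#' @export
competition_ratio <- function(particulate_area, dissolved_area) {
  if (!is.numeric(dissolved_area) || any(dissolved_area <= 0)) {
    stop("dissolved_area must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(particulate_area) || any(particulate_area < 0)) {
    stop("particulate_area must be non-negative", call. = FALSE)
  }
  ratio <- particulate_area / dissolved_area
  list(ratio = ratio, particulate_dominated = ratio > 1)
}

#' Full dissolved-silica supernatant report
#'
#' Chains the supernatant arithmetic: solubility % w/v -> molarity, O-O
#' distance -> tetrahedral footprint, footprint + amount -> dissolved
#' reactive area, and (given a particulate dispersion) the competition
#' ratio.
#'
#' @param solubility_percent Equilibrium solubility, % w/v (default 0.012).
#' @param oo_distance_nm O-O distance, nm (default 0.26).
#' @param volume_dm3 Solution volume, dm^3 (default 1; the dissolved amount
#'   is molarity * volume).
#' @param particulate_mmol Amount of particulate SiO2, mmol (default 169).
#' @param particulate_radius_cm Particle radius, cm (default 17.5 nm).
#' @param const A [model_constants()] object.
#' @return Named list with every intermediate and final quantity.
#' @export
dissolved_silica_report <- function(solubility_percent = 0.012,
                                    oo_distance_nm = 0.26,
                                    volume_dm3 = 1,
                                    particulate_mmol = 169,
                                    particulate_radius_cm = nm_to_cm(17.5),
                                    const = model_constants()) {
  molar <- percent_wv_to_molar(solubility_percent, const$silica_molar_mass)
  footprint <- tetrahedron_base_area(oo_distance_nm)
  moles <- molar * volume_dm3
  dissolved_area <- dissolved_reactive_area(moles, footprint, const)
  particulate_area <- particulate_mmol *
    reactive_area_per_mmol(particulate_radius_cm, const)
  comp <- competition_ratio(particulate_area, dissolved_area)
  list(
    solubility_percent_wv = solubility_percent,
    molar_concentration = molar,
    oo_distance_nm = oo_distance_nm,
    footprint_nm2 = footprint,
    dissolved_moles = moles,
    dissolved_reactive_area_cm2 = dissolved_area,
    particulate_mmol = particulate_mmol,
    particulate_radius_cm = particulate_radius_cm,
    particulate_reactive_area_cm2 = particulate_area,
    competition_ratio = comp$ratio,
    particulate_dominated = comp$particulate_dominated
  )
}
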