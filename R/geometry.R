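#' Number of SiO2 molecules in one nanoparticle
#'
#' The molecule count per particle, C_tr, follows from the particle volume,
#' the density of amorphous silica and its molar mass:
#' C_tr = N_A * (4/3) pi R^3 * rho / M.
#'
#' @param R Particle radius, cm (vectorised).
#' @param const A [model_constants()] object.
#' @return Molecule count per particle.
#' @examples
#' molecules_per_particle(1.75e-6)  # ~4.9e5 for a 17.5 nm radius particle
#' @export
molecules_per_particle <- function(R, const = model_constants()) {
  check_radius(R)
  const$molecules_per_mol * (4 / 3) * pi * R^3 * const$silica_density /
    const$silica_molar_mass
}

#' Reactive area of a single particle
#'
#' The reactive area of one particle is the zone of its surface lying within
#' the reaction layer of thickness h above the lipid plane: pi (2Rh + h^2),
#' the area of the spherical cap's projection annulus. h = 0 gives zero area.
#'
#' @param R Particle radius, cm.
#' @param h Reaction-layer thickness, cm (non-negative).
#' @return Area, cm^2.
#' @export
reactive_area_per_particle <- function(R, h = model_constants()$reaction_layer_thickness_h) {
  check_radius(R)
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0)) {
    stop("h must be non-negative and finite", call. = FALSE)
  }
  pi * (2 * R * h + h^2)
}

#' Number of particles containing 1 mmol of SiO2
#'
#' @param R Particle radius, cm.
#' @param const A [model_constants()] object.
#' @return Particle count per mmol of SiO2.
#' @export
particles_per_mmol <- function(R, const = model_constants()) {
  const$molecules_per_mmol / molecules_per_particle(R, const)
}

#' Specific reactive area per mmol of SiO2
#'
#' The model's currency for adsorption capacity: the total reactive area, per
#' mmol of SiO2 dispersed as particles of radius R,
#' A(R) = pi (2Rh + h^2) * N_particles_per_mmol.
#' Equivalently (the molecule-count form) A = molecules_per_mmol *
#' pi (2Rh + h^2) / C_tr. Strictly decreasing in R for R >> h: larger
#' particles bury more of their SiO2 away from the interface.
#'
#' @param R Particle radius, cm (vectorised).
#' @param const A [model_constants()] object.
#' @return Area per amount, cm^2 mmol^-1 (SiO2 basis).
#' @examples
#' # 0.169 mol of SiO2 as 17.5 nm-radius particles: ~8e5 cm^2 in total
#' 169 * reactive_area_per_mmol(nm_to_cm(17.5))
#' @export
reactive_area_per_mmol <- function(R, const = model_constants()) {
  reactive_area_per_particle(R, const$reaction_layer_thickness_h) *
    particles_per_mmol(R, const)
}

#' Hexagonal close-packed area of 1 mmol of particles
#'
#' The surface area occupied by a mmol of nanoparticles when hexagonally
#' close-packed: SA = molecules_per_mmol * 2 sqrt(3) R^2 (each particle's
#' hexagonal footprint is 2 sqrt(3) R^2). Its reciprocal is the close-packed
#' particle coverage per cm^2.
#'
#' @param R Particle radius, cm.
#' @param const A [model_constants()] object.
#' @return Area per amount, cm^2 mmol^-1 (particle basis).
#' @export
close_packed_area_per_mmol <- function(R, const = model_constants()) {
  check_radius(R)
  const$molecules_per_mmol * 2 * sqrt(3) * R^2
}

#' Size-specific maximum depression of capacitance peak 2
#'
#' A confluent close-packed layer of particles of radius R suppresses peak 2
#' by full_current * pi (2Rh + h^2) / (2 sqrt(3) R^2), the fraction of each
#' hexagonal footprint that is reactive area. Below the crossover radius
#' (see [cap_radius()]) the reactive areas of close-packed particles are
#' already confluent and the depression saturates at the full-suppression
#' current: the ratio is capped at 1.
#'
#' @param R Particle radius, cm (vectorised).
#' @param const A [model_constants()] object.
#' @return Current, uA; never exceeds `const$full_suppression_current`.
#' @export
max_depression_model <- function(R, const = model_constants()) {
  check_radius(R)
  h <- const$reaction_layer_thickness_h
  ratio <- pi * (2 * R * h + h^2) / (2 * sqrt(3) * R^2)
  const$full_suppression_current * pmin(1, ratio)
}

#' Crossover radius of the maximum-depression cap
#'
#' The radius at which the reactive area of a particle equals its hexagonal
#' close-packed footprint, pi (2Rh + h^2) = 2 sqrt(3) R^2; below it the model
#' depression saturates at full suppression. Positive root of the quadratic
#' 2 sqrt(3) R^2 - 2 pi h R - pi h^2 = 0:
#' R* = h (pi + sqrt(pi^2 + 2 sqrt(3) pi)) / (2 sqrt(3)).
#'
#' @param const A [model_constants()] object.
#' @return Radius, cm (~7.18e-7 cm for the default h).
#' @export
cap_radius <- function(const = model_constants()) {
  h <- const$reaction_layer_thickness_h
  h * (pi + sqrt(pi^2 + 2 * sqrt(3) * pi)) / (2 * sqrt(3))
}

#' The v factor converting normalized rates to rate constants
#'
#' v is the size-specific maximum peak depression multiplied by the
#' close-packed area SA of a mmol of particles. With the model depression the
#' products collapse to the printed form
#' v = full_current * pi (2Rh + h^2) * molecules_per_mmol (uncapped).
#' Supplying `max_depression` (e.g. the experimentally observed plateau
#' depression for that size) gives the experimental variant
#' v = max_depression * SA(R).
#'
#' @param R Particle radius, cm.
#' @param const A [model_constants()] object.
#' @param max_depression Optional observed maximum depression, uA, in
#'   (0, full_suppression_current].
#' @return uA cm^2 mmol^-1.
#' @export
v_factor <- function(R, const = model_constants(), max_depression = NULL) {
  check_radius(R)
  if (is.null(max_depression)) {
    return(const$full_suppression_current *
             reactive_area_per_particle(R, const$reaction_layer_thickness_h) *
             const$molecules_per_mmol)
  }
  if (!is.numeric(max_depression) || any(!is.finite(max_depression)) ||
      any(max_depression <= 0) ||
      any(max_depression > const$full_suppression_current + 1e-9)) {
    stop("max_depression must lie in (0, full_suppression_current]", call. = FALSE)
  }
  max_depression * close_packed_area_per_mmol(R, const)
}

#' Per-size geometry summary table
#'
#' Evaluates the full reaction-layer geometry for a set of radii.
#'
#' @param radii_cm Radii, cm.
#' @param const A [model_constants()] object.
#' @return A data.frame with one row per radius: `radius_cm`, `radius_nm`,
#'   `per_particle_area_cm2`, `A_cm2_per_mmol`, `particles_per_mmol`,
#'   `Ctr_molecules`, `SA_cm2_per_mmol`, `delta_I_max_uA`,
#'   `v_model_uA_cm2_per_mmol`.
#' @export
geometry_table <- function(radii_cm, const = model_constants()) {
  check_radius(radii_cm, sanity = TRUE, what = "radii_cm")
  data.frame(
    radius_cm = radii_cm,
    radius_nm = cm_to_nm(radii_cm),
    per_particle_area_cm2 = reactive_area_per_particle(radii_cm, const$reaction_layer_thickness_h),
    A_cm2_per_mmol = reactive_area_per_mmol(radii_cm, const),
    particles_per_mmol = particles_per_mmol(radii_cm, const),
    Ctr_molecules = molecules_per_particle(radii_cm, const),
    SA_cm2_per_mmol = close_packed_area_per_mmol(radii_cm, const),
    delta_I_max_uA = max_depression_model(radii_cm, const),
    v_model_uA_cm2_per_mmol = v_factor(radii_cm, const)
  )
}
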