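#' Physical and model constants of the reaction-layer model
#'
#' Bundles the fixed parameters every equation of the reaction-layer model
#' draws on: the reaction-layer thickness `h`, the density and molar mass of
#' amorphous silica, the capacitance current corresponding to full suppression
#' of peak 2, and the Avogadro-scale molecule counts per mmol and per mol.
#'
#' The molecule counts default to the three-significant-figure value
#' 6.02e20 mmol^-1 (6.02e23 mol^-1) so that worked examples quoted at printed
#' precision reproduce exactly; pass the CODATA value if full precision is
#' preferred.
#'
#' @param reaction_layer_thickness_h Reaction-layer thickness, cm. The
#'   interfacial shell around a silica particle within which interaction with
#'   the lipid layer occurs.
#' @param silica_density Density of amorphous silica, g cm^-3.
#' @param silica_molar_mass Molar mass of SiO2, g mol^-1.
#' @param full_suppression_current Capacitance current peak-2 height fully
#'   suppressed by a confluent close-packed particle layer, uA.
#' @param molecules_per_mmol Number of SiO2 molecules in 1 mmol.
#' @param molecules_per_mol Number of SiO2 molecules in 1 mol; must equal
#'   `1000 * molecules_per_mmol`.
#'
#' @return An object of class `model_constants`: a named list of the six
#'   validated fields.
#' @examples
#' const <- model_constants()
#' const$reaction_layer_thickness_h
#' @export
model_constants <- function(reaction_layer_thickness_h = 3.23e-7,
                            silica_density = 2.196,
                            silica_molar_mass = 60.08,
                            full_suppression_current = 32.1,
                            molecules_per_mmol = 6.02e20,
                            molecules_per_mol = 1000 * molecules_per_mmol) {
  const <- list(
    reaction_layer_thickness_h = reaction_layer_thickness_h,
    silica_density = silica_density,
    silica_molar_mass = silica_molar_mass,
    full_suppression_current = full_suppression_current,
    molecules_per_mmol = molecules_per_mmol,
    molecules_per_mol = molecules_per_mol
  )
  for (nm in names(const)) {
    x <- const[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("model_constants: `", nm, "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (abs(const$molecules_per_mol - 1000 * const$molecules_per_mmol) >
      1e-9 * const$molecules_per_mol) {
    stop("model_constants: molecules_per_mol must equal 1000 * molecules_per_mmol",
         call. = FALSE)
  }
  structure(const, class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Reaction-layer model constants:\n")
  cat(sprintf("  reaction layer thickness h : %.4g cm\n", x$reaction_layer_thickness_h))
  cat(sprintf("  silica density             : %.4g g cm^-3\n", x$silica_density))
  cat(sprintf("  silica molar mass          : %.4g g mol^-1\n", x$silica_molar_mass))
  cat(sprintf("  full-suppression current   : %.4g uA\n", x$full_suppression_current))
  cat(sprintf("  molecules per mmol         : %.4g\n", x$molecules_per_mmol))
  cat(sprintf("  molecules per mol          : %.4g\n", x$molecules_per_mol))
  invisible(x)
}

#' Build model constants from a configuration list
#'
#' Accepts the `constants:` block of a JSON/YAML run configuration (any subset
#' of the `model_constants()` field names) and fills unspecified fields with
#' the defaults.
#'
#' @param config A named list, e.g. parsed from JSON or YAML; `NULL` gives the
#'   defaults.
#' @return A `model_constants` object.
#' @export
constants_from_config <- function(config = NULL) {
  if (is.null(config)) return(model_constants())
  if (!is.list(config)) stop("constants config must be a named list", call. = FALSE)
  allowed <- names(formals(model_constants))
  bad <- setdiff(names(config), allowed)
  if (length(bad)) {
    stop("unknown constants field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(model_constants, config)
}

#' Convert radii between nm and cm
#'
#' All internal computation uses cm because every model formula is stated in
#' cm; nm is accepted at the input boundary (manifests, human-facing tables)
#' and converted once.
#'
#' @param r_nm,r_cm Radii in nm / cm.
#' @return Numeric vector of converted radii.
#' @export
nm_to_cm <- function(r_nm) r_nm * 1e-7

#' @rdname nm_to_cm
#' @export
cm_to_nm <- function(r_cm) r_cm * 1e7

# Shared guard: radius strictly positive, finite; optionally sanity-bounded to
# the colloidal range 1e-7..1e-4 cm (1 nm .. 1 um) to catch nm-vs-cm mix-ups.
check_radius <- function(R, sanity = FALSE, what = "R") {
  if (!is.numeric(R) || any(!is.finite(R)) || any(R <= 0)) {
    stop(what, " must be positive and finite (radius in cm)", call. = FALSE)
  }
  if (sanity && (any(R < 1e-7) || any(R > 1e-4))) {
    stop(what, " outside the sanity range 1e-7..1e-4 cm; ",
         "radii look like they were passed in the wrong unit (nm vs cm)",
         call. = FALSE)
  }
  invisible(R)
}
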