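#' Bottom-up heterogeneous rate constant k1
#'
#' The bottom-up derivation treats adsorption as deposition of SiO2 molecular
#' units: the slope of the k'-versus-A plot, multiplied by 1000 to convert
#' the concentration basis from mmol dm^-3 to mmol cm^-3, divided by the
#' full-suppression current, gives the heterogeneous rate constant
#' k1 = 1000 * slope / I_full in cm s^-1. The SD scales identically.
#'
#' @param slope Slope of k' vs A, uA cm s^-1 (after the 1000x convention).
#' @param slope_sd Its standard deviation (same units); default 0.
#' @param const A [model_constants()] object.
#' @return List of class `rate_constant`: `k` (cm s^-1), `k_sd`.
#' @examples
#' k1_bottom_up(1.36e-5)  # ~4.24e-4 cm s^-1
#' @export
k1_bottom_up <- function(slope, slope_sd = 0, const = model_constants()) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0) {
    stop("slope must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(slope_sd) || slope_sd < 0) {
    stop("slope_sd must be non-negative", call. = FALSE)
  }
  scale <- 1000 / const$full_suppression_current
  structure(list(k = scale * slope, k_sd = scale * slope_sd),
            class = "rate_constant")
}

#' @export
print.rate_constant <- function(x, ...) {
  cat(sprintf("heterogeneous rate constant: %.3g +/- %.2g cm s^-1\n", x$k, x$k_sd))
  invisible(x)
}

#' Top-down heterogeneous rate constant k2 for one particle size
#'
#' The top-down derivation treats adsorption as deposition of whole
#' nanoparticles: k' is divided by the v factor (size-specific maximum peak
#' depression times the close-packed area SA) and rescaled to molecular,
#' cm-based units by the molecule count per particle C_tr and the factor
#' 1000: k2 = k' * 1000 * C_tr(R) / v. The caller chooses v: the model
#' variant `v_factor(R, const)` or the experimental variant
#' `v_factor(R, const, max_depression = <observed>)`.
#'
#' @param k_prime Normalized rate, uA mmol^-1 dm^3 s^-1 (>= 0).
#' @param R Particle radius, cm.
#' @param v v factor, uA cm^2 mmol^-1 (> 0).
#' @param k_prime_sd Optional SD of k'; propagated multiplicatively.
#' @param rel_peak_error Optional relative error of the peak-depression
#'   measurement entering v (dimensionless); combined in quadrature.
#' @param const A [model_constants()] object.
#' @return List of class `rate_constant`: `k` (cm s^-1), `k_sd`.
#' @export
k2_top_down <- function(k_prime, R, v, k_prime_sd = 0, rel_peak_error = 0,
                        const = model_constants()) {
  if (!is.numeric(k_prime) || any(k_prime < 0)) {
    stop("k_prime must be non-negative", call. = FALSE)
  }
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop("v must be positive", call. = FALSE)
  }
  check_radius(R)
  k <- k_prime * 1000 * molecules_per_particle(R, const) / v
  rel_kp <- ifelse(k_prime > 0, k_prime_sd / k_prime, 0)
  k_sd <- propagate_sd(k, rel_sds = cbind(rel_kp, rel_peak_error))
  structure(list(k = k, k_sd = k_sd), class = "rate_constant")
}

#' Slope-corrected normalized rate k'_cor
#'
#' Replaces the measured per-size k' by its value on the best-fit
#' k'-versus-A line: k'_cor(R) = slope * A(R). Substituting k'_cor into the
#' top-down formula removes the scatter of individual k' measurements and
#' makes the resulting rate constant exactly size-independent.
#'
#' @param slope Best-fit slope of k' vs A, uA cm s^-1.
#' @param R Particle radius, cm (vectorised).
#' @param const A [model_constants()] object.
#' @return k'_cor, uA mmol^-1 dm^3 s^-1.
#' @export
kprime_cor <- function(slope, R, const = model_constants()) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0) {
    stop("slope must be a single positive number", call. = FALSE)
  }
  slope * reactive_area_per_mmol(R, const)
}

#' Slope-corrected top-down rate constants k2cor over a radius grid
#'
#' Evaluates the k'_cor -> top-down chain for each radius and summarises the
#' result. Algebraically every entry equals 1000 * slope / I_full (the
#' bottom-up k1), so the across-size SD is zero up to floating point; it is
#' reported as computed, as a self-check of the identity.
#'
#' @param slope Best-fit slope of k' vs A, uA cm s^-1.
#' @param radii_cm Radii, cm; at least one.
#' @param const A [model_constants()] object.
#' @return List of class `k2cor_table`: `table` (data.frame radius_cm,
#'   k2cor), `mean`, `sd` (0 with `single_radius = TRUE` flag when only one
#'   radius is supplied).
#' @export
k2cor_table <- function(slope, radii_cm, const = model_constants()) {
  if (length(radii_cm) < 1L) stop("need at least one radius", call. = FALSE)
  check_radius(radii_cm, sanity = TRUE, what = "radii_cm")
  kc <- kprime_cor(slope, radii_cm, const)
  k2 <- k2_top_down(kc, radii_cm, v_factor(radii_cm, const), const = const)$k
  single <- length(radii_cm) == 1L
  structure(
    list(table = data.frame(radius_cm = radii_cm, k2cor = k2),
         mean = mean(k2), sd = if (single) 0 else stats::sd(k2),
         single_radius = single),
    class = "k2cor_table"
  )
}

#' Size-dependence diagnostics: k'/k'_cor and k2/k2cor
#'
#' Measures the deviation of each size's measured rate from the best-fit
#' line in two independent ways: the ratio of the measured k' to the
#' line-predicted k'_cor, and the ratio of the measured top-down k2 (model
#' v) to the slope-corrected k2cor. The two series coincide identically, so
#' their agreement is a consistency check on the algebra. Error bands divide
#' the k' measurement SD (and, for the k2 route, any peak-measurement error)
#' by the corrected value.
#'
#' @param radii_cm Radii, cm.
#' @param k_prime Measured per-size normalized rates.
#' @param k_prime_sd Their SDs (default 0).
#' @param slope Best-fit slope of k' vs A.
#' @param rel_peak_error Relative peak-measurement error entering the k2
#'   route (default 0).
#' @param const A [model_constants()] object.
#' @return data.frame: radius_cm, ratio_kprime, ratio_kprime_sd, ratio_k2,
#'   ratio_k2_sd.
#' @export
ratio_diagnostics <- function(radii_cm, k_prime, k_prime_sd = 0, slope,
                              rel_peak_error = 0, const = model_constants()) {
  if (length(radii_cm) != length(k_prime)) {
    stop("radii_cm and k_prime must have equal length (size-key mismatch)",
         call. = FALSE)
  }
  k_prime_sd <- rep_len(k_prime_sd, length(k_prime))
  kc <- kprime_cor(slope, radii_cm, const)
  v <- v_factor(radii_cm, const)
  k2 <- k2_top_down(k_prime, radii_cm, v, const = const)$k
  k2c <- k2_top_down(kc, radii_cm, v, const = const)$k
  ratio_kp <- k_prime / kc
  ratio_k2 <- k2 / k2c
  rel_kp <- ifelse(k_prime > 0, k_prime_sd / k_prime, 0)
  data.frame(
    radius_cm = radii_cm,
    ratio_kprime = ratio_kp,
    ratio_kprime_sd = k_prime_sd / kc,
    ratio_k2 = ratio_k2,
    ratio_k2_sd = propagate_sd(ratio_k2, rel_sds = cbind(rel_kp, rel_peak_error))
  )
}

#' First-order propagation of standard deviations
#'
#' For a value formed by products and quotients of independent factors, the
#' relative variances of the factors add in quadrature:
#' SD(y) = |y| * sqrt(sum_i rel_sd_i^2). This first-order, independence-
#' assuming rule is used for every propagated uncertainty in the package.
#'
#' @param value The computed value(s).
#' @param rel_sds Relative SDs of the multiplicative components: a numeric
#'   vector (one value, several components) or a matrix with one row per
#'   element of `value` and one column per component.
#' @return Absolute SD(s), same length as `value`.
#' @examples
#' propagate_sd(10, rel_sds = c(0.03, 0.04))  # 3-4-5: 0.5
#' @export
propagate_sd <- function(value, rel_sds) {
  if (is.matrix(rel_sds)) {
    if (any(!is.finite(rel_sds)) || any(rel_sds < 0)) {
      stop("relative SDs must be non-negative and finite", call. = FALSE)
    }
    rel <- sqrt(rowSums(rel_sds^2))
  } else {
    if (any(!is.finite(rel_sds)) || any(rel_sds < 0)) {
      stop("relative SDs must be non-negative and finite", call. = FALSE)
    }
    rel <- sqrt(sum(rel_sds^2))
  }
  abs(value) * rel
}
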