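#' Construct an adsorption trace
#'
#' One record of capacitance-current peak-2 height versus time during exposure
#' of a DOPC monolayer to a nanoparticle dispersion, tagged with the particle
#' hydrodynamic radius and the dispersion concentration (SiO2 basis). Peak
#' heights are assumed baseline-corrected (peak-to-RCV-baseline) on input.
#'
#' @param times Sampling times, s; strictly increasing.
#' @param peak_heights Peak-2 heights, uA; non-negative, same length as `times`.
#' @param concentration Dispersion concentration C_np, mmol dm^-3 (SiO2 basis).
#' @param radius_cm Hydrodynamic particle radius, cm.
#' @param replicate_id Identifier for the replicate exposure.
#' @return An `adsorption_trace` object (list with the five fields).
#' @export
adsorption_trace <- function(times, peak_heights, concentration,
                             radius_cm, replicate_id = "r1") {
  if (length(times) != length(peak_heights)) {
    stop("times and peak_heights must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) stop("a trace needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(peak_heights)) || any(peak_heights < 0)) {
    stop("peak_heights must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(concentration) || length(concentration) != 1L || concentration < 0) {
    stop("concentration must be a single non-negative number", call. = FALSE)
  }
  check_radius(radius_cm, sanity = TRUE, what = "radius_cm")
  structure(
    list(times = as.numeric(times), peak_heights = as.numeric(peak_heights),
         concentration = concentration, radius_cm = radius_cm,
         replicate_id = as.character(replicate_id)),
    class = "adsorption_trace"
  )
}

#' @export
print.adsorption_trace <- function(x, ...) {
  cat(sprintf(
    "adsorption_trace: %d samples over %.4g-%.4g s, R = %.4g nm, C = %.4g mmol dm^-3, replicate %s\n",
    length(x$times), min(x$times), max(x$times), cm_to_nm(x$radius_cm),
    x$concentration, x$replicate_id))
  invisible(x)
}

# Least-squares slope with standard error, computed via lm so diagnostics
# match R's canonical fitting machinery. R^2 computed directly (summary.lm
# warns on exactly-linear input, which is a legitimate case here: noise-free
# traces); NA when the response is constant.
ols_slope <- function(x, y) {
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  se <- sqrt(diag(vcov_quiet(fit)))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(slope = unname(cf[2L]), slope_se = unname(se[2L]),
       intercept = unname(cf[1L]), intercept_se = unname(se[1L]),
       r_squared = r2, n = length(x))
}

# vcov() routes through summary.lm, which warns on exactly-linear data;
# noise-free traces are exactly linear by design, so that warning is muffled
# (and only that one).
vcov_quiet <- function(fit) {
  withCallingHandlers(
    stats::vcov(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Initial adsorption rate from a trace
#'
#' The initial rate of adsorption V is measured as the rate of decrease of
#' the peak-2 height over an early time window (default 0-50 s): V is minus
#' the least-squares slope of peak height versus time restricted to the
#' window, so monolayer suppression gives positive V. The slope standard
#' error is reported as `V_sd`.
#'
#' When `max_depression` is supplied (the size-specific maximum depression,
#' uA), the fit is additionally truncated at the first sample whose observed
#' depression from the trace's starting height reaches
#' `plateau_fraction * max_depression`: beyond that point the surface
#' approaches saturation and the kinetics are no longer initial-rate. The
#' truncation never applies to traces that stay far from saturation.
#'
#' @param trace An [adsorption_trace()].
#' @param window Length-2 numeric, fit window in s (default `c(0, 50)`).
#' @param max_depression Optional saturation depression for truncation, uA.
#' @param plateau_fraction Fraction of `max_depression` at which truncation
#'   cuts in (default 0.9).
#' @return A list of class `initial_rate`: `V` (uA s^-1), `V_sd`, `window`,
#'   `n_points`, `intercept`, `r_squared`, `truncated_at` (NA if no
#'   truncation applied).
#' @export
initial_rate <- function(trace, window = c(0, 50),
                         max_depression = NULL, plateau_fraction = 0.9) {
  stopifnot(inherits(trace, "adsorption_trace"))
  if (length(window) != 2L || !is.numeric(window) || window[1] >= window[2]) {
    stop("window must be c(start, end) with start < end", call. = FALSE)
  }
  keep <- trace$times >= window[1] & trace$times <= window[2]
  truncated_at <- NA_real_
  if (!is.null(max_depression)) {
    if (!is.numeric(max_depression) || max_depression <= 0) {
      stop("max_depression must be positive", call. = FALSE)
    }
    depression <- trace$peak_heights[1L] - trace$peak_heights
    hit <- which(keep & depression >= plateau_fraction * max_depression)
    if (length(hit)) {
      truncated_at <- trace$times[hit[1L]]
      keep <- keep & trace$times < truncated_at
    }
  }
  if (sum(keep) < 2L) {
    stop("fewer than 2 in-window samples; cannot estimate an initial rate",
         call. = FALSE)
  }
  fit <- ols_slope(trace$times[keep], trace$peak_heights[keep])
  structure(
    list(V = -fit$slope, V_sd = fit$slope_se, window = window,
         n_points = fit$n, intercept = fit$intercept,
         r_squared = fit$r_squared, truncated_at = truncated_at),
    class = "initial_rate"
  )
}

#' Normalized adsorption rate k' for one particle size
#'
#' k' is the slope of initial rate V versus dispersion concentration C_np,
#' fitted by ordinary least squares with a free intercept (the intercept is
#' reported as a diagnostic and is expected to be ~0 for a system whose rate
#' vanishes at zero concentration).
#'
#' @param concentrations C_np values, mmol dm^-3; at least 3 distinct values.
#' @param rates Initial rates V, uA s^-1; same length.
#' @param radius_cm Particle radius, cm (carried into the result).
#' @return A list of class `normalized_rate`: `k_prime`
#'   (uA mmol^-1 dm^3 s^-1), `k_prime_sd` (slope standard error),
#'   `intercept`, `intercept_sd`, `r_squared`, `radius_cm`,
#'   `n_concentrations`.
#' @export
normalized_rate <- function(concentrations, rates, radius_cm) {
  if (length(concentrations) != length(rates)) {
    stop("concentrations and rates must have equal length", call. = FALSE)
  }
  if (length(concentrations) < 3L) {
    stop("need at least 3 (concentration, rate) points", call. = FALSE)
  }
  if (length(unique(concentrations)) < 2L) {
    stop("degenerate design: all concentrations equal", call. = FALSE)
  }
  check_radius(radius_cm, sanity = TRUE, what = "radius_cm")
  fit <- ols_slope(concentrations, rates)
  structure(
    list(k_prime = fit$slope, k_prime_sd = fit$slope_se,
         intercept = fit$intercept, intercept_sd = fit$intercept_se,
         r_squared = fit$r_squared, radius_cm = radius_cm,
         n_concentrations = length(unique(concentrations))),
    class = "normalized_rate"
  )
}

#' Fit k' against the specific reactive area
#'
#' Regresses the per-size normalized rate k' on the specific reactive area
#' A(R) across particle sizes. The model predicts proportionality, so the
#' slope (uA cm s^-1 after the dm^3 to cm^3 accounting applied downstream in
#' [k1_bottom_up()]) is the quantity that carries the rate constant; the
#' intercept and R^2 are diagnostics. Optional 1/SD^2 weighting is available
#' but off by default.
#'
#' @param A Specific reactive areas, cm^2 mmol^-1; one per size, >= 3 sizes.
#' @param k_prime Normalized rates, uA mmol^-1 dm^3 s^-1.
#' @param k_prime_sd Optional per-size k' standard deviations (used only when
#'   `weighted = TRUE`).
#' @param weighted Use weights 1/k_prime_sd^2 (default `FALSE`).
#' @return A list of class `kprime_area_fit`: `slope`, `slope_sd`,
#'   `intercept`, `intercept_sd`, `r_squared`, `n_sizes`, `weighted`.
#' @export
fit_kprime_vs_area <- function(A, k_prime, k_prime_sd = NULL, weighted = FALSE) {
  if (length(A) != length(k_prime)) {
    stop("A and k_prime must have equal length", call. = FALSE)
  }
  if (length(A) < 3L) stop("need at least 3 particle sizes", call. = FALSE)
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("reactive areas must be positive and finite", call. = FALSE)
  }
  if (weighted) {
    if (is.null(k_prime_sd) || any(!is.finite(k_prime_sd)) || any(k_prime_sd <= 0)) {
      stop("weighted fit requires positive k_prime_sd for every size", call. = FALSE)
    }
    fit <- stats::lm(k_prime ~ A, weights = 1 / k_prime_sd^2)
  } else {
    fit <- stats::lm(k_prime ~ A)
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(vcov_quiet(fit)))
  w <- if (weighted) 1 / k_prime_sd^2 else rep(1, length(A))
  tss <- sum(w * (k_prime - stats::weighted.mean(k_prime, w))^2)
  r2 <- if (tss > 0) 1 - sum(w * stats::residuals(fit)^2) / tss else NA_real_
  structure(
    list(slope = unname(cf[2L]), slope_sd = unname(se[2L]),
         intercept = unname(cf[1L]), intercept_sd = unname(se[1L]),
         r_squared = r2, n_sizes = length(A),
         weighted = weighted),
    class = "kprime_area_fit"
  )
}
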