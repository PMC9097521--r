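#' Normalized rate implied by a heterogeneous rate constant
#'
#' Inverts the top-down relation k2 = k' * 1000 * C_tr / v to obtain the
#' normalized rate a dispersion of radius R would show if adsorption
#' proceeded with heterogeneous rate constant `k_het`:
#' k' = k_het * v_model(R) / (1000 * C_tr(R)), which equals
#' k_het * I_full * A(R) / 1000 — proportional to the specific reactive
#' area, as the model predicts.
#'
#' @param k_het Heterogeneous rate constant, cm s^-1 (>= 0).
#' @param R Particle radius, cm (vectorised).
#' @param const A [model_constants()] object.
#' @return k', uA mmol^-1 dm^3 s^-1.
#' @export
kprime_from_rate_constant <- function(k_het, R, const = model_constants()) {
  if (!is.numeric(k_het) || any(k_het < 0)) {
    stop("k_het must be non-negative", call. = FALSE)
  }
  k_het * v_factor(R, const) / (1000 * molecules_per_particle(R, const))
}

# Deterministic per-trace sub-seed derived from the master seed and grid
# indices (multiplicative mixes modulo the Mersenne prime 2^31 - 1), so any
# single trace is reproducible in isolation.
derive_subseed <- function(seed, i_radius, i_conc, i_rep) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + i_radius * 104729) %% m
  x <- (x * 48271 + i_conc * 7919) %% m
  x <- (x * 48271 + i_rep * 131071) %% m
  as.integer(x)
}

#' Generate one synthetic peak-suppression trace
#'
#' Emulates the capacitance-current peak-2 record of an exposure at radius R
#' and concentration C under kinetic control with heterogeneous rate constant
#' `k_het`. The noise-free signal starts at `baseline_peak`, falls at the
#' initial rate k' * C with k' from [kprime_from_rate_constant()], and
#' plateaus at `baseline_peak - delta_I_max(R)`, the size-specific maximum
#' depression (capped at full suppression). Two transient shapes are
#' available:
#' \describe{
#'   \item{`"linear"` (default)}{a linear ramp at slope -k'C that saturates
#'     sharply at the plateau — the linear-initial-kinetics regime the
#'     initial-rate analysis assumes, held exactly until saturation.}
#'   \item{`"exponential"`}{an exponential approach
#'     `delta * (1 - exp(-lambda t))` with `lambda = k'C/delta`, which has
#'     the same initial slope and plateau but is curved throughout.}
#' }
#' Independent Gaussian noise of SD `noise_sd` is added; the trace is clipped
#' at zero (peak heights are non-negative).
#'
#' @param R Particle radius, cm.
#' @param C Dispersion concentration, mmol dm^-3 (>= 0).
#' @param k_het True heterogeneous rate constant, cm s^-1.
#' @param noise_sd Additive Gaussian noise SD, uA (>= 0).
#' @param dt Sampling interval, s (> 0).
#' @param duration Trace duration, s.
#' @param seed Integer seed for the trace's noise.
#' @param baseline_peak Unsuppressed peak-2 height, uA.
#' @param shape `"linear"` or `"exponential"` transient.
#' @param replicate_id Identifier carried into the trace.
#' @param const A [model_constants()] object.
#' @return An [adsorption_trace()].
#' @export
generate_trace <- function(R, C, k_het, noise_sd = 0.1, dt = 1, duration = 300,
                           seed = 1L, baseline_peak = model_constants()$full_suppression_current,
                           shape = c("linear", "exponential"),
                           replicate_id = "r1", const = model_constants()) {
  shape <- match.arg(shape)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.numeric(duration) || duration < dt) {
    stop("duration must cover at least one sampling interval", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  if (!is.numeric(C) || C < 0) stop("C must be non-negative", call. = FALSE)
  times <- seq(0, duration, by = dt)
  delta <- max_depression_model(R, const)
  kp <- kprime_from_rate_constant(k_het, R, const)
  v0 <- kp * C  # initial suppression rate, uA s^-1
  if (v0 <= 0 || delta <= 0) {
    signal <- rep(baseline_peak, length(times))
  } else if (shape == "linear") {
    signal <- baseline_peak - pmin(v0 * times, delta)
  } else {
    lambda <- v0 / delta
    signal <- baseline_peak - delta * (1 - exp(-lambda * times))
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    signal <- signal + stats::rnorm(length(signal), 0, noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  adsorption_trace(times, pmax(signal, 0), concentration = C, radius_cm = R,
                   replicate_id = replicate_id)
}

#' Generate a full synthetic adsorption study
#'
#' One trace per (radius, concentration, replicate) combination, each with a
#' deterministic sub-seed derived from the master seed and the grid indices.
#' The defaults mirror the experimental design the analysis targets: radii
#' 6.75-86 nm, SiO2 concentrations 2-12 mmol dm^-3, additive noise of
#' 0.1 uA, and a ground-truth rate constant of 4.22e-4 cm s^-1.
#'
#' @param k_het True heterogeneous rate constant, cm s^-1.
#' @param radii_cm Particle radii, cm.
#' @param concentrations Concentrations, mmol dm^-3.
#' @param replicates Replicate exposures per condition.
#' @param noise_sd Gaussian noise SD, uA.
#' @param seed Master integer seed.
#' @param dt,duration,baseline_peak,shape Passed to [generate_trace()].
#' @param const A [model_constants()] object.
#' @return An object of class `synthetic_study`: list with `traces` (list of
#'   [adsorption_trace()]), `manifest` (data.frame: trace_index, radius_nm,
#'   conc_mmol_per_dm3, replicate_id), and the generating parameters
#'   including `true_rate_constant` and `seed`.
#' @export
generate_study <- function(k_het = 4.22e-4,
                           radii_cm = nm_to_cm(c(6.75, 15, 25, 46, 66, 86)),
                           concentrations = c(2, 4, 6, 8, 10, 12),
                           replicates = 2,
                           noise_sd = 0.1,
                           seed = 1L,
                           dt = 1, duration = 300,
                           baseline_peak = model_constants()$full_suppression_current,
                           shape = c("linear", "exponential"),
                           const = model_constants()) {
  shape <- match.arg(shape)
  if (!length(radii_cm) || !length(concentrations) || replicates < 1) {
    stop("radius, concentration and replicate grids must be non-empty", call. = FALSE)
  }
  check_radius(radii_cm, sanity = TRUE, what = "radii_cm")
  traces <- list()
  rows <- list()
  idx <- 0L
  for (i in seq_along(radii_cm)) {
    for (j in seq_along(concentrations)) {
      for (r in seq_len(replicates)) {
        idx <- idx + 1L
        sub <- derive_subseed(seed, i, j, r)
        rep_id <- sprintf("rep%d", r)
        traces[[idx]] <- generate_trace(
          R = radii_cm[i], C = concentrations[j], k_het = k_het,
          noise_sd = noise_sd, dt = dt, duration = duration, seed = sub,
          baseline_peak = baseline_peak, shape = shape,
          replicate_id = rep_id, const = const
        )
        rows[[idx]] <- data.frame(
          trace_index = idx,
          radius_nm = cm_to_nm(radii_cm[i]),
          conc_mmol_per_dm3 = concentrations[j],
          replicate_id = rep_id
        )
      }
    }
  }
  structure(
    list(traces = traces, manifest = do.call(rbind, rows),
         true_rate_constant = k_het, radii_cm = radii_cm,
         concentrations = concentrations, replicates = replicates,
         noise_sd = noise_sd, sampling_dt = dt, duration = duration,
         baseline_peak = baseline_peak, shape = shape, seed = seed,
         constants = const),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d traces (%d radii x %d concentrations x %d replicates)\n",
    length(x$traces), length(x$radii_cm), length(x$concentrations), x$replicates))
  cat(sprintf("  true rate constant %.3g cm s^-1, noise %.3g uA, seed %d, shape %s\n",
              x$true_rate_constant, x$noise_sd, x$seed, x$shape))
  invisible(x)
}

#' Write a synthetic study to trace CSVs plus a manifest
#'
#' Emits exactly the on-disk format the manifest-driven pipeline reads: one
#' CSV per trace with columns `time_s, peak2_uA`, a manifest CSV with
#' columns `trace_file, radius_nm, conc_mmol_per_dm3, replicate_id`, and a
#' provenance JSON echoing the generating parameters.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- study$manifest
  files <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    tr <- study$traces[[man$trace_index[i]]]
    files[i] <- sprintf("trace_R%snm_C%s_%s.csv",
                        format(man$radius_nm[i]), format(man$conc_mmol_per_dm3[i]),
                        man$replicate_id[i])
    utils::write.csv(
      data.frame(time_s = tr$times, peak2_uA = tr$peak_heights),
      file.path(dir, files[i]), row.names = FALSE
    )
  }
  out <- data.frame(trace_file = files, radius_nm = man$radius_nm,
                    conc_mmol_per_dm3 = man$conc_mmol_per_dm3,
                    replicate_id = man$replicate_id)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(out, manifest_path, row.names = FALSE)
  prov <- study[c("true_rate_constant", "concentrations", "replicates",
                  "noise_sd", "sampling_dt", "duration", "baseline_peak",
                  "shape", "seed")]
  prov$radii_nm <- cm_to_nm(study$radii_cm)
  prov$constants <- unclass(study$constants)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
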