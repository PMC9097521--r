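#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the analysis chain with its default. May also be
#' built from a JSON/YAML file via [config_from_file()].
#'
#' @param constants A [model_constants()] object.
#' @param rate_window Initial-rate fit window, s (default `c(0, 50)`).
#' @param truncate_at_plateau Truncate each trace's fit window at the first
#'   approach to the size-specific model maximum depression (default `TRUE`;
#'   see [initial_rate()]).
#' @param plateau_fraction Fraction of the maximum depression at which the
#'   truncation cuts in (default 0.9).
#' @param weighted Weight the k'-vs-A fit by 1/SD^2 (default `FALSE`).
#' @param peak_measurement_error Relative error of the capacitance peak
#'   measurement, propagated into the top-down k2 (default 0).
#' @param use_experimental_vmax Derive per-size maximum depressions from the
#'   observed trace plateaus where the plateau is reached (default `TRUE`);
#'   sizes whose traces never saturate fall back to the model value.
#' @return A list of class `run_config`.
#' @export
run_config <- function(constants = model_constants(),
                       rate_window = c(0, 50),
                       truncate_at_plateau = TRUE,
                       plateau_fraction = 0.9,
                       weighted = FALSE,
                       peak_measurement_error = 0,
                       use_experimental_vmax = TRUE) {
  if (length(rate_window) != 2L || rate_window[1] >= rate_window[2]) {
    stop("rate_window must be c(start, end) with start < end", call. = FALSE)
  }
  if (peak_measurement_error < 0) {
    stop("peak_measurement_error must be non-negative", call. = FALSE)
  }
  structure(list(constants = constants, rate_window = rate_window,
                 truncate_at_plateau = truncate_at_plateau,
                 plateau_fraction = plateau_fraction, weighted = weighted,
                 peak_measurement_error = peak_measurement_error,
                 use_experimental_vmax = use_experimental_vmax),
            class = "run_config")
}

#' Build a run configuration from a JSON or YAML file
#'
#' The file may contain a `constants:` block (fields of [model_constants()])
#' plus any of the scalar options of [run_config()].
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `run_config` object.
#' @export
config_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  const <- constants_from_config(cfg$constants)
  cfg$constants <- NULL
  args <- c(list(constants = const), cfg)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(args), allowed)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, args)
}

#' Read one trace CSV
#'
#' Expected columns: `time_s`, `peak2_uA`.
#'
#' @param path CSV path.
#' @return data.frame with the two validated columns.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("time_s", "peak2_uA")
  if (!all(need %in% names(df))) {
    stop("trace file ", path, " must have columns time_s, peak2_uA", call. = FALSE)
  }
  df[need]
}

#' Read a study manifest CSV and its traces
#'
#' Expected manifest columns: `trace_file`, `radius_nm`,
#' `conc_mmol_per_dm3`, `replicate_id`; trace files are resolved relative to
#' the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return List: `manifest` (data.frame) and `traces` (list of
#'   [adsorption_trace()], one per manifest row).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- utils::read.csv(path)
  need <- c("trace_file", "radius_nm", "conc_mmol_per_dm3", "replicate_id")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(man) == 0L) stop("manifest is empty", call. = FALSE)
  base <- dirname(path)
  traces <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(base, man$trace_file[i])
    df <- tryCatch(read_trace_csv(f), error = function(e) {
      stop("manifest row ", i, " (", man$trace_file[i], "): ",
           conditionMessage(e), call. = FALSE)
    })
    traces[[i]] <- adsorption_trace(df$time_s, df$peak2_uA,
                                    concentration = man$conc_mmol_per_dm3[i],
                                    radius_cm = nm_to_cm(man$radius_nm[i]),
                                    replicate_id = man$replicate_id[i])
  }
  list(manifest = man, traces = traces)
}

# Observed plateau depression of one trace: starting height minus the mean of
# the trailing segment (last 5% of samples, at least 3).
observed_depression <- function(trace) {
  n <- length(trace$peak_heights)
  k <- max(3L, ceiling(0.05 * n))
  trace$peak_heights[1L] - mean(trace$peak_heights[(n - k + 1L):n])
}

#' Initial-rate table for a set of traces
#'
#' Applies [initial_rate()] to every trace under a common configuration.
#'
#' @param traces List of [adsorption_trace()] objects.
#' @param config A [run_config()].
#' @return data.frame: one row per trace with radius_cm, radius_nm,
#'   conc_mmol_per_dm3, replicate_id, V, V_sd, n_points, truncated_at.
#' @export
extract_rates <- function(traces, config = run_config()) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    md <- if (config$truncate_at_plateau) {
      max_depression_model(tr$radius_cm, config$constants)
    } else NULL
    ir <- initial_rate(tr, window = config$rate_window, max_depression = md,
                       plateau_fraction = config$plateau_fraction)
    data.frame(radius_cm = tr$radius_cm, radius_nm = cm_to_nm(tr$radius_cm),
               conc_mmol_per_dm3 = tr$concentration,
               replicate_id = tr$replicate_id,
               V = ir$V, V_sd = ir$V_sd, n_points = ir$n_points,
               truncated_at = ir$truncated_at)
  })
  do.call(rbind, rows)
}

#' Run the full rate-constant pipeline
#'
#' Chains every stage: initial rates per trace, normalized rate k' per
#' particle size, the k'-versus-A fit, the bottom-up k1, the per-size
#' top-down k2 (model v and, where trace plateaus are observed, experimental
#' v), the slope-corrected k2cor, and the k'/k'_cor = k2/k2cor ratio
#' diagnostics with propagated uncertainties.
#'
#' @param traces List of [adsorption_trace()] objects (e.g. from
#'   [read_manifest()] or a [generate_study()]'s `$traces`).
#' @param config A [run_config()].
#' @return A list of class `run_report`; see Details. Key entries:
#'   `rates` (per-trace V table), `per_size` (per-radius table with k',
#'   A, delta_I_max, k2 variants, k2cor and ratios), `slope_fit`, `k1`,
#'   `k2cor` (mean/SD), `constants`.
#' @export
run_pipeline <- function(traces, config = run_config()) {
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  const <- config$constants
  rates <- extract_rates(traces, config)

  radii <- sort(unique(rates$radius_cm))
  per_size <- lapply(radii, function(R) {
    sub <- rates[rates$radius_cm == R, ]
    nr <- normalized_rate(sub$conc_mmol_per_dm3, sub$V, R)
    # per-size observed plateau depression: deepest suppression over the
    # size's traces, accepted only when it actually approaches the model
    # plateau (otherwise no trace saturated and the model value is used)
    obs <- max(vapply(traces[which(rates$radius_cm == R)],
                      observed_depression, numeric(1)))
    # the true depression cannot exceed full suppression; noise above that
    # bound is clipped rather than disqualifying the observation
    obs <- min(obs, const$full_suppression_current)
    dmod <- max_depression_model(R, const)
    use_exp <- config$use_experimental_vmax && obs >= 0.8 * dmod
    data.frame(
      radius_cm = R, radius_nm = cm_to_nm(R),
      k_prime = nr$k_prime, k_prime_sd = nr$k_prime_sd,
      intercept = nr$intercept, r_squared = nr$r_squared,
      n_concentrations = nr$n_concentrations,
      delta_I_max_model = dmod,
      delta_I_max_exp = if (use_exp) obs else NA_real_,
      delta_source = if (use_exp) "experimental" else "model"
    )
  })
  per_size <- do.call(rbind, per_size)

  A <- reactive_area_per_mmol(per_size$radius_cm, const)
  per_size$A_cm2_per_mmol <- A
  sfit <- fit_kprime_vs_area(A, per_size$k_prime, per_size$k_prime_sd,
                             weighted = config$weighted)
  k1 <- k1_bottom_up(sfit$slope, sfit$slope_sd, const)

  v_model <- v_factor(per_size$radius_cm, const)
  k2m <- k2_top_down(per_size$k_prime, per_size$radius_cm, v_model,
                     k_prime_sd = per_size$k_prime_sd,
                     rel_peak_error = config$peak_measurement_error,
                     const = const)
  per_size$k2_model <- k2m$k
  per_size$k2_model_sd <- k2m$k_sd
  d_used <- ifelse(is.na(per_size$delta_I_max_exp),
                   per_size$delta_I_max_model, per_size$delta_I_max_exp)
  v_exp <- v_factor(per_size$radius_cm, const, max_depression = d_used)
  k2e <- k2_top_down(per_size$k_prime, per_size$radius_cm, v_exp,
                     k_prime_sd = per_size$k_prime_sd,
                     rel_peak_error = config$peak_measurement_error,
                     const = const)
  per_size$k2_exp <- k2e$k
  per_size$k2_exp_sd <- k2e$k_sd

  k2cor <- k2cor_table(sfit$slope, per_size$radius_cm, const)
  per_size$k2cor <- k2cor$table$k2cor
  ratios <- ratio_diagnostics(per_size$radius_cm, per_size$k_prime,
                              per_size$k_prime_sd, sfit$slope,
                              rel_peak_error = config$peak_measurement_error,
                              const = const)
  per_size$ratio_kprime <- ratios$ratio_kprime
  per_size$ratio_kprime_sd <- ratios$ratio_kprime_sd
  per_size$ratio_k2 <- ratios$ratio_k2
  per_size$ratio_k2_sd <- ratios$ratio_k2_sd

  structure(
    list(constants = unclass(const),
         config = list(rate_window = config$rate_window,
                       truncate_at_plateau = config$truncate_at_plateau,
                       plateau_fraction = config$plateau_fraction,
                       weighted = config$weighted,
                       peak_measurement_error = config$peak_measurement_error,
                       use_experimental_vmax = config$use_experimental_vmax),
         n_traces = length(traces),
         rates = rates,
         per_size = per_size,
         slope_fit = unclass(sfit),
         k1 = list(value = k1$k, sd = k1$k_sd),
         k2cor = list(mean = k2cor$mean, sd = k2cor$sd)),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d traces, %d particle sizes\n",
              x$n_traces, nrow(x$per_size)))
  cat(sprintf("  k' vs A slope : %.3g +/- %.2g uA cm s^-1 (R^2 = %.4f)\n",
              x$slope_fit$slope, x$slope_fit$slope_sd, x$slope_fit$r_squared))
  cat(sprintf("  k1 (bottom-up): %.3g +/- %.2g cm s^-1\n", x$k1$value, x$k1$sd))
  cat(sprintf("  k2cor         : %.3g +/- %.2g cm s^-1 (across sizes)\n",
              x$k2cor$mean, x$k2cor$sd))
  invisible(x)
}

#' Run the pipeline from a manifest on disk and write the report
#'
#' Convenience wrapper: reads the manifest and its traces, runs
#' [run_pipeline()], and writes `report.json`, `rates.csv` and
#' `per_size.csv` under `outdir`. Machine outputs carry full precision.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param outdir Output directory (created if needed).
#' @param config A [run_config()].
#' @return The `run_report`, invisibly.
#' @export
run_pipeline_files <- function(manifest_path, outdir, config = run_config()) {
  ds <- read_manifest(manifest_path)
  report <- run_pipeline(ds$traces, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$rates, file.path(outdir, "rates.csv"), row.names = FALSE)
  utils::write.csv(report$per_size, file.path(outdir, "per_size.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(list(schema = "adsorbkin-report/1"), unclass(report)),
    file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  invisible(report)
}
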