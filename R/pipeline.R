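# Pipeline orchestration: the stage sequence a bench run follows --
# simulate / qc / process / calibrate / quantify / compare -- as one
# dispatching entry point over the package's functions.

#' Pipeline run configuration
#'
#' Bundles the optical configuration, noise defaults, acceptance bounds and
#' the rate window used by \code{\link{run_pipeline}}.
#'
#' @param config An \code{\link{optical_config}}.
#' @param noise An \code{\link{instrument_noise}}.
#' @param r2_bound Linearity acceptance bound on calibration R^2.
#' @param cv_bound_percent Repeatability acceptance bound (percent).
#' @param source_cv_bound_percent Source-stability acceptance bound.
#' @param t0_s,t1_s Rate window (s).
#' @param seed RNG seed for simulation stages.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(config = optical_config(),
                       noise = instrument_noise(),
                       r2_bound = 0.985,
                       cv_bound_percent = 10,
                       source_cv_bound_percent = 0.5,
                       t0_s = 0, t1_s = 60,
                       seed = 20250630) {
  if (r2_bound <= 0 || cv_bound_percent <= 0 || source_cv_bound_percent <= 0)
    stop("acceptance bounds must be positive")
  if (t1_s <= t0_s) stop("invalid rate window")
  structure(list(config = config, noise = noise, r2_bound = r2_bound,
                 cv_bound_percent = cv_bound_percent,
                 source_cv_bound_percent = source_cv_bound_percent,
                 t0_s = t0_s, t1_s = t1_s, seed = seed),
            class = "run_config")
}

.log_info <- function(...) message("INFO  ", sprintf(...))

#' Run one pipeline stage
#'
#' Dispatches the standard assay stages over the package's functions;
#' every QC decision (saturation, dark model applied, bound checks) is
#' logged to the message stream. Deterministic given the configured seed.
#'
#' \describe{
#'   \item{simulate}{Forward-simulate a run at \code{activity_fraction};
#'     writes the trace CSV to \code{out} if given. Returns the
#'     \code{simulated_run}.}
#'   \item{qc}{Saturation + (if the trace is an empty-chip trace) source
#'     stability. Returns a list of flags; \code{ok = FALSE} on failure.}
#'   \item{process}{Dark-subtract (using \code{dark_trace} or the
#'     configured dark model) and compute dA/min. Returns a
#'     \code{result_record}.}
#'   \item{calibrate}{Fit a calibration from \code{pairs} (data.frame
#'     activity/rate). Returns a \code{calibration_curve}.}
#'   \item{quantify}{Invert \code{calibration} at the processed trace's
#'     rate. Returns a \code{result_record} with activity.}
#'   \item{compare}{KS consistency + per-sample relative differences
#'     between \code{reference} and \code{test} activity vectors. Returns a
#'     comparison report.}
#' }
#'
#' @param cfg A \code{\link{run_config}}.
#' @param command One of \code{"simulate"}, \code{"qc"}, \code{"process"},
#'   \code{"calibrate"}, \code{"quantify"}, \code{"compare"}.
#' @param trace A \code{\link{photon_trace}} (qc / process / quantify).
#' @param dark_trace Optional dark \code{photon_trace} to characterize; if
#'   absent, the configured noise model's dark moments are used.
#' @param pairs data.frame of \code{activity}, \code{rate} (calibrate).
#' @param calibration A \code{calibration_curve} (quantify).
#' @param activity_fraction Simulated truth (simulate).
#' @param reference,test Activity vectors in percent (compare).
#' @param sample_type Matrix for calibrate ("plasma" or "whole_blood").
#' @param out Optional output path (simulate: trace CSV; other stages:
#'   JSON records).
#' @return Stage-dependent; see Details.
#' @export
run_pipeline <- function(cfg = run_config(),
                         command = c("simulate", "qc", "process",
                                     "calibrate", "quantify", "compare"),
                         trace = NULL, dark_trace = NULL, pairs = NULL,
                         calibration = NULL, activity_fraction = 1,
                         reference = NULL, test = NULL,
                         sample_type = "plasma", out = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  command <- match.arg(command)

  dark_model <- function() {
    if (!is.null(dark_trace)) {
      .log_info("dark model characterized from supplied trace (n = %d)",
                length(dark_trace))
      characterize_dark_current(dark_trace)
    } else {
      .log_info("dark model taken from configuration: %.2f +/- %.2f",
                cfg$noise$dark_mean_counts, cfg$noise$dark_sd_counts)
      structure(list(mean_counts = cfg$noise$dark_mean_counts,
                     sd_counts = cfg$noise$dark_sd_counts,
                     n_points = 30L),
                class = "dark_current_model")
    }
  }

  switch(command,
    simulate = {
      noise <- cfg$noise
      noise$seed <- cfg$seed
      params <- kinetics_params(at_activity_fraction = activity_fraction)
      run <- simulate_run(params = params, noise = noise,
                          config = cfg$config,
                          t0_s = cfg$t0_s, t1_s = cfg$t1_s)
      .log_info("simulated run at activity %.3f, true rate %.5g AU/min",
                activity_fraction, run$truth$true_rate_per_min)
      if (!is.null(out)) write_trace(run$trace, out)
      run
    },
    qc = {
      if (is.null(trace)) stop("qc requires a trace")
      sat <- check_saturation(trace, cfg$config)
      .log_info("saturation check at %.2f V (threshold %.2f V): %s",
                trace$lamp_voltage_V, cfg$config$saturation_voltage_V,
                if (sat) "SATURATED" else "ok")
      stab <- NULL
      if (trace$sample_type == "empty_chip") {
        stab <- source_stability(trace, cfg$source_cv_bound_percent)
        .log_info("source stability CV %.4g%% (bound %g%%): %s",
                  stab$cv_percent, cfg$source_cv_bound_percent,
                  if (stab$passes) "ok" else "FAIL")
      }
      list(saturated = sat, source_stability = stab,
           ok = !sat && (is.null(stab) || stab$passes))
    },
    process = {
      if (is.null(trace)) stop("process requires a trace")
      if (check_saturation(trace, cfg$config))
        stop("QC failure: saturated trace rejected")
      corrected <- if (trace$dark_subtracted) trace else {
        dm <- dark_model()
        withCallingHandlers(
          subtract_dark(trace, dm),
          warning = function(w) {
            .log_info("QC flag: %s", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      }
      neg <- any(corrected$counts <= 0)
      rate <- compute_rate(corrected, cfg$t0_s, cfg$t1_s, cfg$config)
      .log_info("rate over [%g, %g] s: %.5g AU/min",
                cfg$t0_s, cfg$t1_s, rate$rate_per_min)
      rec <- result_record(corrected, rate, negative_counts = neg)
      if (!is.null(out)) write_results(rec, out)
      rec
    },
    calibrate = {
      if (is.null(pairs)) stop("calibrate requires (activity, rate) pairs")
      curve <- fit_calibration(pairs$activity, pairs$rate,
                               sample_type = sample_type,
                               r2_bound = cfg$r2_bound)
      .log_info("calibration R^2 = %.4f (bound %.4g): linearity %s",
                curve$r_squared, cfg$r2_bound,
                if (curve$passes_linearity) "ok" else "FAIL")
      if (!curve$passes_linearity)
        warning("calibration failed the linearity acceptance bound")
      if (!is.null(out)) write_calibration(curve, out)
      curve
    },
    quantify = {
      if (is.null(calibration))
        stop("configuration error: 'quantify' requires a calibration")
      rec <- run_pipeline(cfg, "process", trace = trace,
                          dark_trace = dark_trace)
      act <- invert_calibration(calibration, rec$rate_per_min,
                                dilution_factor = rec$dilution_factor)
      rec$activity_percent <- act$activity_percent
      rec$calibration_id <- calibration$sample_type
      .log_info("activity: %.1f%%", act$activity_percent)
      if (!is.null(out)) write_results(rec, out)
      rec
    },
    compare = {
      if (is.null(reference) || is.null(test))
        stop("compare requires 'reference' and 'test' activity vectors")
      ks <- ks_consistency(reference, test)
      rd <- relative_difference(reference, test)
      .log_info("KS D = %.4g, p = %.4g", ks$statistic, ks$p_value)
      rep <- list(ks_statistic = ks$statistic,
                  ks_p_value = ks$p_value,
                  reference_percent = reference,
                  test_percent = test,
                  relative_difference_percent = rd$raw,
                  relative_difference_rounded = rd$rounded)
      if (!is.null(out))
        jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA)
      rep
    })
}
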