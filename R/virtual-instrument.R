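# Virtual instrument: forward-simulates the anti-Xa chromogenic reaction,
# the double-pass optics, and the photon-counting noise chain, so every
# pipeline stage can be exercised against known ground truth.
#
# Mechanism being emulated: factor Xa is supplied in excess; antithrombin
# (potentiated by heparin) neutralizes it stoichiometrically (1:1 complex);
# the residual Xa hydrolyzes a chromogenic peptide substrate, releasing
# yellow p-nitroaniline (pNA) which absorbs at 405 nm. The faster the color
# develops, the LOWER the antithrombin activity.

# Instrument characterization defaults (counts per 1000 ms bin): mean
# empty-chip source count and its CV, dark-current mean/SD, and the linear
# temperature dependence of the source count.
.SOURCE_MEAN_DEFAULT  <- 24429585.36
.SOURCE_CV_DEFAULT    <- 0.103      # percent
.DARK_MEAN_DEFAULT    <- 384460.71
.DARK_SD_DEFAULT      <- 559.22
.TEMP_SLOPE_DEFAULT   <- 7704.504   # counts per degree C
.TEMP_INTERCEPT_DEFAULT <- 2.358e7
.DEFAULT_SEED <- 20250630

#' Ground-truth kinetics parameters for the virtual instrument
#'
#' Parameters of the simulated anti-Xa reaction. Residual enzyme after
#' inhibition is \code{max(0, fxa0 - inhibition_capacity * activity)};
#' the residual enzyme then turns over the chromogenic substrate with
#' Michaelis-Menten kinetics, releasing pNA.
#'
#' Defaults are chosen so that the simulated observable matches the scale of
#' a real plasma calibration: a 0\%-activity sample develops color at about
#' 0.038 AU/min and a 100\%-activity calibrator at about 0.012 AU/min, with
#' full inhibition reached just beyond 140\% activity.
#'
#' @param fxa0 Initial factor Xa amount (arbitrary enzyme activity units).
#' @param at_activity_fraction AT activity as a fraction (1.0 = 100\%).
#' @param inhibition_capacity Enzyme units neutralized per unit activity
#'   fraction at full strength.
#' @param substrate0_uM Initial chromogenic substrate concentration (uM).
#' @param kcat_per_s Turnover of residual enzyme (uM substrate / s per
#'   enzyme unit at saturation).
#' @param km_uM Michaelis constant (uM).
#' @param epsilon405_per_M_per_mm Molar absorptivity of pNA at 405 nm
#'   (M^-1 mm^-1); default 990, i.e. the standard 9.9e3 M^-1 cm^-1.
#' @param inhibition_mode \code{"instantaneous"} (stoichiometric 1:1
#'   neutralization completed before the substrate reaction starts; the
#'   default) or \code{"second_order"} (AT-Xa complexation with rate
#'   \code{k_inhib} runs concurrently with substrate turnover).
#' @param k_inhib Second-order inhibition rate (per enzyme unit per s);
#'   used only in \code{"second_order"} mode.
#' @return An object of class \code{kinetics_params}.
#' @export
kinetics_params <- function(fxa0 = 1,
                            at_activity_fraction = 1,
                            inhibition_capacity = 0.02616 / 0.0382,
                            substrate0_uM = 2000,
                            kcat_per_s = 1.0992,
                            km_uM = 50,
                            epsilon405_per_M_per_mm = 990,
                            inhibition_mode = c("instantaneous", "second_order"),
                            k_inhib = 1) {
  inhibition_mode <- match.arg(inhibition_mode)
  vals <- c(fxa0 = fxa0, at_activity_fraction = at_activity_fraction,
            inhibition_capacity = inhibition_capacity,
            substrate0_uM = substrate0_uM, kcat_per_s = kcat_per_s,
            km_uM = km_uM, epsilon405_per_M_per_mm = epsilon405_per_M_per_mm,
            k_inhib = k_inhib)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("kinetics parameters must be finite and nonnegative")
  structure(
    c(as.list(vals[seq_len(7L)]),
      list(inhibition_mode = inhibition_mode, k_inhib = k_inhib)),
    class = "kinetics_params")
}

#' Residual factor Xa after antithrombin inhibition
#' @param params A \code{\link{kinetics_params}}.
#' @return Residual enzyme amount (enzyme units), nonnegative.
#' @export
residual_enzyme <- function(params) {
  stopifnot(inherits(params, "kinetics_params"))
  max(0, params$fxa0 -
        params$inhibition_capacity * params$at_activity_fraction)
}

#' Interferent baseline profile
#'
#' Models sample-matrix interference as an additive absorbance baseline:
#' a static component (icteric/hemolyzed backgrounds: bilirubin and
#' hemoglobin absorb at 405 nm but do not change during the reaction) and a
#' slow drift (a surrogate for lipemic scattering, which does degrade the
#' rate measurement).
#'
#' @param static_absorbance_AU Constant additive absorbance (AU); >= 0.
#' @param drift_AU_per_min Additive absorbance drift (AU/min).
#' @return An object of class \code{interferent_profile}.
#' @export
interferent_profile <- function(static_absorbance_AU = 0,
                                drift_AU_per_min = 0) {
  if (!is.finite(static_absorbance_AU) || static_absorbance_AU < 0)
    stop("'static_absorbance_AU' must be finite and nonnegative")
  structure(list(static_absorbance_AU = static_absorbance_AU,
                 drift_AU_per_min = drift_AU_per_min),
            class = "interferent_profile")
}

#' Instrument noise model
#'
#' Source, dark-current and temperature characterization of the simulated
#' detection chain. Defaults reproduce the instrument's measured values:
#' empty-chip source mean ~2.44e7 counts/bin with CV 0.103\%, Gaussian dark
#' counts of mean 384,460.71 and SD 559.22 per bin, and source counts
#' drifting linearly with temperature at 7704.504 counts/C. The dark SD is
#' far below Poisson for its mean, so dark counts are modeled as Gaussian
#' with the measured moments rather than as shot noise.
#'
#' @param source_mean_counts Mean empty-chip counts per 1000 ms bin.
#' @param source_cv_percent Source stability CV (percent); metadata.
#' @param dark_mean_counts,dark_sd_counts Gaussian dark-count moments.
#' @param temperature_C Simulated ambient temperature; the source mean is
#'   shifted by \code{temp_slope_counts_per_C * (temperature_C - 25)}.
#' @param temp_slope_counts_per_C,temp_intercept_counts Linear temperature
#'   model of the source count.
#' @param shot_noise \code{"poisson"} (counts drawn Poisson around the
#'   expected transmitted count) or \code{"none"} (exact expected counts;
#'   used for noiseless identities).
#' @param seed RNG seed for the simulated acquisition.
#' @return An object of class \code{instrument_noise}.
#' @export
instrument_noise <- function(source_mean_counts = .SOURCE_MEAN_DEFAULT,
                             source_cv_percent = .SOURCE_CV_DEFAULT,
                             dark_mean_counts = .DARK_MEAN_DEFAULT,
                             dark_sd_counts = .DARK_SD_DEFAULT,
                             temperature_C = 25,
                             temp_slope_counts_per_C = .TEMP_SLOPE_DEFAULT,
                             temp_intercept_counts = .TEMP_INTERCEPT_DEFAULT,
                             shot_noise = c("poisson", "none"),
                             seed = .DEFAULT_SEED) {
  shot_noise <- match.arg(shot_noise)
  if (source_mean_counts < 0 || dark_mean_counts < 0 || dark_sd_counts < 0)
    stop("noise means and SDs must be nonnegative")
  structure(
    list(source_mean_counts = source_mean_counts,
         source_cv_percent = source_cv_percent,
         dark_mean_counts = dark_mean_counts,
         dark_sd_counts = dark_sd_counts,
         temperature_C = temperature_C,
         temp_slope_counts_per_C = temp_slope_counts_per_C,
         temp_intercept_counts = temp_intercept_counts,
         shot_noise = shot_noise,
         seed = seed),
    class = "instrument_noise")
}

#' Noise-free instrument (for analytic identities)
#' @param ... Overrides passed to \code{\link{instrument_noise}}.
#' @return An \code{instrument_noise} with shot noise off and zero dark counts.
#' @export
noiseless_instrument <- function(...) {
  instrument_noise(dark_mean_counts = 0, dark_sd_counts = 0,
                   shot_noise = "none", ...)
}

#' Simulate pNA release by residual factor Xa
#'
#' Integrates Michaelis-Menten turnover of the chromogenic substrate by the
#' enzyme left after antithrombin inhibition. In \code{"instantaneous"} mode
#' the AT-Xa complexation is complete at t = 0 and the residual enzyme is
#' constant; in \code{"second_order"} mode complexation and substrate
#' turnover run concurrently.
#'
#' @param params A \code{\link{kinetics_params}}.
#' @param duration_s Simulated reaction time (s).
#' @param dt_s Output time step (s).
#' @return A data.frame with columns \code{time_s} and \code{pna_uM};
#'   \code{pna_uM} is monotone nondecreasing and bounded by
#'   \code{substrate0_uM}.
#' @export
simulate_reaction <- function(params, duration_s = 120, dt_s = 1) {
  stopifnot(inherits(params, "kinetics_params"))
  if (duration_s <= 0 || dt_s <= 0)
    stop("'duration_s' and 'dt_s' must be positive")
  times <- seq(0, duration_s, by = dt_s)
  if (params$inhibition_mode == "instantaneous") {
    e_res <- residual_enzyme(params)
    if (e_res == 0 || params$substrate0_uM == 0) {
      return(data.frame(time_s = times, pna_uM = 0))
    }
    rhs <- function(t, y, p) {
      s <- max(y[["S"]], 0)
      list(c(S = -p$kcat_per_s * p$e_res * s / (p$km_uM + s)))
    }
    out <- deSolve::ode(y = c(S = params$substrate0_uM), times = times,
                        func = rhs,
                        parms = list(kcat_per_s = params$kcat_per_s,
                                     km_uM = params$km_uM, e_res = e_res),
                        method = "lsoda", rtol = 1e-10, atol = 1e-10)
    s <- pmin(pmax(out[, "S"], 0), params$substrate0_uM)
  } else {
    inhibitor0 <- params$inhibition_capacity * params$at_activity_fraction
    rhs <- function(t, y, p) {
      e <- max(y[["E"]], 0); i <- max(y[["I"]], 0); s <- max(y[["S"]], 0)
      complexation <- p$k_inhib * e * i
      list(c(E = -complexation,
             I = -complexation,
             S = -p$kcat_per_s * e * s / (p$km_uM + s)))
    }
    out <- deSolve::ode(y = c(E = params$fxa0, I = inhibitor0,
                              S = params$substrate0_uM),
                        times = times, func = rhs,
                        parms = params, method = "lsoda",
                        rtol = 1e-10, atol = 1e-10)
    s <- pmin(pmax(out[, "S"], 0), params$substrate0_uM)
  }
  pna <- params$substrate0_uM - s
  # Guard the monotonicity contract against integrator round-off.
  pna <- cummax(pna)
  data.frame(time_s = times, pna_uM = pna)
}

#' Convert a pNA concentration series to an absorbance series
#'
#' Beer-Lambert over the double-pass path:
#' A(t) = epsilon * [pNA](t) * l_total + static + drift * t / 60, with
#' l_total twice the chamber gap and the interferent terms an additive
#' baseline.
#'
#' @param conc A data.frame from \code{\link{simulate_reaction}} (columns
#'   \code{time_s}, \code{pna_uM}), or a numeric vector of concentrations
#'   (uM) with \code{times_s} supplied.
#' @param params A \code{\link{kinetics_params}} (for the absorptivity).
#' @param config An \code{\link{optical_config}} (for the path length).
#' @param interferent An \code{\link{interferent_profile}}.
#' @param times_s Times (s) when \code{conc} is a bare vector.
#' @return A data.frame with columns \code{time_s}, \code{absorbance_AU}.
#' @export
concentration_to_absorbance <- function(conc,
                                        params = kinetics_params(),
                                        config = optical_config(),
                                        interferent = interferent_profile(),
                                        times_s = NULL) {
  stopifnot(inherits(config, "optical_config"),
            inherits(interferent, "interferent_profile"))
  if (is.data.frame(conc)) {
    times_s <- conc$time_s
    pna_uM <- conc$pna_uM
  } else {
    if (is.null(times_s)) stop("'times_s' required for a bare vector")
    pna_uM <- conc
  }
  if (any(pna_uM < 0)) stop("concentrations must be nonnegative")
  a <- params$epsilon405_per_M_per_mm * (pna_uM * 1e-6) * total_path_mm(config) +
    interferent$static_absorbance_AU +
    interferent$drift_AU_per_min * times_s / 60
  data.frame(time_s = times_s, absorbance_AU = a)
}

#' Simulate a PMT photon-count trace from an absorbance series
#'
#' Per 1000 ms bin: the expected transmitted count is the
#' temperature-adjusted source mean attenuated by 10^(-A(t)); the recorded
#' count is drawn Poisson around that expectation (or taken exactly when
#' \code{shot_noise = "none"}), and Gaussian dark counts are added. The
#' returned trace carries raw (un-subtracted) counts, as acquired.
#'
#' @param absorbance A data.frame with \code{time_s}, \code{absorbance_AU}.
#' @param noise An \code{\link{instrument_noise}}.
#' @param config An \code{\link{optical_config}}.
#' @param sample_type,sample_id,dilution_factor Trace metadata.
#' @param bin_ms Sampling interval (ms).
#' @return A \code{\link{photon_trace}}.
#' @export
simulate_trace <- function(absorbance,
                           noise = instrument_noise(),
                           config = optical_config(),
                           sample_type = "plasma",
                           sample_id = "simulated",
                           dilution_factor = 1,
                           bin_ms = 1000) {
  stopifnot(inherits(noise, "instrument_noise"),
            inherits(config, "optical_config"))
  source_mean <- noise$source_mean_counts +
    noise$temp_slope_counts_per_C * (noise$temperature_C - 25)
  if (source_mean <= 0)
    stop("configuration error: temperature-adjusted source mean is nonpositive")
  bin_times_s <- seq(min(absorbance$time_s), max(absorbance$time_s),
                     by = bin_ms / 1000)
  a_at_bins <- stats::approx(absorbance$time_s, absorbance$absorbance_AU,
                             xout = bin_times_s, rule = 2)$y
  expected <- source_mean * 10^(-a_at_bins)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  counts <- if (noise$shot_noise == "poisson") {
    as.numeric(stats::rpois(length(expected), expected))
  } else {
    expected
  }
  if (noise$dark_mean_counts > 0 || noise$dark_sd_counts > 0) {
    counts <- counts + stats::rnorm(length(counts),
                                    mean = noise$dark_mean_counts,
                                    sd = noise$dark_sd_counts)
  }
  photon_trace(times_ms = bin_times_s * 1000,
               counts = pmax(counts, 0),
               sample_type = sample_type,
               sample_id = sample_id,
               lamp_voltage_V = config$lamp_voltage_V,
               temperature_C = noise$temperature_C,
               dilution_factor = dilution_factor,
               dark_subtracted = FALSE)
}

#' Simulate a dark-current trace
#'
#' Gaussian dark counts at the configured mean/SD over \code{n_bins} bins.
#'
#' @param noise An \code{\link{instrument_noise}}.
#' @param n_bins Number of 1000 ms bins (default 30).
#' @return A \code{\link{photon_trace}} with \code{sample_type = "dark"}.
#' @export
simulate_dark_trace <- function(noise = instrument_noise(), n_bins = 30) {
  stopifnot(inherits(noise, "instrument_noise"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  counts <- stats::rnorm(n_bins, noise$dark_mean_counts, noise$dark_sd_counts)
  photon_trace(times_ms = seq(0, by = 1000, length.out = n_bins),
               counts = pmax(counts, 0),
               sample_type = "dark", sample_id = "dark",
               temperature_C = noise$temperature_C)
}

#' Simulate an empty-chip source-stability trace
#'
#' Poisson counts around the (temperature-adjusted) source mean, no droplet
#' loaded, dark counts added.
#'
#' @param noise An \code{\link{instrument_noise}}.
#' @param n_bins Number of 1000 ms bins.
#' @return A \code{\link{photon_trace}} with \code{sample_type = "empty_chip"}.
#' @export
simulate_empty_chip_trace <- function(noise = instrument_noise(),
                                      n_bins = 30) {
  a0 <- data.frame(time_s = c(0, n_bins - 1), absorbance_AU = c(0, 0))
  simulate_trace(a0, noise = noise, sample_type = "empty_chip",
                 sample_id = "empty_chip")
}

#' Full forward simulation of one assay run
#'
#' Chains reaction kinetics, Beer-Lambert optics and the photon-counting
#' noise chain into a raw trace, and retains the ground truth (parameters
#' plus the analytic noiseless dA/min) so recovery can be checked.
#'
#' @param params A \code{\link{kinetics_params}}.
#' @param noise An \code{\link{instrument_noise}}.
#' @param config An \code{\link{optical_config}}.
#' @param interferent An \code{\link{interferent_profile}}.
#' @param duration_s Simulated acquisition length (s).
#' @param t0_s,t1_s Rate window used for the stored true rate.
#' @param sample_type,sample_id,dilution_factor Trace metadata.
#' @return An object of class \code{simulated_run}: \code{$trace} (raw
#'   \code{photon_trace}) and \code{$truth} (parameters, noise settings and
#'   \code{true_rate_per_min}).
#' @export
simulate_run <- function(params = kinetics_params(),
                         noise = instrument_noise(),
                         config = optical_config(),
                         interferent = interferent_profile(),
                         duration_s = 90,
                         t0_s = 0, t1_s = 60,
                         sample_type = "plasma",
                         sample_id = "simulated",
                         dilution_factor = 1) {
  conc <- simulate_reaction(params, duration_s = duration_s, dt_s = 1)
  absb <- concentration_to_absorbance(conc, params = params, config = config,
                                      interferent = interferent)
  trace <- simulate_trace(absb, noise = noise, config = config,
                          sample_type = sample_type, sample_id = sample_id,
                          dilution_factor = dilution_factor)
  a0 <- absb$absorbance_AU[which.min(abs(absb$time_s - t0_s))]
  a1 <- absb$absorbance_AU[which.min(abs(absb$time_s - t1_s))]
  true_rate <- (a1 - a0) * 60 / (t1_s - t0_s)
  structure(
    list(trace = trace,
         truth = list(params = params, noise = noise,
                      interferent = interferent,
                      true_rate_per_min = true_rate,
                      t0_s = t0_s, t1_s = t1_s)),
    class = "simulated_run")
}

#' Simulate a calibration data set from a known line
#'
#' Draws (activity, rate) pairs from
#' rate = intercept + slope * activity + N(0, noise_sd), the
#' rate-level view of the calibration experiment: replicate measurements of
#' calibrator dilutions at a few activity levels. Ground truth is retained
#' in the attributes.
#'
#' @param activities Activity fractions of the calibration levels
#'   (default the standard 25/50/75/100\% gradient).
#' @param replicates Replicates per level (default 8).
#' @param intercept,slope Generating line (AU/min; slope per activity
#'   fraction). Defaults are the plasma calibration,
#'   rate = 0.0382 - 0.02616 * activity.
#' @param noise_sd Gaussian measurement noise SD on the rate (AU/min).
#' @param seed RNG seed.
#' @return A data.frame with columns \code{activity}, \code{rate}; the
#'   generating parameters are stored in attribute \code{"truth"}.
#' @export
simulate_calibration_set <- function(activities = c(0.25, 0.5, 0.75, 1.0),
                                     replicates = 8,
                                     intercept = 0.0382,
                                     slope = -0.02616,
                                     noise_sd = 5e-4,
                                     seed = .DEFAULT_SEED) {
  if (length(activities) < 2L)
    stop("at least 2 calibration activities are required")
  if (!is.null(seed)) set.seed(seed)
  a <- rep(activities, each = replicates)
  r <- intercept + slope * a + stats::rnorm(length(a), 0, noise_sd)
  out <- data.frame(activity = a, rate = r)
  attr(out, "truth") <- list(intercept = intercept, slope = slope,
                             noise_sd = noise_sd, replicates = replicates)
  out
}

#' Simulate a diluted whole-blood run
#'
#' Whole blood carries a strong hemoglobin background at 405 nm and the red
#' cells attenuate the observable pNA signal; both motivate on-chip dilution.
#' The simulator scales the static hemoglobin absorbance by
#' 1 / dilution_factor and the kinetic signal amplitude to the diluted
#' regime (whole-blood calibrations are built on samples diluted the same
#' way, so activity remains a relative quantity).
#'
#' @param activity_fraction AT activity (1.0 = 100\%).
#' @param dilution_factor Total on-chip dilution (>= 1; the standard plan
#'   is 1 part blood + 9 parts diluent, factor 10).
#' @param hemoglobin_absorbance_AU Undiluted static hemoglobin background.
#' @param noise An \code{\link{instrument_noise}}.
#' @param config An \code{\link{optical_config}}.
#' @param interferent Extra \code{\link{interferent_profile}} applied on
#'   top of the hemoglobin background.
#' @param wb_intercept,wb_slope Whole-blood rate line at the reference
#'   dilution factor 10 (defaults 0.01363 and -0.00916); the kinetic
#'   amplitude at other dilutions scales as (10 / dilution_factor).
#' @return A \code{simulated_run} (see \code{\link{simulate_run}}).
#' @export
simulate_whole_blood <- function(activity_fraction,
                                 dilution_factor = 10,
                                 hemoglobin_absorbance_AU = 1.2,
                                 noise = instrument_noise(),
                                 config = optical_config(),
                                 interferent = interferent_profile(),
                                 wb_intercept = 0.01363,
                                 wb_slope = -0.00916) {
  if (!is.finite(dilution_factor) || dilution_factor < 1)
    stop("'dilution_factor' must be >= 1")
  static_bg <- hemoglobin_absorbance_AU / dilution_factor +
    interferent$static_absorbance_AU
  # Target rate at this dilution: the reference-dilution line scaled by the
  # remaining blood fraction relative to the 1:9 reference plan.
  target_rate <- (wb_intercept + wb_slope * activity_fraction) *
    (10 / dilution_factor)
  target_rate <- max(target_rate, 0)
  # Back out kinetics that realize the target noiseless rate: zero-order
  # regime, rate_AU_min = eps * d[pNA]/dt(uM/min) * 1e-6 * l_total.
  base <- kinetics_params(at_activity_fraction = 0)
  l_tot <- total_path_mm(config)
  v_uM_per_min <- target_rate / (base$epsilon405_per_M_per_mm * 1e-6 * l_tot)
  v_uM_per_s <- v_uM_per_min / 60
  mm_factor <- base$substrate0_uM / (base$km_uM + base$substrate0_uM)
  kcat <- v_uM_per_s / mm_factor   # enzyme fixed at 1 unit, activity 0
  params <- kinetics_params(fxa0 = 1, at_activity_fraction = 0,
                            inhibition_capacity = base$inhibition_capacity,
                            substrate0_uM = base$substrate0_uM,
                            kcat_per_s = kcat, km_uM = base$km_uM,
                            epsilon405_per_M_per_mm = base$epsilon405_per_M_per_mm)
  run <- simulate_run(params = params, noise = noise, config = config,
                      interferent = interferent_profile(
                        static_absorbance_AU = static_bg,
                        drift_AU_per_min = interferent$drift_AU_per_min),
                      sample_type = "venous_whole_blood",
                      sample_id = sprintf("wb_act%.2f_dil%g",
                                          activity_fraction, dilution_factor),
                      dilution_factor = dilution_factor)
  run$truth$activity_fraction <- activity_fraction
  run$truth$target_rate_per_min <- target_rate
  run$truth$static_background_AU <- static_bg
  run
}
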