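# Pure optical / absorbance math for the double-pass (reflection-transmission)
# detection geometry: incident light crosses the droplet, reflects off the
# bottom electrode, crosses again, and is photon-counted by a PMT.

#' Physical constants
#'
#' CODATA values used throughout the photometry module.
#' @keywords internal
#' @noRd
.PLANCK_H <- 6.62607015e-34   # J s
.LIGHT_C  <- 2.99792458e8     # m / s

#' Optical configuration of the detection module
#'
#' Bundles the geometric and physical constants of the absorbance detection
#' path: a 405 nm bandpass-filtered source, a liquid layer of thickness
#' \code{path_length_mm} traversed twice (incident and reflected pass), a
#' bottom electrode of reflectance \code{reflectance_r}, and a photon-counting
#' detector of unit area \code{detector_area_mm2}.
#'
#' The total optical path used in all absorbance computations is
#' \code{2 * path_length_mm} (double pass). The chamber gap of the chip is
#' not a universal constant, so \code{path_length_mm} is configurable; only
#' ratio-level quantities (delta-absorbance) are independent of it.
#'
#' @param wavelength_nm Center wavelength of the bandpass filter (nm).
#' @param bandwidth_nm Half-peak width of the filter (nm); metadata only, the
#'   optics are treated as monochromatic at \code{wavelength_nm}.
#' @param path_length_mm Single-pass liquid thickness, i.e. the chamber gap (mm).
#' @param reflectance_r Electrode reflectance, dimensionless in (0, 1].
#' @param detector_area_mm2 Detector unit area A (mm^2).
#' @param lamp_voltage_V Supply voltage of the light source (V).
#' @param saturation_voltage_V Voltage above which (strictly) the PMT count
#'   saturates; traces acquired above it are rejected.
#' @return An object of class \code{optical_config}.
#' @examples
#' cfg <- optical_config()
#' photon_energy(cfg)
#' @export
optical_config <- function(wavelength_nm = 405,
                           bandwidth_nm = 10,
                           path_length_mm = 0.3,
                           reflectance_r = 0.9,
                           detector_area_mm2 = 1,
                           lamp_voltage_V = 2.44,
                           saturation_voltage_V = 2.45) {
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1L ||
      !is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop("invalid optical config: 'wavelength_nm' must be a positive number")
  if (reflectance_r <= 0 || reflectance_r > 1)
    stop("invalid optical config: 'reflectance_r' must be in (0, 1]")
  if (path_length_mm <= 0)
    stop("invalid optical config: 'path_length_mm' must be positive")
  if (detector_area_mm2 <= 0)
    stop("invalid optical config: 'detector_area_mm2' must be positive")
  if (saturation_voltage_V <= 0)
    stop("invalid optical config: 'saturation_voltage_V' must be positive")
  structure(
    list(wavelength_nm = wavelength_nm,
         bandwidth_nm = bandwidth_nm,
         path_length_mm = path_length_mm,
         reflectance_r = reflectance_r,
         detector_area_mm2 = detector_area_mm2,
         planck_h = .PLANCK_H,
         light_speed_c = .LIGHT_C,
         lamp_voltage_V = lamp_voltage_V,
         saturation_voltage_V = saturation_voltage_V),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength:   %g nm (half-peak width %g nm)\n",
              x$wavelength_nm, x$bandwidth_nm))
  cat(sprintf("  path length:  %g mm per pass (%g mm double-pass)\n",
              x$path_length_mm, total_path_mm(x)))
  cat(sprintf("  reflectance:  %g\n", x$reflectance_r))
  cat(sprintf("  lamp voltage: %g V (saturation above %g V)\n",
              x$lamp_voltage_V, x$saturation_voltage_V))
  invisible(x)
}

#' Total double-pass optical path length
#'
#' The beam traverses the liquid layer twice (incident and reflected pass),
#' so the effective Beer-Lambert path is twice the chamber gap.
#'
#' @param config An \code{\link{optical_config}}.
#' @return Total path length in mm.
#' @export
total_path_mm <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  2 * config$path_length_mm
}

#' Energy of a single photon at the configured wavelength
#'
#' E = h f with f = c / lambda.
#'
#' @param config An \code{\link{optical_config}}.
#' @return Photon energy in joules.
#' @examples
#' photon_energy(optical_config(wavelength_nm = 405))  # ~4.905e-19 J
#' @export
photon_energy <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  lambda_m <- config$wavelength_nm * 1e-9
  config$planck_h * config$light_speed_c / lambda_m
}

#' Convert optical intensity to a photon arrival rate
#'
#' N_photons = I A / (h f): the optical power I * A collected over the
#' detector unit area, divided by the energy of one photon.
#'
#' @param intensity Optical intensity I (W / mm^2); nonnegative.
#' @param config An \code{\link{optical_config}} supplying A, h and f.
#' @return Photon rate in photons per second.
#' @export
intensity_to_photon_rate <- function(intensity, config) {
  stopifnot(inherits(config, "optical_config"))
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensity must be finite and nonnegative")
  intensity * config$detector_area_mm2 / photon_energy(config)
}

#' Intensity after the double-pass through an absorbing droplet
#'
#' Modified Beer-Lambert transmission for the reflection-transmission path:
#' I_out = I_in * exp(-alpha * l) * r, with l the total (double-pass) path
#' and r the electrode reflectance. Because r is constant it cancels in any
#' absorbance ratio.
#'
#' @param I_in Incident intensity (arbitrary units); nonnegative.
#' @param alpha Solution absorption coefficient (mm^-1, natural log base);
#'   nonnegative.
#' @param config An \code{\link{optical_config}}.
#' @return Reflected output intensity, same units as \code{I_in}.
#' @export
reflected_intensity <- function(I_in, alpha, config) {
  stopifnot(inherits(config, "optical_config"))
  if (any(!is.finite(I_in)) || any(I_in < 0))
    stop("incident intensity must be finite and nonnegative")
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("absorption coefficient must be finite and nonnegative")
  I_in * exp(-alpha * total_path_mm(config)) * config$reflectance_r
}

#' Absorbance from an intensity ratio
#'
#' A(t) = -log10(I(t) / I0). Strictly positive intensities are required;
#' zero or negative intensities are rejected rather than clamped, because a
#' silent clamp would bias delta-absorbance.
#'
#' @param I_t Intensity at time t (must be > 0).
#' @param I0 Reference (incident or time-zero) intensity (must be > 0).
#' @return Absorbance in AU.
#' @export
absorbance <- function(I_t, I0) {
  if (any(!is.finite(I_t)) || any(I_t <= 0))
    stop("intensity I_t must be finite and strictly positive")
  if (any(!is.finite(I0)) || any(I0 <= 0))
    stop("reference intensity I0 must be finite and strictly positive")
  -log10(I_t / I0)
}

#' Absorbance change from two photon counts
#'
#' delta A = log10(N(t0) / N(t1)). All detector constants (photon energy,
#' detector area, electrode reflectance, source brightness) cancel in the
#' count ratio, so raw photon counts are sufficient.
#'
#' @param N_t0 Photon count (or rate) at the start of the window; > 0.
#' @param N_t1 Photon count (or rate) at the end of the window; > 0.
#' @return Absorbance change in AU (positive when counts decrease).
#' @examples
#' delta_absorbance(2e6, 1.5e6)  # log10(4/3) ~= 0.12494
#' @export
delta_absorbance <- function(N_t0, N_t1) {
  if (any(!is.finite(N_t0)) || any(N_t0 <= 0) ||
      any(!is.finite(N_t1)) || any(N_t1 <= 0))
    stop("photon counts must be finite and strictly positive")
  log10(N_t0 / N_t1)
}

#' Absorbance change rate over a time window
#'
#' Computes delta A between two photon counts and rescales it to one minute.
#' The assay's primary observable is the rate over the default 0-60 s window.
#'
#' @param N_t0,N_t1 Photon counts at the window endpoints; > 0.
#' @param t0_s,t1_s Window start and end in seconds; \code{t1_s > t0_s}.
#' @return An object of class \code{rate_result} with fields \code{delta_A},
#'   \code{t0_s}, \code{t1_s} and \code{rate_per_min} (AU / min).
#' @export
delta_absorbance_rate <- function(N_t0, N_t1, t0_s = 0, t1_s = 60) {
  if (!is.finite(t0_s) || !is.finite(t1_s) || t1_s <= t0_s)
    stop("invalid window: t1_s must be greater than t0_s")
  dA <- delta_absorbance(N_t0, N_t1)
  structure(
    list(delta_A = dA,
         t0_s = t0_s,
         t1_s = t1_s,
         rate_per_min = dA * 60 / (t1_s - t0_s)),
    class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("delta A = %.6g AU over [%g, %g] s  ->  %.6g AU/min\n",
              x$delta_A, x$t0_s, x$t1_s, x$rate_per_min))
  invisible(x)
}
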