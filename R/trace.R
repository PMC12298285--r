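# Raw photon-count time series -> QC-validated, dark-corrected dA/min.

.SAMPLE_TYPES <- c("plasma", "venous_whole_blood", "capillary", "calibrator",
                   "dark", "empty_chip")

#' Construct a photon-count trace
#'
#' A time-resolved photon-count trace as acquired by the PMT: one count per
#' 1000 ms bin (other spacings are allowed), plus acquisition metadata.
#'
#' @param times_ms Strictly increasing bin timestamps in milliseconds,
#'   zero-based at acquisition start.
#' @param counts Photon counts per bin; nonnegative while raw, real-valued
#'   after dark subtraction.
#' @param sample_type One of \code{"plasma"}, \code{"venous_whole_blood"},
#'   \code{"capillary"}, \code{"calibrator"}, \code{"dark"},
#'   \code{"empty_chip"}.
#' @param sample_id Free-form sample identifier.
#' @param lamp_voltage_V Acquisition voltage of the light source (V).
#' @param temperature_C Ambient temperature during acquisition, or NA.
#' @param dilution_factor Total dilution applied to the sample (>= 1).
#' @param dark_subtracted Has the dark-current mean already been removed?
#' @return An object of class \code{photon_trace}.
#' @export
photon_trace <- function(times_ms, counts,
                         sample_type = "plasma",
                         sample_id = "sample",
                         lamp_voltage_V = 2.44,
                         temperature_C = NA_real_,
                         dilution_factor = 1,
                         dark_subtracted = FALSE) {
  times_ms <- as.numeric(times_ms)
  counts <- as.numeric(counts)
  if (length(times_ms) != length(counts))
    stop("'times_ms' and 'counts' must have the same length")
  if (length(times_ms) == 0L)
    stop("empty trace: at least one bin is required")
  if (any(!is.finite(times_ms)) || any(diff(times_ms) <= 0))
    stop("'times_ms' must be finite and strictly increasing")
  if (any(!is.finite(counts)))
    stop("'counts' must be finite")
  if (!dark_subtracted && any(counts < 0))
    stop("raw (not dark-subtracted) counts must be nonnegative")
  sample_type <- match.arg(sample_type, .SAMPLE_TYPES)
  if (!is.na(dilution_factor) && dilution_factor < 1)
    stop("'dilution_factor' must be >= 1")
  structure(
    list(times_ms = times_ms,
         counts = counts,
         sample_type = sample_type,
         sample_id = sample_id,
         lamp_voltage_V = lamp_voltage_V,
         temperature_C = temperature_C,
         dilution_factor = dilution_factor,
         dark_subtracted = dark_subtracted),
    class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("Photon trace '%s' (%s): %d bins over %g s%s\n",
              x$sample_id, x$sample_type, length(x$counts),
              diff(range(x$times_ms)) / 1000,
              if (x$dark_subtracted) ", dark-subtracted" else ""))
  cat(sprintf("  counts: %.6g .. %.6g (first .. last)\n",
              x$counts[1L], x$counts[length(x$counts)]))
  invisible(x)
}

#' @export
length.photon_trace <- function(x) length(x$counts)

#' Characterize detector dark current
#'
#' Mean and sample standard deviation (n - 1 denominator) of a dark trace
#' acquired with the source blocked; this scalar model is subtracted from
#' every subsequent acquisition.
#'
#' @param trace A \code{\link{photon_trace}} with
#'   \code{sample_type = "dark"}.
#' @return An object of class \code{dark_current_model} with fields
#'   \code{mean_counts}, \code{sd_counts}, \code{n_points}.
#' @export
characterize_dark_current <- function(trace) {
  stopifnot(inherits(trace, "photon_trace"))
  if (trace$sample_type != "dark")
    stop("dark-current characterization requires a trace with sample_type 'dark'")
  if (length(trace$counts) < 2L)
    stop("insufficient data: at least 2 dark bins are required")
  structure(
    list(mean_counts = mean(trace$counts),
         sd_counts = stats::sd(trace$counts),
         n_points = length(trace$counts)),
    class = "dark_current_model")
}

#' @export
print.dark_current_model <- function(x, ...) {
  cat(sprintf("Dark current: %.2f +/- %.2f counts/bin (mean +/- SD, n = %d)\n",
              x$mean_counts, x$sd_counts, x$n_points))
  invisible(x)
}

#' Subtract the dark-current mean from a trace
#'
#' Removes the scalar dark mean from every bin. Corrected counts may go
#' negative in very low-light bins; they are kept (clamping would bias
#' delta-absorbance upward) but a warning is raised, and rate computation
#' later rejects nonpositive endpoint counts.
#'
#' @param trace A raw \code{\link{photon_trace}} (not yet dark-subtracted).
#' @param dark A \code{dark_current_model} from
#'   \code{\link{characterize_dark_current}}.
#' @return The trace with corrected counts and \code{dark_subtracted = TRUE}.
#' @export
subtract_dark <- function(trace, dark) {
  stopifnot(inherits(trace, "photon_trace"),
            inherits(dark, "dark_current_model"))
  if (trace$dark_subtracted)
    stop("trace is already dark-subtracted; refusing to subtract twice")
  corrected <- trace$counts - dark$mean_counts
  if (any(corrected <= 0))
    warning(sprintf(
      "%d bin(s) have nonpositive counts after dark subtraction",
      sum(corrected <= 0)))
  trace$counts <- corrected
  trace$dark_subtracted <- TRUE
  trace
}

#' Light-source stability check on an empty-chip trace
#'
#' Coefficient of variation of the photon count with no droplet loaded.
#' The source is accepted as stable when CV stays within
#' \code{cv_bound_percent} (default 0.5\%).
#'
#' @param trace A \code{\link{photon_trace}} with
#'   \code{sample_type = "empty_chip"}.
#' @param cv_bound_percent Acceptance bound on CV (percent).
#' @return An object of class \code{source_stability_report} with
#'   \code{mean_counts}, \code{cv_percent}, \code{passes}.
#' @export
source_stability <- function(trace, cv_bound_percent = 0.5) {
  stopifnot(inherits(trace, "photon_trace"))
  if (trace$sample_type != "empty_chip")
    stop("source stability requires a trace with sample_type 'empty_chip'")
  if (length(trace$counts) < 2L)
    stop("insufficient data: at least 2 bins are required")
  m <- mean(trace$counts)
  if (m == 0) stop("undefined CV: mean count is zero")
  cv <- 100 * stats::sd(trace$counts) / m
  structure(
    list(mean_counts = m,
         cv_percent = cv,
         cv_bound_percent = cv_bound_percent,
         passes = cv <= cv_bound_percent),
    class = "source_stability_report")
}

#' @export
print.source_stability_report <- function(x, ...) {
  cat(sprintf("Source stability: mean %.2f counts/bin, CV %.4g%% (bound %g%%) -> %s\n",
              x$mean_counts, x$cv_percent, x$cv_bound_percent,
              if (x$passes) "PASS" else "FAIL"))
  invisible(x)
}

#' Fit the linear temperature dependence of the source count
#'
#' Ordinary least squares of mean photon counts on ambient temperature.
#' Used to document (and optionally correct) the slow drift of the source
#' with temperature; over the instrument's operating range the effect on
#' delta-absorbance is negligible, so correction is off by default
#' downstream.
#'
#' @param temps_C Temperatures in degrees Celsius; at least 2 distinct.
#' @param counts Mean photon counts at each temperature.
#' @return An object of class \code{temperature_model} with
#'   \code{slope_counts_per_C}, \code{intercept_counts}, \code{r_squared}.
#' @export
fit_temperature_model <- function(temps_C, counts) {
  if (length(temps_C) != length(counts))
    stop("'temps_C' and 'counts' must have the same length")
  if (length(unique(temps_C)) < 2L)
    stop("rank deficiency: at least 2 distinct temperatures are required")
  fit <- stats::lm(counts ~ temps_C)
  # noiseless collinear input is a legitimate oracle case; summary.lm warns
  r2 <- if (stats::var(counts) == 0) 1
        else suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope_counts_per_C = unname(stats::coef(fit)[2L]),
         intercept_counts = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         fit = fit),
    class = "temperature_model")
}

#' @export
print.temperature_model <- function(x, ...) {
  cat(sprintf("Temperature model: counts = %.6g + %.6g * T(C), R^2 = %.4f\n",
              x$intercept_counts, x$slope_counts_per_C, x$r_squared))
  invisible(x)
}

#' Predicted source counts at a temperature
#' @param model A \code{temperature_model}.
#' @param temps_C Temperatures (C).
#' @return Predicted counts per bin.
#' @export
predict_counts <- function(model, temps_C) {
  stopifnot(inherits(model, "temperature_model"))
  model$intercept_counts + model$slope_counts_per_C * temps_C
}

#' Remove modeled temperature drift from a trace
#'
#' Optional pre-step: subtracts the model-predicted source-count offset of
#' the trace's acquisition temperature relative to a reference temperature.
#' Off by default in the pipeline, because the temperature effect on the
#' count ratio is negligible over the operating range.
#'
#' @param trace A \code{\link{photon_trace}} with \code{temperature_C} set.
#' @param model A \code{temperature_model}.
#' @param reference_C Reference temperature (C).
#' @return The trace with drift-corrected counts.
#' @export
correct_temperature <- function(trace, model, reference_C = 25) {
  stopifnot(inherits(trace, "photon_trace"),
            inherits(model, "temperature_model"))
  if (is.na(trace$temperature_C))
    stop("trace has no acquisition temperature")
  offset <- model$slope_counts_per_C * (trace$temperature_C - reference_C)
  trace$counts <- trace$counts - offset
  trace
}

#' PMT saturation check
#'
#' The photon count saturates when the lamp voltage strictly exceeds the
#' configured saturation threshold; the threshold voltage itself is usable.
#' Saturated traces are rejected by rate computation.
#'
#' @param trace A \code{\link{photon_trace}}.
#' @param config An \code{\link{optical_config}} supplying the threshold.
#' @return TRUE if saturated.
#' @export
check_saturation <- function(trace, config = optical_config()) {
  stopifnot(inherits(trace, "photon_trace"),
            inherits(config, "optical_config"))
  if (is.null(trace$lamp_voltage_V) || is.na(trace$lamp_voltage_V))
    stop("trace has no lamp voltage")
  trace$lamp_voltage_V > config$saturation_voltage_V
}

# Nearest bin to a target time; ties broken toward the earlier bin.
.nearest_bin <- function(times_ms, target_ms) {
  d <- abs(times_ms - target_ms)
  which(d == min(d))[1L]
}

#' Absorbance change rate of a dark-corrected trace
#'
#' Picks the photon counts at the bins nearest to \code{t0_s} and
#' \code{t1_s} (ties toward the earlier bin; no interpolation, since the
#' 1000 ms bin spacing bounds the timing error at 0.5 s over a 60 s window)
#' and computes delta A / min via the count-ratio law.
#'
#' @param trace A dark-subtracted, non-saturated \code{\link{photon_trace}}.
#' @param t0_s,t1_s Rate window in seconds (defaults 0 and 60).
#' @param config An \code{\link{optical_config}} for the saturation check.
#' @return A \code{rate_result} (see \code{\link{delta_absorbance_rate}}).
#' @export
compute_rate <- function(trace, t0_s = 0, t1_s = 60,
                         config = optical_config()) {
  stopifnot(inherits(trace, "photon_trace"))
  if (!trace$dark_subtracted)
    stop("trace must be dark-subtracted before rate computation")
  if (check_saturation(trace, config))
    stop("saturated trace: lamp voltage exceeds the saturation threshold")
  if (t1_s <= t0_s) stop("invalid window: t1_s must be greater than t0_s")
  span <- range(trace$times_ms) / 1000
  half_bin_s <- if (length(trace$times_ms) > 1L)
    min(diff(trace$times_ms)) / 2000 else 0
  if (t0_s < span[1L] - half_bin_s || t1_s > span[2L] + half_bin_s)
    stop(sprintf("window [%g, %g] s lies outside the trace span [%g, %g] s",
                 t0_s, t1_s, span[1L], span[2L]))
  i0 <- .nearest_bin(trace$times_ms, t0_s * 1000)
  i1 <- .nearest_bin(trace$times_ms, t1_s * 1000)
  N0 <- trace$counts[i0]
  N1 <- trace$counts[i1]
  if (!is.finite(N0) || !is.finite(N1) || N0 <= 0 || N1 <= 0)
    stop("data quality: nonpositive corrected counts at a window endpoint")
  delta_absorbance_rate(N0, N1, t0_s = t0_s, t1_s = t1_s)
}
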