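# Calibration fitting, inverse quantification of AT activity, and
# method-validation statistics (repeatability CV, KS consistency,
# relative differences against a reference instrument).

#' Fit a linear calibration curve
#'
#' Ordinary least squares of the absorbance change rate (dA/min) on AT
#' activity, with activity expressed as a FRACTION of the calibrator
#' (1.0 = 100\%). The slope is expected to be negative: higher antithrombin
#' activity leaves less residual factor Xa, slows the color reaction, and
#' lowers dA/min. Inverse prediction is by algebraic inversion of this line
#' (classical calibration), not by regressing activity on rate.
#'
#' @param activities Activity fractions of the calibration points; at least
#'   2 distinct values.
#' @param rates Measured dA/min at each point (AU/min).
#' @param sample_type Matrix the calibration was built in: \code{"plasma"}
#'   or \code{"whole_blood"}. Activities are always read against the
#'   calibration of the matching matrix.
#' @param r2_bound Linearity acceptance bound on R^2 (default 0.985).
#' @return An object of class \code{calibration_curve} with \code{intercept},
#'   \code{slope}, \code{r_squared}, \code{pearson_r}, \code{n_points},
#'   \code{passes_linearity}, \code{sample_type}.
#' @examples
#' a <- c(0.25, 0.5, 0.75, 1.0)
#' fit_calibration(a, 0.0382 - 0.02616 * a)
#' @export
fit_calibration <- function(activities, rates,
                            sample_type = c("plasma", "whole_blood"),
                            r2_bound = 0.985) {
  sample_type <- match.arg(sample_type)
  if (length(activities) != length(rates))
    stop("'activities' and 'rates' must have the same length")
  if (length(activities) < 2L)
    stop("at least 2 calibration points are required")
  if (length(unique(activities)) < 2L)
    stop("rank deficiency: calibration requires at least 2 distinct activities")
  fit <- stats::lm(rates ~ activities)
  cf <- stats::coef(fit)
  # Noiseless collinear data can make summary()'s R^2 fragile; derive it
  # from residuals directly.
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((rates - mean(rates))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  r2 <- min(max(r2, 0), 1)
  pr <- suppressWarnings(stats::cor(activities, rates))
  if (is.na(pr)) pr <- 0
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) c(NA_real_, NA_real_))
  structure(
    list(intercept = unname(cf[1L]),
         slope = unname(cf[2L]),
         r_squared = r2,
         pearson_r = pr,
         n_points = length(activities),
         se_intercept = unname(se[1L]),
         se_slope = unname(se[2L]),
         r2_bound = r2_bound,
         passes_linearity = r2 >= r2_bound,
         sample_type = sample_type),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration (%s, n = %d): dA/min = %.5g %s %.5g * activity\n",
              x$sample_type, x$n_points, x$intercept,
              if (x$slope < 0) "-" else "+", abs(x$slope)))
  cat(sprintf("  R^2 = %.4f (bound %.4g) -> linearity %s; Pearson r = %.4f\n",
              x$r_squared, x$r2_bound,
              if (x$passes_linearity) "PASS" else "FAIL", x$pearson_r))
  invisible(x)
}

#' Predicted dA/min at a given activity
#' @param object A \code{calibration_curve}.
#' @param activity_fraction Activity as a fraction (1.0 = 100\%).
#' @param ... Unused.
#' @return Predicted rate (AU/min).
#' @export
predict.calibration_curve <- function(object, activity_fraction, ...) {
  object$intercept + object$slope * activity_fraction
}

#' Invert a calibration curve to estimate activity
#'
#' Classical (inverse-prediction) calibration: the measured rate is mapped
#' back through the fitted line, activity = (rate - intercept) / slope.
#'
#' @param curve A \code{calibration_curve}.
#' @param rate Measured dA/min (AU/min); may be a vector.
#' @param dilution_factor Dilution applied to the sample; recorded only --
#'   activity is a relative quantity against the matching calibrator, so no
#'   back-multiplication is applied.
#' @param slope_tol Minimum |slope| considered invertible.
#' @return An object of class \code{activity_result} with
#'   \code{rate_per_min}, \code{activity_fraction}, \code{activity_percent},
#'   \code{dilution_factor}, \code{sample_type}.
#' @export
invert_calibration <- function(curve, rate, dilution_factor = 1,
                               slope_tol = 1e-12) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || abs(curve$slope) < slope_tol)
    stop("ill-conditioned calibration: |slope| is below tolerance")
  frac <- (rate - curve$intercept) / curve$slope
  structure(
    list(rate_per_min = rate,
         activity_fraction = frac,
         activity_percent = 100 * frac,
         dilution_factor = dilution_factor,
         sample_type = curve$sample_type),
    class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("AT activity: %s%% (rate %s AU/min, %s calibration)\n",
              paste(sprintf("%.1f", x$activity_percent), collapse = ", "),
              paste(signif(x$rate_per_min, 5), collapse = ", "),
              x$sample_type))
  invisible(x)
}

#' Repeatability of replicate measurements
#'
#' CV(\%) = 100 * SD / mean over replicate measurements (sample SD, n - 1
#' denominator). Acceptance follows the pharmacopoeial repeatability rule
#' CV <= 10\% for this assay class.
#'
#' @param values Replicate measurements (activity \%, or dA/min); n >= 2.
#' @param cv_bound_percent Acceptance bound (default 10).
#' @return An object of class \code{repeatability_report} with \code{mean},
#'   \code{sd}, \code{cv_percent}, \code{passes}.
#' @export
repeatability <- function(values, cv_bound_percent = 10) {
  if (length(values) < 2L)
    stop("at least 2 replicate values are required")
  m <- mean(values)
  if (m == 0) stop("undefined CV: mean is zero")
  cv <- 100 * stats::sd(values) / abs(m)
  structure(
    list(mean = m,
         sd = stats::sd(values),
         cv_percent = cv,
         cv_bound_percent = cv_bound_percent,
         passes = cv <= cv_bound_percent),
    class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("Repeatability: mean %.4g, SD %.4g, CV %.3g%% (bound %g%%) -> %s\n",
              x$mean, x$sd, x$cv_percent, x$cv_bound_percent,
              if (x$passes) "PASS" else "FAIL"))
  invisible(x)
}

# Round half away from zero to `digits` decimals (display convention for
# reported activity differences; full precision is always retained).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Relative difference against a reference measurement
#'
#' 100 * |reference - test| / reference, the per-sample agreement metric
#' for comparing the device against a reference laboratory instrument.
#'
#' @param reference_percent Reference-instrument activity (\%); > 0.
#' @param test_percent Device activity (\%).
#' @return A list with \code{raw} (full precision) and \code{rounded}
#'   (one decimal, half-up) relative differences in percent; vectors when
#'   the inputs are vectors.
#' @examples
#' relative_difference(112, 112.227)$rounded  # 0.2
#' @export
relative_difference <- function(reference_percent, test_percent) {
  if (any(!is.finite(reference_percent)) || any(reference_percent <= 0))
    stop("reference activity must be finite and strictly positive")
  raw <- 100 * abs(reference_percent - test_percent) / reference_percent
  list(raw = raw, rounded = round_half_up(raw, 1))
}

#' Two-sample Kolmogorov-Smirnov consistency check
#'
#' D = sup |ECDF_a - ECDF_b| with the asymptotic two-sample p-value, used
#' to check that device results on clinical samples are distributed
#' consistently with the calibrator-anchored results.
#'
#' @param sample_a,sample_b Nonempty numeric samples.
#' @return A list with \code{statistic} (D) and \code{p_value}.
#' @export
ks_consistency <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("insufficient data: both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Sample-preparation dilution plan
#'
#' Returns the prescribed dilution for a sample type. Plasma (and
#' reconstituted calibrators) are pre-diluted off-chip, 8 uL supernatant
#' into 320 uL of factor dilution buffer. Whole blood and capillary blood
#' are diluted on-chip, 1 part sample to 9 parts diluent (factor 10), to
#' suppress the hemoglobin background from red cells. Activity is read
#' against the calibration built in the matching matrix, so no post-hoc
#' back-correction for dilution is applied.
#'
#' @param sample_type One of \code{"plasma"}, \code{"calibrator"},
#'   \code{"venous_whole_blood"}, \code{"capillary"}.
#' @return A list describing the plan: \code{sample_type},
#'   \code{dilution_factor}, \code{stage} (off_chip / on_chip),
#'   \code{sample_parts}, \code{diluent_parts}, \code{calibration_matrix},
#'   \code{back_correct} (always FALSE).
#' @export
apply_dilution_plan <- function(sample_type) {
  if (length(sample_type) != 1L || !sample_type %in%
      c("plasma", "calibrator", "venous_whole_blood", "capillary"))
    stop("unknown sample type: no dilution plan configured")
  if (sample_type %in% c("plasma", "calibrator")) {
    list(sample_type = sample_type,
         dilution_factor = (8 + 320) / 8,
         stage = "off_chip",
         sample_parts = 8, diluent_parts = 320,
         calibration_matrix = "plasma",
         back_correct = FALSE)
  } else {
    list(sample_type = sample_type,
         dilution_factor = 10,
         stage = "on_chip",
         sample_parts = 1, diluent_parts = 9,
         calibration_matrix = "whole_blood",
         back_correct = FALSE)
  }
}
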