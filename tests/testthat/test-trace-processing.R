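test_that("photon trace constructor enforces its invariants", {
  expect_error(photon_trace(c(0, 1000, 500), c(1, 2, 3)), "increasing")
  expect_error(photon_trace(c(0, 1000), c(1, 2, 3)), "length")
  expect_error(photon_trace(c(0, 1000), c(-1, 2)), "nonnegative")
  expect_error(photon_trace(numeric(0), numeric(0)), "empty")
  expect_error(photon_trace(c(0, 1000), c(1, 2), dilution_factor = 0.5),
               "dilution_factor")
  tr <- photon_trace(c(0, 1000), c(5, 6), sample_type = "dark")
  expect_s3_class(tr, "photon_trace")
  expect_length(tr, 2L)
})

test_that("dark-current characterization reports sample mean and SD", {
  flat <- photon_trace(seq(0, 4000, 1000), rep(384461, 5),
                       sample_type = "dark")
  dm <- characterize_dark_current(flat)
  expect_equal(dm$mean_counts, 384461)
  expect_equal(dm$sd_counts, 0)
  tr <- photon_trace(seq(0, 4000, 1000),
                     c(384000, 384200, 384400, 384600, 384800),
                     sample_type = "dark")
  dm <- characterize_dark_current(tr)
  expect_equal(dm$mean_counts, 384400)
  expect_equal(dm$sd_counts, 316.23, tolerance = 1e-4)   # n-1 denominator
  expect_equal(dm$n_points, 5L)
  # wrong sample type and insufficient data are rejected
  expect_error(characterize_dark_current(
    photon_trace(c(0, 1000), c(1, 2), sample_type = "plasma")), "dark")
  expect_error(characterize_dark_current(
    photon_trace(0, 5, sample_type = "dark")), "nsufficient")
})

test_that("30-point dark simulation recovers the generator mean", {
  noise <- instrument_noise(seed = 424242)
  dm <- characterize_dark_current(simulate_dark_trace(noise, n_bins = 30))
  expect_lt(abs(dm$mean_counts - DARK_MEAN), 3 * DARK_SD / sqrt(30))
})

test_that("dark subtraction is scalar, single-shot, and warns on nonpositive", {
  tr <- photon_trace(c(0, 1000), c(1384461, 1384461))
  out <- subtract_dark(tr, make_dark(384461))
  expect_equal(out$counts, c(1e6, 1e6))
  expect_true(out$dark_subtracted)
  expect_error(subtract_dark(out, make_dark(384461)), "twice")
  # zero dark mean is the identity
  expect_equal(subtract_dark(tr, zero_dark)$counts, tr$counts)
  # nonpositive corrected counts are kept but flagged
  low <- photon_trace(c(0, 1000), c(384000, 500000))
  expect_warning(res <- subtract_dark(low, make_dark(384461)), "nonpositive")
  expect_equal(res$counts[1], -461)
})

test_that("dark subtraction must precede the log-ratio to matter", {
  # worked pair: a decaying trace plus a constant dark offset
  dark_mean <- 384461
  true_counts <- c(2e6, 1.6e6)
  raw <- photon_trace(c(0, 60000), true_counts + dark_mean)
  wrong <- delta_absorbance(raw$counts[1], raw$counts[2])  # skipped subtraction
  corrected <- subtract_dark(raw, make_dark(dark_mean))
  right <- delta_absorbance(corrected$counts[1], corrected$counts[2])
  expect_equal(right, log10(2e6 / 1.6e6), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(wrong, right)))
  expect_lt(wrong, right)   # unremoved dark biases delta A downward
})

test_that("source stability reports CV and applies the acceptance bound", {
  flat <- photon_trace(seq(0, 3000, 1000), rep(2.4e7, 4),
                       sample_type = "empty_chip")
  rep0 <- source_stability(flat)
  expect_equal(rep0$cv_percent, 0)
  expect_true(rep0$passes)
  tr <- photon_trace(seq(0, 7000, 1000),
                     c(100, 102, 98, 101, 99, 100, 103, 97),
                     sample_type = "empty_chip")
  rep1 <- source_stability(tr)
  expect_equal(rep1$mean_counts, 100)
  expect_equal(rep1$cv_percent, 2.0)
  expect_false(rep1$passes)           # 2% > 0.5% bound
  expect_true(source_stability(tr, cv_bound_percent = 5)$passes)
  expect_error(source_stability(
    photon_trace(c(0, 1000), c(1, 2), sample_type = "plasma")), "empty_chip")
})

test_that("Poisson empty-chip CV converges to 1/sqrt(mean)", {
  mu <- 2.44e7
  noise <- instrument_noise(source_mean_counts = mu, dark_mean_counts = 0,
                            dark_sd_counts = 0, seed = 7)
  n_bins <- 400
  tr <- simulate_empty_chip_trace(noise, n_bins = n_bins)
  rep <- source_stability(tr)
  cv_expected <- 100 / sqrt(mu)           # ~0.02%
  # sampling error of a CV estimate from n bins is ~ CV / sqrt(2 n)
  mc_err <- cv_expected / sqrt(2 * n_bins)
  expect_lt(abs(rep$cv_percent - cv_expected), 3 * mc_err)
  expect_true(rep$passes)
})

test_that("temperature model is recovered by OLS", {
  temps <- c(18, 23, 28, 33, 38)
  exact <- TEMP_INTERCEPT + TEMP_SLOPE * temps
  m <- fit_temperature_model(temps, exact)
  expect_equal(m$slope_counts_per_C, TEMP_SLOPE, tolerance = 1e-6)
  expect_equal(m$intercept_counts, TEMP_INTERCEPT, tolerance = 1e-6)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  # two points define the line exactly
  m2 <- fit_temperature_model(c(10, 20), c(100, 300))
  expect_equal(m2$slope_counts_per_C, 20)
  expect_equal(m2$intercept_counts, -100)
  # noisy recovery within 3 SE
  set.seed(99)
  noisy <- exact + stats::rnorm(5, 0, 5000)
  m3 <- fit_temperature_model(temps, noisy)
  se <- summary(m3$fit)$coefficients["temps_C", "Std. Error"]
  expect_lt(abs(m3$slope_counts_per_C - TEMP_SLOPE), 3 * se)
  expect_error(fit_temperature_model(c(25, 25), c(1, 2)), "ank deficiency")
})

test_that("temperature correction shifts counts by the modeled drift", {
  m <- fit_temperature_model(c(18, 38), TEMP_INTERCEPT + TEMP_SLOPE * c(18, 38))
  tr <- photon_trace(c(0, 1000), c(2.4e7, 2.4e7), temperature_C = 30)
  out <- correct_temperature(tr, m, reference_C = 25)
  expect_equal(out$counts, tr$counts - TEMP_SLOPE * 5, tolerance = 1e-6)
  expect_equal(predict_counts(m, 25), TEMP_INTERCEPT + TEMP_SLOPE * 25,
               tolerance = 1e-6)
})

test_that("saturation flag uses a strict voltage threshold", {
  cfg <- optical_config(saturation_voltage_V = 2.45)
  mk <- function(v) photon_trace(c(0, 1000), c(1, 2), lamp_voltage_V = v)
  expect_false(check_saturation(mk(2.44), cfg))
  expect_true(check_saturation(mk(2.46), cfg))
  expect_false(check_saturation(mk(2.45), cfg))   # boundary is usable
})

test_that("compute_rate picks nearest bins and applies the count-ratio law", {
  # flat trace -> zero rate
  flat <- make_corrected_trace(rep(1e6, 61))
  expect_equal(compute_rate(flat)$rate_per_min, 0)
  # worked decay over 60 s
  counts <- c(1e6, rep(0.99e6, 59), 0.9772e6)
  tr <- make_corrected_trace(counts)
  expect_equal(compute_rate(tr)$rate_per_min, 0.01002, tolerance = 1e-3)
  # guards
  raw <- photon_trace(c(0, 60000), c(1e6, 9e5))
  expect_error(compute_rate(raw), "dark-subtracted")
  sat <- make_corrected_trace(rep(1e6, 61), lamp_voltage_V = 2.46)
  expect_error(compute_rate(sat), "aturated")
  short <- make_corrected_trace(rep(1e6, 10))
  expect_error(compute_rate(short), "span")
  neg <- make_corrected_trace(c(-5, rep(1e6, 60)))
  expect_error(compute_rate(neg), "quality")
})

test_that("compute_rate is invariant to source brightness", {
  set.seed(3)
  counts <- 1e6 * 10^(-cumsum(stats::runif(61, 0, 0.002)))
  base <- compute_rate(make_corrected_trace(counts))$rate_per_min
  for (k in c(1e-3, 0.5, 7, 1e4)) {
    scaled <- compute_rate(make_corrected_trace(k * counts))$rate_per_min
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("lower AT activity gives the faster color reaction", {
  rate_at <- function(a) {
    run <- simulate_run(kinetics_params(at_activity_fraction = a),
                        noise = noiseless_instrument())
    compute_rate(subtract_dark(run$trace, zero_dark))$rate_per_min
  }
  expect_gt(rate_at(0.25), rate_at(1.0))
})
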