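test_that("full inhibition yields no pNA release", {
  p <- kinetics_params(fxa0 = 1, inhibition_capacity = 1,
                       at_activity_fraction = 1)
  expect_equal(residual_enzyme(p), 0)
  conc <- simulate_reaction(p, duration_s = 120, dt_s = 1)
  expect_true(all(conc$pna_uM == 0))
})

test_that("reaction is zero-order when substrate is far above Km", {
  p <- kinetics_params(at_activity_fraction = 0, substrate0_uM = 5e4,
                       km_uM = 50)
  conc <- simulate_reaction(p, duration_s = 60, dt_s = 1)
  e_res <- residual_enzyme(p)
  analytic <- p$kcat_per_s * e_res * conc$time_s   # zero-order limit
  rel_err <- abs(conc$pna_uM[-1] - analytic[-1]) / analytic[-1]
  expect_lt(max(rel_err), 0.01)
  # doubling residual enzyme doubles early-time product
  p2 <- kinetics_params(fxa0 = 2, at_activity_fraction = 0,
                        substrate0_uM = 5e4, km_uM = 50)
  conc2 <- simulate_reaction(p2, duration_s = 60, dt_s = 1)
  expect_equal(conc2$pna_uM[11] / conc$pna_uM[11], 2, tolerance = 0.01)
})

test_that("pNA is monotone nondecreasing and conserves substrate", {
  for (a in c(0, 0.3, 0.8, 1.2)) {
    p <- kinetics_params(at_activity_fraction = a, substrate0_uM = 100)
    conc <- simulate_reaction(p, duration_s = 600, dt_s = 5)
    expect_true(all(diff(conc$pna_uM) >= 0))
    expect_true(all(conc$pna_uM <= p$substrate0_uM + 1e-9))
  }
  # second-order inhibition obeys the same bounds
  p2 <- kinetics_params(at_activity_fraction = 0.5,
                        inhibition_mode = "second_order", k_inhib = 0.5)
  conc2 <- simulate_reaction(p2, duration_s = 120, dt_s = 1)
  expect_true(all(diff(conc2$pna_uM) >= 0))
  expect_true(all(conc2$pna_uM <= p2$substrate0_uM + 1e-9))
  expect_error(kinetics_params(km_uM = -1), "nonnegative")
})

test_that("Beer-Lambert conversion uses the double-pass path", {
  cfg <- optical_config(path_length_mm = 0.3)   # l_total = 0.6 mm
  p <- kinetics_params(epsilon405_per_M_per_mm = 990)
  a <- concentration_to_absorbance(10, params = p, config = cfg, times_s = 0)
  expect_equal(a$absorbance_AU, 0.00594, tolerance = 1e-10)
  # zero concentration, no interferent -> zero absorbance
  expect_equal(
    concentration_to_absorbance(0, params = p, config = cfg,
                                times_s = 0)$absorbance_AU, 0)
  # static interferent shifts A but cancels in delta A downstream
  intf <- interferent_profile(static_absorbance_AU = 0.8)
  a2 <- concentration_to_absorbance(c(0, 0), params = p, config = cfg,
                                    interferent = intf, times_s = c(0, 60))
  expect_equal(a2$absorbance_AU, c(0.8, 0.8))
})

test_that("simulated traces follow the attenuation law exactly when noiseless", {
  # flat zero absorbance -> flat trace at the source mean
  a0 <- data.frame(time_s = c(0, 30), absorbance_AU = c(0, 0))
  tr <- simulate_trace(a0, noise = noiseless_instrument(
    source_mean_counts = 1e7))
  expect_true(all(tr$counts == 1e7))
  # A(60) = 0.01 -> count ratio 10^-0.01
  a1 <- data.frame(time_s = c(0, 60), absorbance_AU = c(0, 0.01))
  tr1 <- simulate_trace(a1, noise = noiseless_instrument())
  n <- length(tr1$counts)
  expect_equal(tr1$counts[n] / tr1$counts[1], 10^(-0.01), tolerance = 1e-12)
  expect_equal(tr1$counts[n] / tr1$counts[1], 0.97724, tolerance = 1e-4)
})

test_that("Poisson shot noise has CV 1/sqrt(N) and seeds reproduce exactly", {
  mu <- 1e6
  a0 <- data.frame(time_s = c(0, 499), absorbance_AU = c(0, 0))
  noise <- instrument_noise(source_mean_counts = mu, dark_mean_counts = 0,
                            dark_sd_counts = 0, seed = 101)
  tr <- simulate_trace(a0, noise = noise)
  cv <- 100 * stats::sd(tr$counts) / mean(tr$counts)
  cv_expected <- 100 / sqrt(mu)
  expect_lt(abs(cv - cv_expected), 3 * cv_expected / sqrt(2 * 500))
  # bit-for-bit reproducibility at the count level
  tr2 <- simulate_trace(a0, noise = noise)
  expect_identical(tr$counts, tr2$counts)
  # a different seed gives a different realization
  tr3 <- simulate_trace(a0, noise = instrument_noise(
    source_mean_counts = mu, dark_mean_counts = 0, dark_sd_counts = 0,
    seed = 102))
  expect_false(identical(tr$counts, tr3$counts))
})

test_that("noiseless simulate -> process recovers the analytic rate", {
  cfg <- optical_config()
  for (a in c(0, 0.25, 0.5, 0.75, 1.0)) {
    p <- kinetics_params(at_activity_fraction = a)
    conc <- simulate_reaction(p, duration_s = 90, dt_s = 1)
    run <- simulate_run(p, noise = noiseless_instrument(), config = cfg)
    measured <- compute_rate(subtract_dark(run$trace, zero_dark),
                             config = cfg)$rate_per_min
    # analytic double-pass Beer-Lambert rate from the concentration series
    d_pna <- conc$pna_uM[conc$time_s == 60] - conc$pna_uM[conc$time_s == 0]
    analytic <- p$epsilon405_per_M_per_mm * d_pna * 1e-6 * total_path_mm(cfg)
    expect_equal(measured, analytic, tolerance = 1e-8)
  }
})

test_that("static interferent leaves the rate unchanged; drift does not", {
  p <- kinetics_params(at_activity_fraction = 0.5)
  rate_with <- function(intf) {
    run <- simulate_run(p, noise = noiseless_instrument(), interferent = intf)
    compute_rate(subtract_dark(run$trace, zero_dark))$rate_per_min
  }
  base <- rate_with(interferent_profile())
  for (s in c(0.1, 0.6, 1.5)) {
    expect_equal(rate_with(interferent_profile(static_absorbance_AU = s)),
                 base, tolerance = 1e-10)
  }
  # lipemic-style drift biases the measured rate by its own magnitude
  drifted <- rate_with(interferent_profile(drift_AU_per_min = 0.005))
  expect_equal(drifted - base, 0.005, tolerance = 1e-6)
})

test_that("noiseless rate is strictly decreasing in AT activity", {
  activities <- seq(0, 1.4, by = 0.2)   # spans up to full inhibition
  rates <- vapply(activities, function(a) {
    run <- simulate_run(kinetics_params(at_activity_fraction = a),
                        noise = noiseless_instrument())
    compute_rate(subtract_dark(run$trace, zero_dark))$rate_per_min
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("calibration-set generator honors its line and noise contract", {
  exact <- simulate_calibration_set(noise_sd = 0, seed = 1)
  expect_equal(exact$rate, 0.0382 - 0.02616 * exact$activity,
               tolerance = 1e-12)
  expect_equal(nrow(exact), 32L)        # 4 levels x 8 replicates
  # degenerate activities propagate to a rank-deficiency error downstream
  degen <- simulate_calibration_set(activities = c(0.5, 0.5), seed = 1)
  expect_error(fit_calibration(degen$activity, degen$rate), "ank deficiency")
})

test_that("whole-blood simulation responds to dilution as designed", {
  noise <- noiseless_instrument()
  run10 <- simulate_whole_blood(0.5, dilution_factor = 10, noise = noise)
  run1 <- simulate_whole_blood(0.5, dilution_factor = 1, noise = noise)
  # hemoglobin background falls 10-fold under the 1:9 plan
  expect_equal(run1$truth$static_background_AU /
                 run10$truth$static_background_AU, 10)
  # measured rate decreases monotonically (and convexly) with dilution
  rates <- vapply(c(1, 2, 5, 10, 20), function(d) {
    run <- simulate_whole_blood(0.5, dilution_factor = d, noise = noise)
    compute_rate(subtract_dark(run$trace, zero_dark))$rate_per_min
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_true(all(diff(diff(rates)) > 0))
  # higher activity -> smaller rate at fixed dilution
  r025 <- simulate_whole_blood(0.25, noise = noise)
  r100 <- simulate_whole_blood(1.0, noise = noise)
  expect_gt(compute_rate(subtract_dark(r025$trace, zero_dark))$rate_per_min,
            compute_rate(subtract_dark(r100$trace, zero_dark))$rate_per_min)
  expect_error(simulate_whole_blood(0.5, dilution_factor = 0.5), ">= 1")
})

test_that("simulated truth stores a recomputable noiseless rate", {
  p <- kinetics_params(at_activity_fraction = 0.75)
  run <- simulate_run(p, noise = noiseless_instrument())
  conc <- simulate_reaction(p, duration_s = 90, dt_s = 1)
  absb <- concentration_to_absorbance(conc, params = p)
  recomputed <- (absb$absorbance_AU[absb$time_s == 60] -
                   absb$absorbance_AU[absb$time_s == 0])
  expect_equal(run$truth$true_rate_per_min, recomputed, tolerance = 1e-12)
})
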