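# Shared fixtures and independent oracles.

# Dark model with prescribed moments (bypasses characterization).
make_dark <- function(mean_counts, sd_counts = 0, n = 30L) {
  structure(list(mean_counts = mean_counts, sd_counts = sd_counts,
                 n_points = n),
            class = "dark_current_model")
}

zero_dark <- make_dark(0)

# A dark-subtracted trace straight from counts.
make_corrected_trace <- function(counts, dt_ms = 1000, ...) {
  photon_trace(times_ms = seq(0, by = dt_ms, length.out = length(counts)),
               counts = counts, dark_subtracted = TRUE, ...)
}

# Brute-force two-sample KS statistic: scan |ECDF_a - ECDF_b| over the
# pooled values. Independent of stats::ks.test.
ks_D_oracle <- function(a, b) {
  x <- sort(unique(c(a, b)))
  Fa <- vapply(x, function(v) mean(a <= v), numeric(1))
  Fb <- vapply(x, function(v) mean(b <= v), numeric(1))
  max(abs(Fa - Fb))
}

# Instrument characterization values used as generator ground truth.
DARK_MEAN <- 384460.71
DARK_SD <- 559.22
SOURCE_MEAN <- 24429585.36
TEMP_SLOPE <- 7704.504
TEMP_INTERCEPT <- 2.358e7
PLASMA_LINE <- c(intercept = 0.0382, slope = -0.02616)
WB_LINE <- c(intercept = 0.01363, slope = -0.00916)
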