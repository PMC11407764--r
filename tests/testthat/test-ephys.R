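# Field-potential sweep metrics, normalization and outcome classification.

test_that("sweep construction enforces the paired-pulse protocol", {
  expect_error(ephys_sweep(rnorm(100), 10000, stimulus_times_s = c(0.001, 0.004)),
               "50 ms")
  expect_error(ephys_sweep(rnorm(100), 10000, stimulus_times_s = 2),
               "within the sweep")
})

test_that("fiber-volley metrics recover a noiseless synthetic volley exactly", {
  g <- gen_sweep(noise_mV = 0)
  m <- fiber_volley_metrics(g$sweep)
  expect_false(m$missing)
  expect_equal(m$fv_amplitude_mV, g$ground_truth$fv$amplitude_mV,
               tolerance = 0.02)
  expect_equal(m$fv_hwhm_ms, g$ground_truth$fv$hwhm_ms, tolerance = 0.02)
  expect_equal(m$fv_delay_ms, g$ground_truth$fv$delay_ms, tolerance = 0.02)
})

test_that("fiber-volley metrics are stable under default generator noise", {
  errs <- t(vapply(1:20, function(i) {
    g <- gen_sweep(seed = 200 + i)
    m <- fiber_volley_metrics(g$sweep)
    c(m$fv_amplitude_mV / g$ground_truth$fv$amplitude_mV - 1,
      m$fv_hwhm_ms / g$ground_truth$fv$hwhm_ms - 1,
      m$fv_delay_ms / g$ground_truth$fv$delay_ms - 1)
  }, numeric(3)))
  expect_lt(max(abs(apply(errs, 2, stats::median))), 0.05)
})

test_that("a flat trace yields a missing fiber volley", {
  sw <- ephys_sweep(rnorm(2500, 0, 0.005), 10000)
  m <- fiber_volley_metrics(sw)
  expect_true(m$missing)
  expect_true(is.na(m$fv_amplitude_mV))
})

test_that("sweep metrics respect gain and offset invariances", {
  g <- gen_sweep(noise_mV = 0)
  sw2 <- g$sweep; sw2$voltage_mV <- 2 * sw2$voltage_mV
  sw3 <- g$sweep; sw3$voltage_mV <- sw3$voltage_mV + 1.7
  m1 <- fiber_volley_metrics(g$sweep)
  m2 <- fiber_volley_metrics(sw2)
  m3 <- fiber_volley_metrics(sw3)
  expect_equal(m2$fv_amplitude_mV, 2 * m1$fv_amplitude_mV, tolerance = 1e-9)
  expect_equal(m2$fv_hwhm_ms, m1$fv_hwhm_ms, tolerance = 1e-9)
  expect_equal(m2$fv_delay_ms, m1$fv_delay_ms, tolerance = 1e-9)
  expect_equal(m3$fv_amplitude_mV, m1$fv_amplitude_mV, tolerance = 1e-9)
  s1 <- fepsp_slope(g$sweep); s2 <- fepsp_slope(sw2); s3 <- fepsp_slope(sw3)
  expect_equal(s2$fepsp_slope_mV_per_ms, 2 * s1$fepsp_slope_mV_per_ms,
               tolerance = 1e-9)
  expect_equal(s3$fepsp_slope_mV_per_ms, s1$fepsp_slope_mV_per_ms,
               tolerance = 1e-9)
})

test_that("HWHM interpolation agrees with a 100x-oversampled crossing search", {
  g <- gen_sweep(noise_mV = 0)
  m <- fiber_volley_metrics(g$sweep)
  t0 <- g$sweep$stimulus_times_s[1]
  seg <- g$sweep$time_s >= t0 & g$sweep$time_s <= t0 + 3e-3
  ref <- brute_hwhm_ms(g$sweep$time_s[seg], g$sweep$voltage_mV[seg],
                       m$baseline_mV, NULL)
  expect_lt(abs(m$fv_hwhm_ms / ref - 1), 0.01)
})

test_that("an exact linear ramp gives its slope back", {
  fs <- 10000
  n <- 2500
  t <- (0:(n - 1)) / fs
  v <- numeric(n)
  t0 <- 0.02
  ramp <- t > t0 + 0.004 & t <= t0 + 0.004 + 0.0024
  v[ramp] <- -0.5 * (t[ramp] - (t0 + 0.004)) * 1e3  # -0.5 mV/ms down-ramp
  v[t > t0 + 0.004 + 0.0024] <- min(v)
  sw <- ephys_sweep(v, fs, stimulus_times_s = c(t0, t0 + 0.05))
  s <- fepsp_slope(sw)
  expect_false(s$low_confidence)
  expect_equal(s$fepsp_slope_mV_per_ms, 0.5, tolerance = 1e-6)
})

test_that("a flat trace yields zero slope with a low-confidence flag", {
  sw <- ephys_sweep(rep(0, 2500), 10000)
  s <- fepsp_slope(sw)
  expect_equal(s$fepsp_slope_mV_per_ms, 0)
  expect_true(s$low_confidence)
})

test_that("the measured alpha-function slope matches the analytic band slope", {
  g <- gen_sweep(noise_mV = 0)
  s <- fepsp_slope(g$sweep)
  expect_lt(abs(s$fepsp_slope_mV_per_ms /
                  g$ground_truth$fepsp_slope_mV_per_ms - 1), 0.05)
})

test_that("the paired-pulse ratio behaves and survives the generator round trip", {
  expect_equal(paired_pulse_ratio(1, 1)$ppr, 1)
  expect_equal(paired_pulse_ratio(0.4, 0.8)$ppr, 2)
  expect_true(paired_pulse_ratio(0, 1)$undefined)
  g <- gen_sweep(ppr = 1.5, seed = 5)
  s1 <- fepsp_slope(g$sweep, 1)
  s2 <- fepsp_slope(g$sweep, 2)
  pp <- paired_pulse_ratio(s1$fepsp_slope_mV_per_ms, s2$fepsp_slope_mV_per_ms)
  expect_equal(pp$ppr, 1.5, tolerance = 0.05)
})

test_that("baseline normalization fixes the baseline mean at exactly 1", {
  t <- seq(0, 3600, by = 20)
  const <- experiment_timeline(t, data.frame(fepsp_slope = rep(0.5, length(t))))
  n1 <- normalize_to_baseline(const)
  expect_equal(n1$metrics$fepsp_slope, rep(1, length(t)))
  stepped <- experiment_timeline(
    t, data.frame(fepsp_slope = ifelse(t <= 600, 0.5, 1.0)))
  n2 <- normalize_to_baseline(stepped)
  bl <- t <= 600
  expect_equal(mean(n2$metrics$fepsp_slope[bl]), 1, tolerance = 1e-12)
  expect_equal(n2$metrics$fepsp_slope[!bl], rep(2, sum(!bl)))
  short <- experiment_timeline(t[1:40], data.frame(fepsp_slope = rep(1, 40)),
                               baseline_epoch_s = c(0, 100))
  expect_error(normalize_to_baseline(short), "at least 10")
  zero <- experiment_timeline(t, data.frame(fepsp_slope = rep(0, length(t))))
  expect_error(normalize_to_baseline(zero), "zero or non-finite")
})

test_that("a programmed late potentiation is recovered by the end-epoch mean", {
  g <- gen_experiment("ischemia", potentiation = 1.3, seed = 42)
  nt <- normalize_to_baseline(g$timeline)
  out <- classify_outcome(nt)
  expect_equal(out$end_ratios[["fepsp_slope"]], 1.3, tolerance = 0.05)
  expect_identical(out$classification, "recovered")
})

test_that("the outcome rule is a strict threshold on the end-epoch mean", {
  t <- seq(0, 3600, by = 20)
  mk <- function(end_level) {
    tl <- experiment_timeline(
      t, data.frame(fepsp_slope = ifelse(t <= 600, 1, end_level)))
    classify_outcome(normalize_to_baseline(tl))
  }
  expect_identical(mk(0.05)$classification, "failure")
  expect_identical(mk(1.2)$classification, "recovered")
  expect_identical(mk(0.5)$classification, "failure")   # boundary: not above
  expect_identical(mk(0.5000001)$classification, "recovered")
})

test_that("the classifier reproduces the generating scenario on every seed", {
  for (scenario in c("control", "ischemia", "ischemia_failure")) {
    for (seed in 1:20) {
      g <- gen_experiment(scenario, seed = seed)
      out <- classify_outcome(normalize_to_baseline(g$timeline))
      expect_identical(out$classification, g$ground_truth$expected_outcome)
      if (scenario == "ischemia_failure") {
        # the fiber volley recovers even though the fEPSP fails
        expect_gt(out$end_ratios[["fv_amplitude"]], 0.9)
      }
    }
  }
})
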