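# iGluSnFR line-scan processing: dF/F0, decay kinetics, paired pulses.

test_that("averaging repeats is the element-wise mean and shrinks noise", {
  g <- gen_linescan(n_repeats = 4, seed = 1)
  avg <- average_repeats(g$scans)
  expect_equal(avg$n_averaged, 4L)
  expect_equal(avg$fluorescence,
               (g$scans[[1]]$fluorescence + g$scans[[2]]$fluorescence +
                  g$scans[[3]]$fluorescence + g$scans[[4]]$fluorescence) / 4)
  one <- average_repeats(g$scans[1])
  expect_equal(one$n_averaged, 1L)
  expect_equal(one$fluorescence, g$scans[[1]]$fluorescence)
  # residual s.d. around the known truth shrinks ~ 1/sqrt(n)
  resid_sd <- function(scan) {
    tr <- compute_dff(scan)
    stats::sd(tr$dff - g$ground_truth$dff_true)
  }
  expect_lt(resid_sd(avg), 0.7 * resid_sd(g$scans[[1]]))
  bad <- g$scans
  bad[[2]]$fluorescence <- bad[[2]]$fluorescence[, 1:10]
  expect_error(average_repeats(bad), "shapes differ")
})

test_that("dF/F0 is zero for constant signal and one for a doubling step", {
  nt <- 200
  m <- matrix(20, 32, nt)
  m[1:16, ] <- 20 + 100
  sc <- line_scan(m, 378.8, roi = c(1, 16), background_roi = c(17, 32),
                  stimulus_times_s = 0.3)
  tr <- compute_dff(sc)
  expect_equal(tr$f0, 100)
  expect_equal(tr$dff, rep(0, nt))
  m2 <- m
  step_cols <- 150:nt
  m2[1:16, step_cols] <- 20 + 200
  tr2 <- compute_dff(line_scan(m2, 378.8, c(1, 16), c(17, 32), 0.3))
  expect_equal(max(tr2$dff), 1, tolerance = 1e-12)
})

test_that("a scan whose indicator signal vanishes is rejected", {
  m <- matrix(20, 32, 100)  # signal rows equal background rows
  sc <- line_scan(m, 378.8, c(1, 16), c(17, 32), 0.1)
  expect_error(compute_dff(sc), "unusable")
})

test_that("programmed peaks are recovered from generated scans", {
  g <- gen_linescan(peak_dff = c(0.30, 0.42), seed = 3)
  tr <- compute_dff(average_repeats(g$scans))
  expect_lt(abs(tr$peak_amplitudes[1] - 0.30), 0.02)
  g0 <- gen_linescan(peak_dff = c(0.30, 0.42), noise_sd = 0, seed = 4)
  tr0 <- compute_dff(average_repeats(g0$scans))
  expect_equal(tr0$peak_amplitudes[1], 0.30, tolerance = 1e-9)
})

test_that("dF/F0 is invariant to gain when the background is zero", {
  g <- gen_linescan(background = 0, noise_sd = 0, seed = 5)
  sc <- average_repeats(g$scans)
  sc2 <- sc; sc2$fluorescence <- 3.7 * sc2$fluorescence
  expect_equal(compute_dff(sc2)$dff, compute_dff(sc)$dff, tolerance = 1e-12)
})

test_that("a noiseless mono-exponential decay is recovered to 1e-6", {
  g <- gen_linescan(peak_dff = 0.3, stimulus_times_s = 0.25,
                    tau_ms = 40, noise_sd = 0, seed = 6)
  tr <- compute_dff(average_repeats(g$scans))
  d <- fit_decay(tr, pulse_index = 1)
  expect_true(d$converged)
  expect_equal(d$tau_ms, 40, tolerance = 1e-6)
})

test_that("decay recovery holds at default noise and across the TBOA-like factor", {
  g <- gen_linescan(tau_ms = 40, seed = 7)
  d <- fit_decay(compute_dff(average_repeats(g$scans)))
  expect_true(d$converged)
  expect_equal(d$tau_ms, 40, tolerance = 0.05 * 40)
  # uptake block multiplies the decay constant ~15-fold
  gs <- gen_linescan(peak_dff = 0.3, stimulus_times_s = 0.25, tau_ms = 40,
                     duration_s = 1, seed = 8)
  gb <- gen_linescan(peak_dff = 0.3, stimulus_times_s = 0.25, tau_ms = 600,
                     duration_s = 5, seed = 9)
  d1 <- fit_decay(compute_dff(average_repeats(gs$scans)), 1)
  d2 <- fit_decay(compute_dff(average_repeats(gb$scans)), 1,
                  fit_window_ms = 3000)
  expect_equal(d2$tau_ms / d1$tau_ms, 15, tolerance = 1.5)
})

test_that("decay-constant recovery is unbiased across the physiological range", {
  for (tau in c(20, 40, 400)) {
    rel <- vapply(1:50, function(i) {
      g <- gen_linescan(peak_dff = 0.3, stimulus_times_s = 0.25,
                        tau_ms = tau, duration_s = max(1, tau / 100),
                        seed = 3000 + i)
      d <- fit_decay(compute_dff(average_repeats(g$scans)), 1,
                     fit_window_ms = max(500, 5 * tau))
      d$tau_ms / tau - 1
    }, numeric(1))
    expect_lt(abs(stats::median(rel)), 0.02)
  }
})

test_that("transient PPR subtracts the pulse-1 tail and recovers the truth", {
  g <- gen_linescan(peak_dff = c(0.30, 0.42), tau_ms = 40, seed = 10)
  tr <- compute_dff(average_repeats(g$scans))
  pp <- transient_ppr(tr)
  expect_false(pp$undefined)
  expect_equal(pp$ppr, 1.4, tolerance = 0.05 * 1.4)
  # equal noiseless pulses give a corrected ratio of 1
  ge <- gen_linescan(peak_dff = c(0.30, 0.30), noise_sd = 0, seed = 11)
  ppe <- transient_ppr(compute_dff(average_repeats(ge$scans)))
  expect_equal(ppe$ppr, 1, tolerance = 0.02)
  # without the correction the second peak carries pulse 1's predicted tail
  pp_raw <- transient_ppr(compute_dff(average_repeats(ge$scans)),
                          subtract_residual = FALSE)
  gt <- ge$ground_truth
  dt_ms <- diff(gt$stimulus_times_s) * 1e3
  predicted_tail <- 0.30 * exp(-dt_ms / gt$tau_ms)
  expect_equal(pp_raw$ppr - ppe$ppr, predicted_tail / 0.30,
               tolerance = 0.03)
})

test_that("bleaching lowers F0 but leaves the normalized peak unchanged", {
  # construction property, exact without noise
  c1 <- compute_dff(average_repeats(
    gen_linescan(bleach_factor = 1, noise_sd = 0, seed = 12)$scans))
  c2 <- compute_dff(average_repeats(
    gen_linescan(bleach_factor = 0.6, noise_sd = 0, seed = 12)$scans))
  expect_equal(c2$f0 / c1$f0, 0.6, tolerance = 1e-9)
  expect_equal(c2$peak_amplitudes, c1$peak_amplitudes, tolerance = 1e-9)
  # at default noise the median peak shift across seeds stays within 2%
  rel <- vapply(1:5, function(i) {
    t1 <- compute_dff(average_repeats(
      gen_linescan(bleach_factor = 1, seed = 500 + i)$scans))
    t2 <- compute_dff(average_repeats(
      gen_linescan(bleach_factor = 0.6, seed = 600 + i)$scans))
    t2$peak_amplitudes[1] / t1$peak_amplitudes[1] - 1
  }, numeric(1))
  expect_lt(abs(stats::median(rel)), 0.02)
})
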