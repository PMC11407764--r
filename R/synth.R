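# Seeded synthetic-data generators.
#
# Each generator emulates one recording modality with the statistical
# structure its analysis stage assumes, and always returns the exact ground
# truth next to the data, so every analyzer can be validated by a
# generate-analyze round trip without any experimental data. Scenario
# effect magnitudes (potentiation factor, failure residual, K+ peaks) are
# configuration defaults chosen well inside the classifier margins; they
# are not claims about experimental effect sizes. Identical arguments and
# seed give bit-identical output; the caller's RNG state is preserved.

.seed_in <- function(seed) {
  if (is.null(seed)) return(NULL)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  old
}
.seed_out <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Synthetic electrode calibration points
#'
#' Voltages from the forward calibration model plus additive Gaussian
#' noise.
#'
#' @param E0_mV,slope_mV_per_decade,c_interference_mM Ground-truth
#'   calibration parameters (Nicolsky-Eisenman; zero interference gives
#'   Nernst).
#' @param concentrations_mM Standard concentrations (>= 2).
#' @param noise_mV Gaussian noise s.d. (mV, default 0.5; 0 gives exact
#'   forward values).
#' @param seed RNG seed.
#' @return List: `points` (a [calibration_points()]), `ground_truth`.
#' @export
gen_calibration_points <- function(E0_mV = 0, slope_mV_per_decade = 61,
                                   c_interference_mM = 0,
                                   concentrations_mM = c(0.1, 0.3, 1, 3, 10, 30),
                                   noise_mV = 0.5, seed = NULL) {
  stopifnot(length(concentrations_mM) >= 2, noise_mV >= 0)
  old <- .seed_in(seed); on.exit(.seed_out(old))
  truth <- list(E0_mV = E0_mV, slope_mV_per_decade = slope_mV_per_decade,
                c_interference_mM = c_interference_mM)
  v <- concentration_to_voltage(concentrations_mM, truth) +
    stats::rnorm(length(concentrations_mM), 0, noise_mV)
  list(points = calibration_points(concentrations_mM, v),
       ground_truth = c(truth, list(noise_mV = noise_mV, seed = seed)))
}

#' Named tissue scenarios for the RTI generator
#'
#' `"slice_like"` uses the acute-slice validation values (volume fraction
#' 0.19, tortuosity 1.54); `"free_medium"` emulates an agarose-gel control
#' (volume fraction ~1, tortuosity ~1).
#'
#' @param scenario `"slice_like"` or `"free_medium"`.
#' @param D_free_cm2_s Free-medium TMA diffusion coefficient.
#' @return A [tissue_params()].
#' @export
tissue_scenario <- function(scenario = c("slice_like", "free_medium"),
                            D_free_cm2_s = 1.31e-5) {
  scenario <- match.arg(scenario)
  switch(scenario,
         slice_like = tissue_params(0.19, D_free_cm2_s / 1.54^2,
                                    D_free_cm2_s = D_free_cm2_s),
         free_medium = tissue_params(1, D_free_cm2_s,
                                     D_free_cm2_s = D_free_cm2_s))
}

#' Synthetic TMA iontophoresis transient
#'
#' Forward RTI trace plus multiplicative Gaussian noise, recorded as an
#' absolute curve on a bath baseline.
#'
#' @param tissue A [tissue_params()] ground truth (see [tissue_scenario()]).
#' @param source An [rti_source()] (default 100 nA x 30 s, transport
#'   number 0.3).
#' @param distance_um Source-electrode distance (default 150 um).
#' @param noise_frac Multiplicative noise s.d. (default 0.02).
#' @param t_end_s,dt_s Time grid (default 90 s at 0.25 s).
#' @param baseline_mM Bath TMA concentration (default 1 mM).
#' @param seed RNG seed.
#' @return List: `curve` (a [tma_curve()], kind `"absolute"`),
#'   `ground_truth`.
#' @export
gen_tma_curve <- function(tissue, source = rti_source(), distance_um = 150,
                          noise_frac = 0.02, t_end_s = 90, dt_s = 0.25,
                          baseline_mM = 1, seed = NULL) {
  stopifnot(inherits(tissue, "tissue_params"), noise_frac >= 0)
  old <- .seed_in(seed); on.exit(.seed_out(old))
  tt <- seq(dt_s, t_end_s, by = dt_s)
  clean <- rti_forward(tt, distance_um, source, tissue)
  noisy <- clean * (1 + stats::rnorm(length(clean), 0, noise_frac))
  curve <- tma_curve(tt, noisy + baseline_mM, distance_um, source,
                     baseline_mM = baseline_mM, kind = "absolute")
  list(curve = curve,
       ground_truth = list(alpha = tissue$alpha,
                           D_star_cm2_s = tissue$D_star_cm2_s,
                           lambda = tissue$lambda,
                           k_prime_per_s = tissue$k_prime_per_s,
                           D_free_cm2_s = tissue$D_free_cm2_s,
                           noise_frac = noise_frac, seed = seed))
}

# alpha-function EPSP shape (positive-going unit peak at t = tau after
# onset); zero before onset
.alpha_fn <- function(t, onset, tau) {
  u <- (t - onset) / tau
  ifelse(u > 0, u * exp(1 - u), 0)
}

#' Synthetic paired-pulse field-potential sweep
#'
#' Sum of a fast biphasic stimulus artifact, a Gaussian fiber-volley trough
#' and an alpha-function fEPSP per pulse (pulse 2 scaled by the paired-
#' pulse ratio), plus additive Gaussian noise. Component timings must be
#' ordered artifact < fiber volley < fEPSP onset.
#'
#' @param fv List: `amplitude_mV`, `hwhm_ms`, `delay_ms` (trough delay
#'   after the stimulus).
#' @param fepsp List: `amplitude_mV`, `tau_ms` (alpha-function time
#'   constant), `onset_ms` (after the stimulus).
#' @param ppr Paired-pulse ratio applied to the pulse-2 fEPSP amplitude.
#' @param artifact List: `amplitude_mV`, `width_ms`.
#' @param noise_mV Additive Gaussian noise s.d. (default 0.01).
#' @param sampling_rate_hz Default 10000.
#' @param stimulus_times_s Default c(0.02, 0.07).
#' @param duration_s Sweep length (default 0.25 s).
#' @param seed RNG seed.
#' @return List: `sweep` (an [ephys_sweep()]) and `ground_truth`, which
#'   includes the analytic fEPSP slope over the default 20-80% rising-phase
#'   band (`fepsp_slope_mV_per_ms`, from dense evaluation of the alpha
#'   function).
#' @export
gen_sweep <- function(fv = list(amplitude_mV = 0.4, hwhm_ms = 0.6,
                                delay_ms = 1.2),
                      fepsp = list(amplitude_mV = 1.2, tau_ms = 3,
                                   onset_ms = 3),
                      ppr = 1.5,
                      artifact = list(amplitude_mV = 3, width_ms = 0.1),
                      noise_mV = 0.01, sampling_rate_hz = 10000,
                      stimulus_times_s = c(0.02, 0.07), duration_s = 0.25,
                      seed = NULL) {
  if (!(artifact$width_ms < fv$delay_ms && fv$delay_ms < fepsp$onset_ms))
    stop("component timings must be ordered artifact < fiber volley < fEPSP")
  old <- .seed_in(seed); on.exit(.seed_out(old))
  n <- round(duration_s * sampling_rate_hz)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  v <- numeric(n)
  sigma_fv <- fv$hwhm_ms * 1e-3 / (2 * sqrt(2 * log(2)))
  for (k in seq_along(stimulus_times_s)) {
    t0 <- stimulus_times_s[k]
    scale_epsp <- if (k == 2) ppr else 1
    u <- (t - t0) / (artifact$width_ms * 1e-3)
    v <- v + artifact$amplitude_mV * u * exp(-u^2) * (u > 0)
    v <- v - fv$amplitude_mV *
      exp(-((t - t0 - fv$delay_ms * 1e-3)^2) / (2 * sigma_fv^2))
    v <- v - scale_epsp * fepsp$amplitude_mV *
      .alpha_fn(t, t0 + fepsp$onset_ms * 1e-3, fepsp$tau_ms * 1e-3)
  }
  v <- v + stats::rnorm(n, 0, noise_mV)
  sw <- ephys_sweep(v, sampling_rate_hz, stimulus_times_s)
  # analytic fEPSP slope over the 20-80% band, by dense evaluation
  td <- seq(0, 6 * fepsp$tau_ms * 1e-3, by = 1e-7)
  shape <- -fepsp$amplitude_mV * .alpha_fn(td, 0, fepsp$tau_ms * 1e-3)
  ipk <- which.min(shape)
  amp <- -shape[ipk]
  band <- which(shape[1:ipk] <= -0.2 * amp & shape[1:ipk] >= -0.8 * amp)
  sl <- stats::lm.fit(cbind(1, td[band] * 1e3), shape[band])$coefficients[[2]]
  list(sweep = sw,
       ground_truth = list(
         fv = fv, fepsp = fepsp, ppr = ppr, artifact = artifact,
         noise_mV = noise_mV,
         fepsp_slope_mV_per_ms = abs(sl), seed = seed))
}

#' Synthetic extracellular K+ transient
#'
#' A smooth rise/decay concentration transient confined to the insult
#' window on a flat baseline, plus additive Gaussian noise. Optionally also
#' returns the voltage-domain trace seen by a calibrated electrode.
#'
#' @param baseline_mM Resting extracellular K+ (default 3 mM).
#' @param peak_delta_mM Peak increase above baseline (mM).
#' @param window_s Insult window `c(start, end)` (s).
#' @param duration_s Trace length (s).
#' @param rise_s,decay_s Rise and decay time constants (s).
#' @param noise_mM Additive noise s.d. (default 0.05).
#' @param dt_s Sample interval (default 1 s).
#' @param cal Optional electrode calibration; if given, a voltage-domain
#'   `ion_trace` generated through the forward calibration model is
#'   returned as `voltage_trace`.
#' @param seed RNG seed.
#' @return List: `trace` (concentration [ion_trace()]), `voltage_trace`
#'   (or NULL), `ground_truth`.
#' @export
gen_k_trace <- function(baseline_mM = 3, peak_delta_mM = 8,
                        window_s = c(900, 1200), duration_s = 3600,
                        rise_s = 30, decay_s = 45, noise_mM = 0.05,
                        dt_s = 1, cal = NULL, seed = NULL) {
  stopifnot(window_s[1] > 0, window_s[2] > window_s[1],
            window_s[2] < duration_s)
  old <- .seed_in(seed); on.exit(.seed_out(old))
  t <- seq(0, duration_s, by = dt_s)
  delta <- numeric(length(t))
  in_win <- t >= window_s[1] & t <= window_s[2]
  delta[in_win] <- peak_delta_mM * (1 - exp(-(t[in_win] - window_s[1]) / rise_s))
  at_end <- peak_delta_mM * (1 - exp(-diff(window_s) / rise_s))
  post <- t > window_s[2]
  delta[post] <- at_end * exp(-(t[post] - window_s[2]) / decay_s)
  conc <- baseline_mM + delta + stats::rnorm(length(t), 0, noise_mM)
  trace <- ion_trace(t, conc, kind = "concentration",
                     ischemia_window_s = window_s)
  vtrace <- NULL
  if (!is.null(cal))
    vtrace <- ion_trace(t, concentration_to_voltage(pmax(conc, 1e-6), cal),
                        kind = "voltage", ischemia_window_s = window_s)
  list(trace = trace, voltage_trace = vtrace,
       ground_truth = list(baseline_mM = baseline_mM,
                           peak_delta_mM = peak_delta_mM,
                           achieved_peak_mM = at_end, window_s = window_s,
                           rise_s = rise_s, decay_s = decay_s,
                           noise_mM = noise_mM, seed = seed))
}

# scenario template for the normalized fEPSP / fiber-volley courses
.experiment_template <- function(time_s, scenario, isch_win_s,
                                 potentiation, failure_residual,
                                 recovery_tau_s, potentiation_tau_s) {
  fepsp <- rep(1, length(time_s))
  fv <- rep(1, length(time_s))
  if (scenario == "control")
    return(list(fepsp = fepsp, fv = fv))
  during <- time_s >= isch_win_s[1] & time_s < isch_win_s[2] + 60
  after <- time_s >= isch_win_s[2] + 60
  t_rec <- time_s - (isch_win_s[2] + 60)
  # both signals collapse during the insult (plus ~1 min washout lag)
  fepsp[during] <- 0.02
  fv[during] <- 0.05
  fv[after] <- 1 - 0.95 * exp(-t_rec[after] / recovery_tau_s)
  if (scenario == "ischemia") {
    # recovery overshooting into lasting potentiation
    target <- potentiation
    fepsp[after] <- target + (0.02 - target) * exp(-t_rec[after] / potentiation_tau_s)
  } else {
    fepsp[after] <- failure_residual +
      (0.02 - failure_residual) * exp(-t_rec[after] / recovery_tau_s)
  }
  list(fepsp = fepsp, fv = fv)
}

#' Synthetic chemical-ischemia experiment
#'
#' Generates an experiment timeline (one sweep every `sweep_interval_s`)
#' whose per-sweep fEPSP-slope and fiber-volley metrics follow a scenario
#' template plus multiplicative noise, together with a matching
#' extracellular K+ trace peaking inside the insult window. Scenarios:
#' `"control"` (stable), `"ischemia"` (transient suppression, full
#' fiber-volley recovery, lasting fEPSP potentiation) and
#' `"ischemia_failure"` (fiber volley recovers, fEPSP pinned near zero);
#' the failure scenario carries a larger K+ surge.
#'
#' @param scenario One of `"control"`, `"ischemia"`, `"ischemia_failure"`.
#' @param duration_min Recording length (default 60 min).
#' @param ischemia_start_min Insult onset (default 15 min).
#' @param ischemia_duration_min Insult duration, 2-5 min (default 2 for
#'   `"ischemia"`, 5 for `"ischemia_failure"`).
#' @param sweep_interval_s One sweep per this interval (default 20 s).
#' @param baseline_fepsp_slope_mV_per_ms,baseline_fv_amplitude_mV Baseline
#'   metric levels.
#' @param potentiation Late fEPSP level of the `"ischemia"` scenario
#'   relative to baseline (default 1.3).
#' @param failure_residual Late fEPSP level of the failure scenario
#'   (default 0.05).
#' @param noise_frac Per-sweep multiplicative noise s.d. (default 0.03).
#' @param k_peak_mM Peak K+ increase (default 5 mM; 10 mM for failure).
#' @param seed RNG seed.
#' @return List: `timeline` (an [experiment_timeline()] with metrics
#'   `fepsp_slope` and `fv_amplitude`), `k_trace` (an [ion_trace()]),
#'   `ground_truth` (scenario, template levels, expected outcome label).
#' @export
gen_experiment <- function(scenario = c("control", "ischemia",
                                        "ischemia_failure"),
                           duration_min = 60, ischemia_start_min = 15,
                           ischemia_duration_min = NULL,
                           sweep_interval_s = 20,
                           baseline_fepsp_slope_mV_per_ms = 0.5,
                           baseline_fv_amplitude_mV = 0.4,
                           potentiation = 1.3, failure_residual = 0.05,
                           noise_frac = 0.03, k_peak_mM = NULL,
                           seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(ischemia_duration_min))
    ischemia_duration_min <- if (scenario == "ischemia_failure") 5 else 2
  if (ischemia_duration_min < 2 || ischemia_duration_min > 5)
    stop("ischemia duration must be within 2-5 min")
  if (is.null(k_peak_mM))
    k_peak_mM <- switch(scenario, control = 0, ischemia = 5,
                        ischemia_failure = 10)
  old <- .seed_in(seed); on.exit(.seed_out(old))
  time_s <- seq(0, duration_min * 60, by = sweep_interval_s)
  isch_win <- c(ischemia_start_min, ischemia_start_min +
                  ischemia_duration_min) * 60
  tmpl <- .experiment_template(time_s, scenario, isch_win,
                               potentiation, failure_residual,
                               recovery_tau_s = 180,
                               potentiation_tau_s = 420)
  noise <- function(n) 1 + stats::rnorm(n, 0, noise_frac)
  metrics <- data.frame(
    fepsp_slope = baseline_fepsp_slope_mV_per_ms * tmpl$fepsp *
      noise(length(time_s)),
    fv_amplitude = baseline_fv_amplitude_mV * tmpl$fv *
      noise(length(time_s))
  )
  timeline <- experiment_timeline(
    time_s, metrics, baseline_epoch_s = c(0, 600),
    end_epoch_s = c(max(time_s) - 600, max(time_s)),
    ischemia_window_s = if (scenario == "control") NULL else isch_win)
  kt <- if (k_peak_mM > 0)
    gen_k_trace(peak_delta_mM = k_peak_mM, window_s = isch_win,
                duration_s = duration_min * 60, seed = NULL)$trace
  else
    ion_trace(time_s, 3 + stats::rnorm(length(time_s), 0, 0.05),
              kind = "concentration")
  list(timeline = timeline, k_trace = kt,
       ground_truth = list(
         scenario = scenario,
         expected_outcome = if (scenario == "ischemia_failure") "failure"
         else "recovered",
         ischemia_window_s = if (scenario == "control") NULL else isch_win,
         potentiation = potentiation, failure_residual = failure_residual,
         k_peak_mM = k_peak_mM, noise_frac = noise_frac, seed = seed))
}

#' Synthetic iGluSnFR line scans
#'
#' Repeated position x time arrays: signal-ROI rows carry
#' `background + F0 * bleach * (1 + dff(t))` where `dff(t)` is a sum of
#' stimulus-locked transients with instantaneous rise and mono-exponential
#' decay; background rows carry the background level alone; every pixel
#' receives Gaussian noise. Stimulus times are aligned to the scan grid so
#' the programmed peak is sampled exactly.
#'
#' @param peak_dff Per-pulse peak amplitudes (dF/F0 units; default
#'   c(0.30, 0.42)).
#' @param tau_ms Decay time constant (default 40 ms).
#' @param f0 Resting indicator fluorescence of the ROI (a.u., default 100).
#' @param bleach_factor Multiplicative resting-fluorescence factor for this
#'   time point (default 1; < 1 emulates the slow decline over an
#'   experiment).
#' @param background Background fluorescence level (a.u., default 20).
#' @param noise_sd Per-pixel Gaussian noise s.d. (a.u., default 4).
#' @param n_repeats Number of repeated scans (default 5; 4-6 typical).
#' @param scan_rate_hz Default 378.8.
#' @param duration_s Scan length (default 1 s).
#' @param stimulus_times_s Stimulus onsets (default c(0.25, 0.30), snapped
#'   to the scan grid).
#' @param n_positions Rows of the array (default 64).
#' @param roi,background_roi Row ranges (defaults c(5, 40) and c(49, 64)).
#' @param seed RNG seed.
#' @return List: `scans` (list of [line_scan()]), `ground_truth`.
#' @export
gen_linescan <- function(peak_dff = c(0.30, 0.42), tau_ms = 40, f0 = 100,
                         bleach_factor = 1, background = 20, noise_sd = 4,
                         n_repeats = 5, scan_rate_hz = 378.8,
                         duration_s = 1, stimulus_times_s = c(0.25, 0.30),
                         n_positions = 64, roi = c(5, 40),
                         background_roi = c(49, 64), seed = NULL) {
  stopifnot(tau_ms > 0, f0 > 0, bleach_factor > 0, n_repeats >= 1)
  old <- .seed_in(seed); on.exit(.seed_out(old))
  nt <- round(duration_s * scan_rate_hz)
  t <- (seq_len(nt) - 1) / scan_rate_hz
  stim <- t[pmax(1, round(stimulus_times_s * scan_rate_hz) + 1)]
  dff <- numeric(nt)
  for (k in seq_along(stim)) {
    on <- t >= stim[k] - 1e-12
    dff[on] <- dff[on] + peak_dff[k] * exp(-(t[on] - stim[k]) / (tau_ms * 1e-3))
  }
  roi_rows <- roi[1]:roi[2]
  scans <- lapply(seq_len(n_repeats), function(i) {
    m <- matrix(background, nrow = n_positions, ncol = nt)
    m[roi_rows, ] <- background +
      matrix(f0 * bleach_factor * (1 + dff), nrow = length(roi_rows),
             ncol = nt, byrow = TRUE)
    m <- m + matrix(stats::rnorm(n_positions * nt, 0, noise_sd),
                    n_positions, nt)
    line_scan(m, scan_rate_hz, roi, background_roi, stim)
  })
  list(scans = scans,
       ground_truth = list(peak_dff = peak_dff, tau_ms = tau_ms, f0 = f0,
                           bleach_factor = bleach_factor,
                           background = background, noise_sd = noise_sd,
                           n_repeats = n_repeats,
                           stimulus_times_s = stim, dff_true = dff,
                           seed = seed))
}
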