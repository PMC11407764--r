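# Extracellular field-potential sweep analysis.
#
# A sweep is a single paired-pulse extracellular recording: stimulus
# artifact, presynaptic fiber volley (FV, a fast negative deflection) and
# field EPSP (a slower negative deflection whose initial slope indexes
# synaptic strength). Metrics are extracted per pulse; experiment timelines
# normalize metrics to a baseline epoch and classify the post-insult
# outcome by the recovery of the normalized fEPSP slope.

#' Extracellular field-potential sweep
#'
#' @param voltage_mV Voltage samples (mV).
#' @param sampling_rate_hz Sampling rate (Hz, default 10000).
#' @param stimulus_times_s Stimulus onsets (s from sweep start); two onsets
#'   50 ms apart for the paired-pulse protocol.
#' @param artifact_blank_ms Per-stimulus blanking interval (ms, default
#'   0.5): samples within it are excluded from analysis.
#' @param isi_s Expected inter-stimulus interval for a paired-pulse sweep
#'   (s, default 0.05); checked when exactly two stimuli are given.
#' @return An object of class `ephys_sweep`.
#' @export
ephys_sweep <- function(voltage_mV, sampling_rate_hz = 10000,
                  stimulus_times_s = c(0.01, 0.06),
                  artifact_blank_ms = 0.5, isi_s = 0.05) {
  stopifnot(sampling_rate_hz > 0, length(voltage_mV) > 1,
            artifact_blank_ms >= 0)
  dur <- length(voltage_mV) / sampling_rate_hz
  if (any(stimulus_times_s < 0) || any(stimulus_times_s >= dur))
    stop("stimulus times must lie within the sweep")
  if (length(stimulus_times_s) == 2 &&
      abs(diff(stimulus_times_s) - isi_s) > 1e-9)
    stop("paired-pulse sweep requires stimulus separation of ",
         isi_s * 1e3, " ms")
  x <- list(voltage_mV = as.numeric(voltage_mV),
            sampling_rate_hz = sampling_rate_hz,
            time_s = (seq_along(voltage_mV) - 1) / sampling_rate_hz,
            stimulus_times_s = stimulus_times_s,
            artifact_blank_ms = artifact_blank_ms)
  class(x) <- "ephys_sweep"
  x
}

# pre-stimulus baseline samples for a pulse (window before the FIRST
# stimulus, so pulse 2 inherits a clean baseline)
.sweep_baseline <- function(sw, baseline_ms = 5) {
  t0 <- sw$stimulus_times_s[1]
  idx <- sw$time_s >= (t0 - baseline_ms * 1e-3) & sw$time_s < t0
  if (!any(idx)) idx <- sw$time_s < t0
  sw$voltage_mV[idx]
}

# linear interpolation of the time where the trace crosses `level`,
# scanning from index `from` in direction `dir` (+1/-1)
.cross_time <- function(time_s, v, level, from, dir) {
  i <- from
  n <- length(v)
  while (i + dir >= 1 && i + dir <= n) {
    j <- i + dir
    if ((v[i] - level) * (v[j] - level) <= 0 && v[i] != v[j]) {
      f <- (level - v[i]) / (v[j] - v[i])
      return(time_s[i] + f * (time_s[j] - time_s[i]))
    }
    i <- j
  }
  NA_real_
}

#' Fiber-volley metrics of one pulse
#'
#' Detects the fiber volley as the first negative deflection inside the
#' search window after the stimulus (artifact blanked) and measures its
#' amplitude (baseline-to-trough, positive mV), half width at half maximum
#' (linear interpolation at the half-amplitude crossings, ms) and delay
#' (stimulus onset to trough, ms). If no deflection exceeds the noise floor
#' (3 x MAD of the pre-stimulus baseline), the metrics are flagged missing.
#'
#' @param sw An [ephys_sweep()].
#' @param pulse_index Which stimulus (default 1).
#' @param search_window_ms Post-stimulus search window (ms, default
#'   c(0.5, 3)); the lower edge should not precede the artifact blank.
#' @param baseline_ms Pre-stimulus baseline length (ms, default 5).
#' @return List: `fv_amplitude_mV`, `fv_hwhm_ms`, `fv_delay_ms`,
#'   `missing` (logical), `baseline_mV`.
#' @export
fiber_volley_metrics <- function(sw, pulse_index = 1,
                                 search_window_ms = c(0.5, 3),
                                 baseline_ms = 5) {
  stopifnot(inherits(sw, "ephys_sweep"),
            pulse_index %in% seq_along(sw$stimulus_times_s))
  t0 <- sw$stimulus_times_s[pulse_index]
  lo <- max(search_window_ms[1], sw$artifact_blank_ms)
  win <- sw$time_s >= t0 + lo * 1e-3 &
    sw$time_s <= t0 + search_window_ms[2] * 1e-3
  if (!any(win)) stop("empty fiber-volley search window")
  base <- .sweep_baseline(sw, baseline_ms)
  b0 <- mean(base)
  noise <- stats::mad(base)
  v <- sw$voltage_mV
  idx_win <- which(win)
  trough_rel <- which.min(v[idx_win])
  trough <- idx_win[trough_rel]
  amp <- b0 - v[trough]
  if (amp <= 3 * noise || amp <= 0) {
    return(list(fv_amplitude_mV = NA_real_, fv_hwhm_ms = NA_real_,
                fv_delay_ms = NA_real_, missing = TRUE, baseline_mV = b0))
  }
  half <- b0 - amp / 2
  t_left <- .cross_time(sw$time_s, v, half, trough, -1L)
  t_right <- .cross_time(sw$time_s, v, half, trough, +1L)
  hwhm <- if (is.na(t_left) || is.na(t_right)) NA_real_ else
    (t_right - t_left) * 1e3
  list(fv_amplitude_mV = amp,
       fv_hwhm_ms = hwhm,
       fv_delay_ms = (sw$time_s[trough] - t0) * 1e3,
       missing = FALSE, baseline_mV = b0)
}

#' Initial slope of the field EPSP
#'
#' Fits a straight line to the rising (negative-going) phase of the fEPSP
#' of one pulse, over the samples between `fit_fraction_range` of the
#' baseline-to-peak amplitude (default 20-80%). The magnitude of the
#' negative slope is reported positive, in mV/ms. A trace whose deflection
#' stays within the noise floor returns slope 0 with `low_confidence =
#' TRUE`.
#'
#' @param sw An [ephys_sweep()].
#' @param pulse_index Which stimulus (default 1).
#' @param epsp_window_ms Post-stimulus window containing the fEPSP peak
#'   (ms, default c(3, 15); should start after the fiber volley).
#' @param fit_fraction_range Amplitude fractions delimiting the fitted
#'   rising-phase samples (default c(0.2, 0.8)).
#' @param baseline_ms Pre-stimulus baseline length (ms).
#' @return List: `fepsp_slope_mV_per_ms`, `amplitude_mV`, `n_fit`,
#'   `low_confidence`.
#' @export
fepsp_slope <- function(sw, pulse_index = 1, epsp_window_ms = c(3, 15),
                        fit_fraction_range = c(0.2, 0.8), baseline_ms = 5) {
  stopifnot(inherits(sw, "ephys_sweep"),
            pulse_index %in% seq_along(sw$stimulus_times_s),
            fit_fraction_range[1] < fit_fraction_range[2])
  t0 <- sw$stimulus_times_s[pulse_index]
  win <- sw$time_s >= t0 + epsp_window_ms[1] * 1e-3 &
    sw$time_s <= t0 + epsp_window_ms[2] * 1e-3
  if (!any(win)) stop("empty fEPSP window")
  base <- .sweep_baseline(sw, baseline_ms)
  b0 <- mean(base)
  noise <- stats::mad(base)
  v <- sw$voltage_mV
  idx_win <- which(win)
  trough <- idx_win[which.min(v[idx_win])]
  amp <- b0 - v[trough]
  if (amp <= 3 * noise || amp <= 0) {
    return(list(fepsp_slope_mV_per_ms = 0, amplitude_mV = max(amp, 0),
                n_fit = 0L, low_confidence = TRUE))
  }
  lo_level <- b0 - fit_fraction_range[1] * amp
  hi_level <- b0 - fit_fraction_range[2] * amp
  # walk back from the trough to find the rising-phase segment
  seg <- idx_win[1]:trough
  vs <- v[seg]
  in_band <- vs <= lo_level & vs >= hi_level
  # use the contiguous run adjacent to the trough (the rising limb)
  runs <- rle(in_band)
  if (!any(runs$values)) in_fit <- integer(0) else {
    ends <- cumsum(runs$lengths)
    starts_ <- ends - runs$lengths + 1
    k <- utils::tail(which(runs$values), 1)
    in_fit <- seg[starts_[k]:ends[k]]
  }
  if (length(in_fit) < 4)
    stop("fewer than 4 samples on the fitted rising phase; increase the ",
         "sampling rate or widen fit_fraction_range")
  tt <- sw$time_s[in_fit] * 1e3  # ms
  fit <- stats::lm.fit(cbind(1, tt), v[in_fit])
  list(fepsp_slope_mV_per_ms = abs(fit$coefficients[[2]]),
       amplitude_mV = amp, n_fit = length(in_fit), low_confidence = FALSE)
}

#' Paired-pulse ratio
#'
#' Ratio of the second to the first pulse of a per-pulse metric. A first
#' pulse indistinguishable from zero yields `NA` with `undefined = TRUE`.
#'
#' @param pulse1,pulse2 Metric values (e.g. fEPSP slopes or peak
#'   amplitudes).
#' @param eps Threshold below which pulse 1 counts as zero (default 1e-9).
#' @return List: `ppr`, `undefined`.
#' @export
paired_pulse_ratio <- function(pulse1, pulse2, eps = 1e-9) {
  if (!is.finite(pulse1) || abs(pulse1) <= eps)
    return(list(ppr = NA_real_, undefined = TRUE))
  list(ppr = pulse2 / pulse1, undefined = FALSE)
}

#' Experiment timeline of per-sweep metrics
#'
#' @param time_s Sweep times (s, strictly increasing; one sweep per 20 s in
#'   the standard protocol).
#' @param metrics Data.frame of per-sweep metrics (e.g. `fepsp_slope`,
#'   `fv_amplitude`), one row per sweep.
#' @param baseline_epoch_s Baseline epoch `c(start, end)` (s, default
#'   c(0, 600): the first 10 min).
#' @param end_epoch_s Final analysis epoch (s); default the last 10 min of
#'   the recording.
#' @param ischemia_window_s Optional insult window `c(start, end)` (s);
#'   must start after the baseline epoch.
#' @return An object of class `ephys_timeline`.
#' @export
experiment_timeline <- function(time_s, metrics,
                                baseline_epoch_s = c(0, 600),
                                end_epoch_s = NULL,
                                ischemia_window_s = NULL) {
  stopifnot(all(diff(time_s) > 0), nrow(metrics) == length(time_s))
  if (is.null(end_epoch_s))
    end_epoch_s <- c(max(time_s) - 600, max(time_s))
  if (baseline_epoch_s[1] < min(time_s) - 1e-9 ||
      end_epoch_s[2] > max(time_s) + 1e-9)
    stop("epochs must lie within the recording")
  if (!is.null(ischemia_window_s) &&
      ischemia_window_s[1] < baseline_epoch_s[2])
    stop("the baseline epoch must precede the ischemia window")
  x <- list(time_s = time_s, metrics = as.data.frame(metrics),
            baseline_epoch_s = baseline_epoch_s, end_epoch_s = end_epoch_s,
            ischemia_window_s = ischemia_window_s, normalized = FALSE)
  class(x) <- "ephys_timeline"
  x
}

#' Normalize timeline metrics to their baseline-epoch mean
#'
#' Divides every metric column by its mean over the baseline epoch, so the
#' baseline mean of each normalized course is exactly 1. Requires at least
#' `min_baseline_sweeps` sweeps in the baseline epoch and a non-zero
#' baseline mean for every metric.
#'
#' @param timeline An [experiment_timeline()].
#' @param min_baseline_sweeps Minimum baseline sweeps (default 10).
#' @return The timeline with normalized metrics (`normalized = TRUE`) and
#'   the baseline means stored as `baseline_means`.
#' @export
normalize_to_baseline <- function(timeline, min_baseline_sweeps = 10) {
  stopifnot(inherits(timeline, "ephys_timeline"))
  idx <- timeline$time_s >= timeline$baseline_epoch_s[1] &
    timeline$time_s <= timeline$baseline_epoch_s[2]
  if (sum(idx) < min_baseline_sweeps)
    stop("need at least ", min_baseline_sweeps, " baseline sweeps, have ",
         sum(idx))
  means <- vapply(timeline$metrics, function(col) mean(col[idx]), numeric(1))
  if (any(!is.finite(means) | means == 0))
    stop("zero or non-finite baseline mean for: ",
         paste(names(means)[!is.finite(means) | means == 0], collapse = ", "))
  timeline$metrics[] <- Map(`/`, timeline$metrics, means)
  timeline$baseline_means <- means
  timeline$normalized <- TRUE
  timeline
}

#' Classify the post-insult outcome of an experiment
#'
#' Applies the recovery rule to the normalized fEPSP-slope course: the
#' episode is a postsynaptic `"failure"` if the end-epoch mean does not
#' recover to strictly above `threshold` (default 0.5, i.e. 50% of
#' baseline), otherwise `"recovered"`. End/baseline ratios of all metrics
#' are reported alongside.
#'
#' @param timeline A normalized [experiment_timeline()] (see
#'   [normalize_to_baseline()]).
#' @param metric Metric column driving the classification (default
#'   `"fepsp_slope"`).
#' @param threshold Recovery threshold on the normalized end-epoch mean
#'   (default 0.5).
#' @return An object of class `episode_outcome`: `classification`
#'   (`"recovered"` or `"failure"`), `end_ratios` (named vector),
#'   `threshold`, `metric`.
#' @export
classify_outcome <- function(timeline, metric = "fepsp_slope",
                             threshold = 0.5) {
  stopifnot(inherits(timeline, "ephys_timeline"))
  if (!isTRUE(timeline$normalized))
    stop("classify_outcome needs a normalized timeline")
  if (!metric %in% names(timeline$metrics))
    stop("metric '", metric, "' not in the timeline")
  idx <- timeline$time_s >= timeline$end_epoch_s[1] &
    timeline$time_s <= timeline$end_epoch_s[2]
  if (!any(idx)) stop("the end epoch contains no sweeps")
  ratios <- vapply(timeline$metrics, function(col) mean(col[idx]), numeric(1))
  cls <- if (ratios[[metric]] > threshold) "recovered" else "failure"
  out <- list(classification = cls, end_ratios = ratios,
              threshold = threshold, metric = metric)
  class(out) <- "episode_outcome"
  out
}

#' @export
print.episode_outcome <- function(x, ...) {
  cat(sprintf("Episode outcome: %s (%s end/baseline = %.3f, threshold %.2f)\n",
              x$classification, x$metric, x$end_ratios[[x$metric]],
              x$threshold))
  invisible(x)
}
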