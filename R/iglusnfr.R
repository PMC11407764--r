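# iGluSnFR line-scan processing.
#
# A line scan is a position x time fluorescence array acquired at a fixed
# scan rate; a signal ROI along the position axis carries the indicator
# response, a background ROI carries non-indicator fluorescence. Repeats
# are averaged first, the background is subtracted, F0 is the pre-stimulus
# mean, and transients are quantified as dF/F0 with per-pulse peak
# amplitudes and a mono-exponential decay time constant.

#' iGluSnFR line scan
#'
#' @param fluorescence Numeric matrix, positions in rows, time points in
#'   columns (a.u.).
#' @param scan_rate_hz Line rate (Hz, default 378.8).
#' @param roi Integer range `c(first, last)` of signal rows.
#' @param background_roi Integer range of background rows; must not overlap
#'   the signal ROI.
#' @param stimulus_times_s Stimulus onsets (s from scan start).
#' @return An object of class `line_scan`.
#' @export
line_scan <- function(fluorescence, scan_rate_hz = 378.8, roi,
                      background_roi, stimulus_times_s) {
  stopifnot(is.matrix(fluorescence), scan_rate_hz > 0,
            length(roi) == 2, length(background_roi) == 2)
  np <- nrow(fluorescence)
  if (roi[1] < 1 || roi[2] > np || background_roi[1] < 1 ||
      background_roi[2] > np || roi[1] > roi[2] ||
      background_roi[1] > background_roi[2])
    stop("ROI ranges must lie within the position axis")
  if (max(roi[1], background_roi[1]) <= min(roi[2], background_roi[2]))
    stop("signal and background ROIs must be disjoint")
  dur <- ncol(fluorescence) / scan_rate_hz
  if (any(stimulus_times_s < 0) || any(stimulus_times_s >= dur))
    stop("stimulus times must lie within the scan")
  x <- list(fluorescence = fluorescence, scan_rate_hz = scan_rate_hz,
            roi = as.integer(roi), background_roi = as.integer(background_roi),
            stimulus_times_s = stimulus_times_s,
            time_s = (seq_len(ncol(fluorescence)) - 1) / scan_rate_hz,
            n_averaged = 1L)
  class(x) <- "line_scan"
  x
}

#' Average repeated line scans
#'
#' Element-wise mean of repeated scans of the same line (identical shapes,
#' scan rates and stimulus times); the repeat count is recorded. Averaging
#' precedes background subtraction in the analysis chain.
#'
#' @param scans List of [line_scan()] objects (typically 4-6 repeats).
#' @return A `line_scan` with the averaged array and `n_averaged` set.
#' @export
average_repeats <- function(scans) {
  stopifnot(length(scans) >= 1,
            all(vapply(scans, inherits, logical(1), "line_scan")))
  ref <- scans[[1]]
  for (s in scans[-1]) {
    if (!identical(dim(s$fluorescence), dim(ref$fluorescence)))
      stop("scan shapes differ; cannot average")
    if (s$scan_rate_hz != ref$scan_rate_hz)
      stop("scan rates differ; cannot average")
  }
  ref$fluorescence <- Reduce(`+`, lapply(scans, `[[`, "fluorescence")) /
    length(scans)
  ref$n_averaged <- length(scans)
  ref
}

#' Compute the dF/F0 transient of a line scan
#'
#' Per time point, the signal is the ROI row-mean minus the background ROI
#' row-mean; `F0` is the signal mean over the pre-stimulus baseline window;
#' the transient is `(signal - F0)/F0`. Peak amplitudes are measured per
#' stimulus as the maximum of dF/F0 inside `peak_window_ms` after the
#' stimulus; the second pulse of a pair is measured above the extrapolated
#' exponential tail of the first (see [transient_ppr()]).
#'
#' @param scan A [line_scan()] (usually after [average_repeats()]).
#' @param baseline_window_s `c(start, end)` of the baseline (s); defaults
#'   to everything before the first stimulus.
#' @param peak_window_ms Post-stimulus window for peak search (ms, default
#'   30).
#' @return An object of class `glu_transient`: `time_s`, `dff`, `f0`,
#'   `peak_amplitudes` (per stimulus), `n_averaged`, `scan_rate_hz`,
#'   `stimulus_times_s`.
#' @export
compute_dff <- function(scan, baseline_window_s = NULL,
                        peak_window_ms = 30) {
  stopifnot(inherits(scan, "line_scan"))
  sig_rows <- scan$roi[1]:scan$roi[2]
  bg_rows <- scan$background_roi[1]:scan$background_roi[2]
  sig <- colMeans(scan$fluorescence[sig_rows, , drop = FALSE]) -
    colMeans(scan$fluorescence[bg_rows, , drop = FALSE])
  if (is.null(baseline_window_s))
    baseline_window_s <- c(0, min(scan$stimulus_times_s))
  if (baseline_window_s[2] > min(scan$stimulus_times_s) + 1e-9)
    stop("baseline window must precede the first stimulus")
  bl <- scan$time_s >= baseline_window_s[1] &
    scan$time_s < baseline_window_s[2]
  if (!any(bl)) stop("baseline window contains no samples")
  f0 <- mean(sig[bl])
  if (!is.finite(f0) || f0 <= 0)
    stop("non-positive resting fluorescence after background subtraction; ",
         "scan unusable")
  dff <- (sig - f0) / f0
  peaks <- vapply(scan$stimulus_times_s, function(t0) {
    win <- scan$time_s >= t0 & scan$time_s <= t0 + peak_window_ms * 1e-3
    if (!any(win)) NA_real_ else max(dff[win])
  }, numeric(1))
  x <- list(time_s = scan$time_s, dff = dff, f0 = f0,
            peak_amplitudes = peaks, n_averaged = scan$n_averaged,
            scan_rate_hz = scan$scan_rate_hz,
            stimulus_times_s = scan$stimulus_times_s)
  class(x) <- "glu_transient"
  x
}

#' Fit the mono-exponential decay of a glutamate transient
#'
#' Least-squares fit of `A exp(-t/tau) + c` to the dF/F0 trace from the
#' post-peak sample of the chosen pulse to `fit_window_ms` later (the
#' offset `c` is fitted, not fixed at zero). The decay time constant is
#' reported in ms; a fit that does not converge or lands outside
#' (1 ms, 10 s) is flagged.
#'
#' @param transient A [compute_dff()] result.
#' @param pulse_index Which stimulus' decay to fit (default 2, the second
#'   pulse of a pair).
#' @param fit_window_ms Length of the fitted window after the peak (ms,
#'   default 500).
#' @param peak_window_ms Post-stimulus window in which the peak is located
#'   (ms, default 30).
#' @return List: `tau_ms`, `A`, `offset`, `converged`.
#' @export
fit_decay <- function(transient, pulse_index = 2, fit_window_ms = 500,
                      peak_window_ms = 30) {
  stopifnot(inherits(transient, "glu_transient"),
            pulse_index %in% seq_along(transient$stimulus_times_s))
  t0 <- transient$stimulus_times_s[pulse_index]
  win <- transient$time_s >= t0 &
    transient$time_s <= t0 + peak_window_ms * 1e-3
  if (!any(win)) stop("no samples in the peak window")
  ipk <- which(win)[which.max(transient$dff[win])]
  fit_idx <- transient$time_s >= transient$time_s[ipk] &
    transient$time_s <= transient$time_s[ipk] + fit_window_ms * 1e-3
  tt <- (transient$time_s[fit_idx] - transient$time_s[ipk]) * 1e3  # ms
  yy <- transient$dff[fit_idx]
  if (length(tt) < 5) stop("too few samples in the decay window")
  A0 <- max(yy[1], 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * exp(-tt / tau) + c0,
                      start = list(A = A0, tau = 50, c0 = 0),
                      lower = c(A = 0, tau = 0.1, c0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau_ms = NA_real_, A = NA_real_, offset = NA_real_,
                converged = FALSE))
  cf <- stats::coef(fit)
  tau <- unname(cf["tau"])
  ok <- isTRUE(fit$convInfo$isConv) && tau > 1 && tau < 1e4
  list(tau_ms = tau, A = unname(cf["A"]), offset = unname(cf["c0"]),
       converged = ok)
}

#' Paired-pulse ratio of a glutamate transient
#'
#' Ratio of the second to the first peak dF/F0 of a paired-pulse transient.
#' Because the pulses are 50 ms apart and the decay is slower, the second
#' peak is measured above the extrapolated mono-exponential tail of the
#' first pulse (`subtract_residual = FALSE` disables the correction).
#'
#' @param transient A [compute_dff()] result with two stimuli.
#' @param subtract_residual Subtract pulse 1's extrapolated tail (default
#'   TRUE).
#' @param peak_window_ms Peak search window per pulse (ms, default 30).
#' @param tail_fit_window_ms Window used to fit pulse 1's decay for the
#'   extrapolation (ms); default the inter-stimulus gap.
#' @param eps Pulse-1 peak threshold below which the PPR is undefined.
#' @return List: `ppr`, `peak1`, `peak2` (residual-corrected), `undefined`.
#' @export
transient_ppr <- function(transient, subtract_residual = TRUE,
                          peak_window_ms = 30, tail_fit_window_ms = NULL,
                          eps = 1e-6) {
  stopifnot(inherits(transient, "glu_transient"))
  if (length(transient$stimulus_times_s) < 2)
    stop("paired-pulse ratio needs two stimuli")
  st <- transient$stimulus_times_s
  peak_at <- function(t0) {
    win <- transient$time_s >= t0 &
      transient$time_s <= t0 + peak_window_ms * 1e-3
    i <- which(win)[which.max(transient$dff[win])]
    list(i = i, v = transient$dff[i], t = transient$time_s[i])
  }
  p1 <- peak_at(st[1]); p2 <- peak_at(st[2])
  if (!is.finite(p1$v) || p1$v <= eps)
    return(list(ppr = NA_real_, peak1 = p1$v, peak2 = p2$v,
                undefined = TRUE))
  peak2 <- p2$v
  if (subtract_residual) {
    if (is.null(tail_fit_window_ms))  # stop short of the second stimulus
      tail_fit_window_ms <- (st[2] - p1$t) * 1e3 - 3
    d1 <- fit_decay(transient, pulse_index = 1,
                    fit_window_ms = tail_fit_window_ms,
                    peak_window_ms = peak_window_ms)
    if (isTRUE(d1$converged)) {
      resid1 <- d1$A * exp(-((p2$t - p1$t) * 1e3) / d1$tau_ms) + d1$offset
      peak2 <- p2$v - resid1
    }
  }
  list(ppr = peak2 / p1$v, peak1 = p1$v, peak2 = peak2, undefined = FALSE)
}
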