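# Ion-selective microelectrode calibration and trace conversion.
#
# Electrodes are calibrated against concentration standards; the voltage-
# concentration relation is Nernstian at high concentrations with a
# departure in the low sub-millimolar range that is captured by the
# Nicolsky-Eisenman form with a single lumped interfering-background term:
#   V = E0 + slope * log10(c + c_interference).
# Activities are approximated by concentrations throughout (the standards
# are defined by concentration).

#' A set of electrode calibration points
#'
#' @param concentration_mM Standard concentrations (mM, > 0).
#' @param voltage_mV Measured electrode potentials (mV).
#' @return An object of class `calibration_points` (a data.frame).
#' @export
calibration_points <- function(concentration_mM, voltage_mV) {
  stopifnot(length(concentration_mM) == length(voltage_mV),
            all(concentration_mM > 0))
  x <- data.frame(concentration_mM = concentration_mM,
                  voltage_mV = voltage_mV)
  class(x) <- c("calibration_points", "data.frame")
  x
}

#' Fit an electrode calibration
#'
#' Least-squares fit of the calibration model to measured points.
#' `model = "nernst"` fits `V = E0 + slope log10(c)` (>= 2 points, linear);
#' `model = "nicolsky_eisenman"` adds the lumped interfering background,
#' `V = E0 + slope log10(c + c_int)` (>= 3 points, nonlinear with the
#' Nernst fit as starting point). With `c_int = 0` the NE model reproduces
#' the Nernst fit exactly.
#'
#' @param points A [calibration_points()] (or data.frame with the same
#'   columns).
#' @param model `"nernst"` or `"nicolsky_eisenman"`.
#' @param temperature_K Recording temperature, stored for reference
#'   (default 307 K).
#' @return An object of class `electrode_cal`: `model`, `E0_mV`,
#'   `slope_mV_per_decade`, `c_interference_mM`, `temperature_K`,
#'   `residual_norm`.
#' @export
fit_calibration <- function(points, model = c("nernst", "nicolsky_eisenman"),
                            temperature_K = 307) {
  model <- match.arg(model)
  c_mM <- points$concentration_mM
  V <- points$voltage_mV
  need <- if (model == "nernst") 2L else 3L
  if (length(c_mM) < need)
    stop("need at least ", need, " calibration points for model ", model)
  if (length(unique(c_mM)) < 2L)
    stop("degenerate calibration: all standards have the same concentration")
  lin <- stats::lm(V ~ log10(c_mM))
  E0 <- unname(stats::coef(lin)[1])
  slope <- unname(stats::coef(lin)[2])
  c_int <- 0
  rn <- sqrt(sum(stats::resid(lin)^2))
  if (model == "nicolsky_eisenman") {
    # perfectly Nernstian data make the interference term unidentifiable
    # (singular Jacobian at c_int = 0); the NE model then reduces to the
    # Nernst fit with zero interference
    fit <- tryCatch(
      minpack.lm::nlsLM(
        V ~ E0 + slope * log10(c_mM + c_int),
        start = list(E0 = E0, slope = slope, c_int = 0.01),
        lower = c(E0 = -Inf, slope = 1e-6, c_int = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      E0 <- unname(cf["E0"]); slope <- unname(cf["slope"])
      c_int <- unname(cf["c_int"])
      rn <- sqrt(sum(stats::resid(fit)^2))
    }
  }
  if (slope <= 0)
    stop("fitted slope is not positive; not a cation electrode response")
  cal <- list(model = model, E0_mV = E0, slope_mV_per_decade = slope,
              c_interference_mM = c_int, temperature_K = temperature_K,
              residual_norm = rn)
  class(cal) <- "electrode_cal"
  cal
}

#' @export
print.electrode_cal <- function(x, ...) {
  cat(sprintf("Electrode calibration (%s): E0 = %.2f mV, slope = %.2f mV/decade",
              x$model, x$E0_mV, x$slope_mV_per_decade))
  if (x$model == "nicolsky_eisenman")
    cat(sprintf(", interference = %.4g mM", x$c_interference_mM))
  cat("\n")
  invisible(x)
}

#' Forward calibration model: concentration to voltage
#'
#' @param c_mM Concentration (mM).
#' @param cal An [fit_calibration()] result (or a list with the same
#'   fields).
#' @return Electrode potential (mV).
#' @export
concentration_to_voltage <- function(c_mM, cal) {
  stopifnot(all(c_mM >= 0))
  cal$E0_mV + cal$slope_mV_per_decade *
    log10(c_mM + cal$c_interference_mM)
}

#' Convert electrode voltage to concentration
#'
#' Exact analytic inversion of the calibration model:
#' `c = 10^((V - E0)/slope) - c_interference`. Raw inverses below zero
#' (possible for the Nicolsky-Eisenman model at very low voltages) are
#' floored at 0; the number of floored samples is reported as the
#' `n_floored` attribute.
#'
#' @param voltage_mV Electrode potential(s) (mV).
#' @param cal An [fit_calibration()] result.
#' @return Concentration(s) in mM (>= 0), with attribute `n_floored`.
#' @export
voltage_to_concentration <- function(voltage_mV, cal) {
  raw <- 10^((voltage_mV - cal$E0_mV) / cal$slope_mV_per_decade) -
    cal$c_interference_mM
  n_floored <- sum(raw < 0)
  if (n_floored > 0)
    warning(n_floored, " sample(s) below the electrode floor set to 0 mM")
  out <- pmax(raw, 0)
  attr(out, "n_floored") <- n_floored
  out
}

#' Decade-step electrode quality control
#'
#' The acceptance rule for a freshly calibrated electrode: the voltage
#' response to a 10-fold concentration increase must exceed the threshold
#' (strictly; default 50 mV). An ideal Nernstian monovalent-cation
#' electrode at 307 K responds with ~61 mV and passes.
#'
#' @param c_low_mM,v_low_mV Lower standard and its potential.
#' @param c_high_mM,v_high_mV Higher standard (must be 10x the lower) and
#'   its potential.
#' @param threshold_mV Pass threshold (mV, default 50).
#' @return Logical: TRUE if the electrode passes.
#' @export
electrode_qc <- function(c_low_mM, v_low_mV, c_high_mM, v_high_mV,
                         threshold_mV = 50) {
  if (abs(c_high_mM / c_low_mM - 10) > 1e-6)
    stop("QC requires an exact 10-fold concentration pair, got ratio ",
         signif(c_high_mM / c_low_mM, 4))
  (v_high_mV - v_low_mV) > threshold_mV
}

#' Ion concentration / electrode voltage trace
#'
#' @param time_s Strictly increasing sample times (s).
#' @param value Samples: mV for `kind = "voltage"`, mM for
#'   `kind = "concentration"`.
#' @param kind `"concentration"` or `"voltage"`.
#' @param ischemia_window_s Optional `c(start, end)` of the metabolic
#'   insult (s).
#' @return An object of class `ion_trace`.
#' @export
ion_trace <- function(time_s, value, kind = c("concentration", "voltage"),
                      ischemia_window_s = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(time_s) == length(value), all(diff(time_s) > 0))
  if (!is.null(ischemia_window_s)) {
    stopifnot(length(ischemia_window_s) == 2,
              ischemia_window_s[1] < ischemia_window_s[2])
  }
  x <- list(time_s = time_s, value = value, kind = kind,
            ischemia_window_s = ischemia_window_s)
  class(x) <- "ion_trace"
  x
}

#' Convert a voltage trace to a concentration trace
#'
#' @param trace An [ion_trace()] of kind `"voltage"`.
#' @param cal An [fit_calibration()] result.
#' @return An `ion_trace` of kind `"concentration"`.
#' @export
convert_trace <- function(trace, cal) {
  stopifnot(inherits(trace, "ion_trace"))
  if (trace$kind != "voltage")
    stop("trace is already in concentration units")
  ion_trace(trace$time_s,
            as.numeric(voltage_to_concentration(trace$value, cal)),
            kind = "concentration",
            ischemia_window_s = trace$ischemia_window_s)
}

#' Maximum concentration increase over a window
#'
#' Baseline-subtracted peak: the baseline is the mean over a pre-window
#' interval (default the 60 s preceding the window) and the result is the
#' maximum of `value - baseline` inside the window. Used for the maximum
#' extracellular K+ increase during a metabolic insult.
#'
#' @param trace An [ion_trace()] of kind `"concentration"`.
#' @param window_s `c(start, end)` of the analysis window (s); defaults to
#'   the trace's `ischemia_window_s`.
#' @param baseline_s Length of the pre-window baseline interval (s,
#'   default 60).
#' @return Maximum increase (mM) with attribute `baseline_mM`.
#' @export
max_delta <- function(trace, window_s = NULL, baseline_s = 60) {
  stopifnot(inherits(trace, "ion_trace"))
  if (trace$kind != "concentration")
    stop("max_delta needs a concentration trace; use convert_trace() first")
  if (is.null(window_s)) window_s <- trace$ischemia_window_s
  if (is.null(window_s)) stop("no analysis window given")
  if (window_s[1] < min(trace$time_s) || window_s[2] > max(trace$time_s))
    stop("window outside the trace span")
  in_win <- trace$time_s >= window_s[1] & trace$time_s <= window_s[2]
  if (!any(in_win)) stop("window contains no samples")
  pre <- trace$time_s >= (window_s[1] - baseline_s) &
    trace$time_s < window_s[1]
  if (!any(pre)) stop("no samples in the pre-window baseline interval")
  baseline <- mean(trace$value[pre])
  out <- max(trace$value[in_win] - baseline)
  attr(out, "baseline_mM") <- baseline
  out
}
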