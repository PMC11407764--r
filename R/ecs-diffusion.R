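# Real-time iontophoresis (RTI) estimation of extracellular-space (ECS)
# properties. A TMA+ point source is driven by a constant iontophoretic
# current for a fixed duration; the concentration transient recorded at a
# known distance by an ion-selective microelectrode is described by the
# classical constant-point-source solution of the porous-medium diffusion
# equation (volume fraction alpha, effective diffusion coefficient D*,
# optional first-order clearance k'). Fitting the transient yields alpha and
# D*, and the tortuosity lambda = sqrt(D/D*). All diffusion math is CGS
# (cm, s, mol); distances are um at the interface.

#' Iontophoretic point-source parameters
#'
#' @param current_nA Iontophoresis current (nA, default 100).
#' @param pulse_s Pulse duration (s, default 30).
#' @param transport_number Fraction of the current carried by TMA+ out of
#'   the pipette (default 0.3).
#' @param valence Ion valence (default +1 for TMA+).
#' @return An object of class `rti_source` with the molar release rate
#'   `Q_mol_s = I * n_t / (z F)`.
#' @export
rti_source <- function(current_nA = 100, pulse_s = 30,
                       transport_number = 0.3, valence = 1) {
  stopifnot(current_nA > 0, pulse_s > 0, transport_number > 0,
            transport_number <= 1, valence >= 1)
  s <- list(current_nA = current_nA, pulse_s = pulse_s,
            transport_number = transport_number, valence = valence,
            Q_mol_s = current_nA * 1e-9 * transport_number /
              (valence * .const$F))
  class(s) <- "rti_source"
  s
}

#' Tissue diffusion parameters for the RTI model
#'
#' @param alpha ECS volume fraction (0 < alpha <= 1).
#' @param D_star_cm2_s Effective TMA diffusion coefficient (cm^2/s).
#' @param k_prime_per_s Linear clearance rate (1/s, default 0).
#' @param D_free_cm2_s Free-medium TMA diffusion coefficient (cm^2/s,
#'   default 1.31e-5 at ~34 C).
#' @return An object of class `tissue_params` including the derived
#'   tortuosity `lambda`.
#' @export
tissue_params <- function(alpha, D_star_cm2_s, k_prime_per_s = 0,
                          D_free_cm2_s = 1.31e-5) {
  stopifnot(alpha > 0, alpha <= 1, D_star_cm2_s > 0, k_prime_per_s >= 0)
  if (D_star_cm2_s > D_free_cm2_s * (1 + 1e-12))
    stop("D_star exceeds D_free: unphysical (lambda < 1)")
  p <- list(alpha = alpha, D_star_cm2_s = D_star_cm2_s,
            k_prime_per_s = k_prime_per_s, D_free_cm2_s = D_free_cm2_s,
            lambda = tortuosity(D_free_cm2_s, D_star_cm2_s))
  class(p) <- "tissue_params"
  p
}

#' Tortuosity from free and effective diffusion coefficients
#'
#' `lambda = sqrt(D_free / D_star)`; the hindrance of extracellular
#' diffusion relative to a free medium.
#'
#' @param D_free_cm2_s,D_star_cm2_s Free and effective diffusion
#'   coefficients (same units).
#' @return Dimensionless tortuosity (>= 1).
#' @export
tortuosity <- function(D_free_cm2_s, D_star_cm2_s) {
  stopifnot(D_star_cm2_s > 0)
  if (any(D_star_cm2_s > D_free_cm2_s * (1 + 1e-12)))
    stop("D_star > D_free implies lambda < 1: unphysical fit")
  sqrt(D_free_cm2_s / D_star_cm2_s)
}

# constant-source solution, concentration in the ECS (mM) at radius r (cm)
# for elapsed source-on time t (vector, s); 0 for t <= 0
.rti_on <- function(t, r_cm, Q_mol_s, alpha, D, k) {
  out <- numeric(length(t))
  pos <- t > 0
  if (!any(pos)) return(out)
  tp <- t[pos]
  pref <- Q_mol_s / (8 * pi * D * alpha * r_cm)  # mol/cm^3
  b <- sqrt(k / D)
  u <- r_cm / (2 * sqrt(D * tp))
  v <- sqrt(k * tp)
  out[pos] <- pref * (exp(r_cm * b) * pracma::erfc(u + v) +
                        exp(-r_cm * b) * pracma::erfc(u - v))
  out * 1e6  # mol/cm^3 -> mM
}

#' Forward RTI model: TMA+ transient at a distance from a point source
#'
#' Above-baseline TMA+ concentration in the ECS at distance `distance_um`
#' from a constant point source switched on at t = 0 for the source's pulse
#' duration, in a porous medium with volume fraction `alpha`, effective
#' diffusion coefficient `D_star` and optional linear clearance `k_prime`.
#' After the pulse the trace is the exact on-source superposition
#' `C_on(t) - C_on(t - pulse_s)`. With `k_prime = 0` the solution reduces to
#' the uptake-free `erfc` form, approaching the steady state
#' `Q / (4 pi D* alpha r)` during a long pulse.
#'
#' @param time_s Time grid (s, non-negative, covering pulse and decay).
#' @param distance_um Source-electrode distance (um; must be positive).
#' @param source An [rti_source()].
#' @param tissue A [tissue_params()].
#' @return Above-baseline concentration (mM), same length as `time_s`.
#' @export
rti_forward <- function(time_s, distance_um, source = rti_source(),
                        tissue) {
  stopifnot(inherits(source, "rti_source"), inherits(tissue, "tissue_params"))
  if (any(time_s < 0)) stop("time_s must be non-negative")
  if (distance_um <= 0) stop("distance must be positive")
  r_cm <- distance_um * 1e-4
  on <- .rti_on(time_s, r_cm, source$Q_mol_s, tissue$alpha,
                tissue$D_star_cm2_s, tissue$k_prime_per_s)
  off <- .rti_on(time_s - source$pulse_s, r_cm, source$Q_mol_s,
                 tissue$alpha, tissue$D_star_cm2_s, tissue$k_prime_per_s)
  on - off
}

#' TMA+ concentration transient container
#'
#' @param time_s Strictly increasing time grid (s).
#' @param tma_mM Concentration (mM): above-baseline (`kind =
#'   "above_baseline"`) or absolute with a recorded bath baseline
#'   (`kind = "absolute"`, default baseline 1 mM TMACl).
#' @param distance_um Source-electrode distance (um, validity range
#'   50-500 um by default).
#' @param source An [rti_source()].
#' @param baseline_mM Bath TMA concentration (mM, default 1).
#' @param kind `"above_baseline"` or `"absolute"`.
#' @param distance_range_um Accepted distance range.
#' @return An object of class `tma_curve`.
#' @export
tma_curve <- function(time_s, tma_mM, distance_um, source = rti_source(),
                      baseline_mM = 1, kind = c("above_baseline", "absolute"),
                      distance_range_um = c(50, 500)) {
  kind <- match.arg(kind)
  stopifnot(length(time_s) == length(tma_mM), all(diff(time_s) > 0))
  if (distance_um < distance_range_um[1] || distance_um > distance_range_um[2])
    stop("distance ", distance_um, " um outside validity range ",
         distance_range_um[1], "-", distance_range_um[2], " um")
  x <- list(time_s = time_s, tma_mM = tma_mM, distance_um = distance_um,
            source = source, baseline_mM = baseline_mM, kind = kind)
  class(x) <- "tma_curve"
  x
}

#' Write / read a TMA curve as CSV plus metadata sidecar
#'
#' The data file holds two columns (`time_s`, `tma_mM`); the sidecar
#' (`<file>.meta.csv`, key/value) records distance, source parameters,
#' baseline and kind so the curve round-trips losslessly.
#'
#' @param curve A [tma_curve()].
#' @param file Path of the data CSV.
#' @return `write_tma_curve` returns `file` invisibly; `read_tma_curve`
#'   returns a `tma_curve`.
#' @export
write_tma_curve <- function(curve, file) {
  stopifnot(inherits(curve, "tma_curve"))
  utils::write.csv(data.frame(time_s = curve$time_s, tma_mM = curve$tma_mM),
                   file, row.names = FALSE)
  meta <- data.frame(
    key = c("distance_um", "current_nA", "pulse_s", "transport_number",
            "valence", "baseline_mM", "kind"),
    value = c(curve$distance_um, curve$source$current_nA,
              curve$source$pulse_s, curve$source$transport_number,
              curve$source$valence, curve$baseline_mM, curve$kind))
  utils::write.csv(meta, paste0(file, ".meta.csv"), row.names = FALSE)
  invisible(file)
}

#' @rdname write_tma_curve
#' @export
read_tma_curve <- function(file) {
  d <- utils::read.csv(file)
  m <- utils::read.csv(paste0(file, ".meta.csv"))
  meta <- stats::setNames(as.list(m$value), m$key)
  num <- function(k) as.numeric(meta[[k]])
  tma_curve(d$time_s, d$tma_mM, distance_um = num("distance_um"),
            source = rti_source(num("current_nA"), num("pulse_s"),
                                num("transport_number"), num("valence")),
            baseline_mM = num("baseline_mM"), kind = meta[["kind"]])
}

#' Fit the RTI forward model to a TMA transient
#'
#' Trust-region Levenberg-Marquardt least squares ([minpack.lm::nlsLM]) of
#' [rti_forward()] to a recorded curve over `(alpha, D_star)` and optionally
#' `k_prime`, with bounds `0 < alpha <= 1`, `0 < D_star <= D_free`. The fit
#' is multi-started from three coarse grid points and the lowest residual
#' norm wins. Absolute-mode curves have the recorded bath baseline
#' subtracted first. Non-convergence yields a flagged result, not an error.
#'
#' @param curve A [tma_curve()] covering both the rise and the decay phase.
#' @param D_free_cm2_s Free-medium diffusion coefficient used for the
#'   tortuosity and the upper bound on `D_star`.
#' @param fit_k_prime Also fit the clearance rate (default FALSE, k' = 0).
#' @param starts Optional data.frame of start points (`alpha`, `D_star`);
#'   defaults to a 3-point coarse grid.
#' @return An object of class `rti_fit`: `alpha`, `D_star_cm2_s`, `lambda`,
#'   `k_prime_per_s`, `residual_norm`, `converged`, `covariance` (parameter
#'   covariance estimate or NULL), `n_points`.
#' @export
fit_rti <- function(curve, D_free_cm2_s = 1.31e-5, fit_k_prime = FALSE,
                    starts = NULL) {
  stopifnot(inherits(curve, "tma_curve"))
  y <- curve$tma_mM
  if (curve$kind == "absolute") y <- y - curve$baseline_mM
  t <- curve$time_s
  if (max(t) <= curve$source$pulse_s)
    stop("curve must extend beyond the source pulse (rise and decay)")
  if (is.null(starts))
    starts <- data.frame(alpha = c(0.1, 0.3, 0.8),
                         D_star = D_free_cm2_s * c(0.3, 0.6, 0.95))
  r_cm <- curve$distance_um * 1e-4
  # raw solution without the physical-bounds validation of tissue_params():
  # numeric-Jacobian steps at the box bounds must evaluate smoothly just
  # outside them; the box constraints of nlsLM still bound the optimum
  model <- function(alpha, D_star, k_prime) {
    on <- .rti_on(t, r_cm, curve$source$Q_mol_s, alpha, D_star,
                  max(k_prime, 0))
    off <- .rti_on(t - curve$source$pulse_s, r_cm, curve$source$Q_mol_s,
                   alpha, D_star, max(k_prime, 0))
    on - off
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- list(alpha = starts$alpha[i], D_star = starts$D_star[i])
    lower <- c(alpha = 1e-4, D_star = D_free_cm2_s * 1e-4)
    upper <- c(alpha = 1, D_star = D_free_cm2_s)
    if (fit_k_prime) {
      start$k_prime <- 1e-3
      lower <- c(lower, k_prime = 0)
      upper <- c(upper, k_prime = 1)
    }
    fit <- tryCatch({
      if (fit_k_prime)
        minpack.lm::nlsLM(y ~ model(alpha, D_star, k_prime), start = start,
                          lower = lower, upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ model(alpha, D_star, 0), start = start,
                          lower = lower, upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    out <- list(alpha = NA_real_, D_star_cm2_s = NA_real_, lambda = NA_real_,
                k_prime_per_s = if (fit_k_prime) NA_real_ else 0,
                residual_norm = NA_real_, converged = FALSE,
                covariance = NULL, n_points = length(y),
                D_free_cm2_s = D_free_cm2_s)
    class(out) <- "rti_fit"
    return(out)
  }
  cf <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  out <- list(
    alpha = unname(cf["alpha"]),
    D_star_cm2_s = unname(cf["D_star"]),
    lambda = tortuosity(D_free_cm2_s, unname(cf["D_star"])),
    k_prime_per_s = if (fit_k_prime) unname(cf["k_prime"]) else 0,
    residual_norm = best$rn,
    converged = isTRUE(best$fit$convInfo$isConv),
    covariance = vc,
    n_points = length(y),
    D_free_cm2_s = D_free_cm2_s
  )
  class(out) <- "rti_fit"
  out
}

#' @export
print.rti_fit <- function(x, ...) {
  cat("RTI fit", if (!x$converged) "(NOT converged: values unreliable)", "\n")
  cat(sprintf("  alpha = %.4f, D* = %.3e cm^2/s, lambda = %.3f, k' = %g /s\n",
              x$alpha, x$D_star_cm2_s, x$lambda, x$k_prime_per_s))
  cat(sprintf("  residual norm %.4g over %d points\n",
              x$residual_norm, x$n_points))
  invisible(x)
}

#' Compare two RTI fits (e.g. before vs after an insult)
#'
#' Relative change `(after/before - 1)` of the ECS volume fraction and the
#' effective diffusion coefficient, with first-order uncertainty propagated
#' from the fit covariance estimates (delta method, independent fits).
#'
#' @param before,after Converged [fit_rti()] results.
#' @return A data.frame with rows `alpha` and `D_star`: `before`, `after`,
#'   `relative_change`, `se`.
#' @export
compare_rti_fits <- function(before, after) {
  stopifnot(inherits(before, "rti_fit"), inherits(after, "rti_fit"))
  if (!before$converged || !after$converged)
    stop("refusing to compare unconverged fits")
  se_of <- function(fit, par) {
    if (is.null(fit$covariance)) return(NA_real_)
    sqrt(fit$covariance[par, par])
  }
  row <- function(par, b, a) {
    rel <- a / b - 1
    se_b <- se_of(before, par); se_a <- se_of(after, par)
    se <- abs(a / b) * sqrt((se_a / a)^2 + (se_b / b)^2)
    data.frame(parameter = par, before = b, after = a,
               relative_change = rel, se = se)
  }
  rbind(row("alpha", before$alpha, after$alpha),
        row("D_star", before$D_star_cm2_s, after$D_star_cm2_s))
}
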