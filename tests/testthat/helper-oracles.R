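# Independent numerical oracles used by the tests.

# Finite-difference (finite-volume) solution of the porous-medium point
# source problem: spherically symmetric diffusion with volume fraction
# alpha, effective diffusion D (cm^2/s), linear clearance k (1/s) and a
# constant molar source Q (mol/s) released into the ECS at the origin for
# `pulse_s` seconds. Written independently of the package's closed-form
# solution; explicit Euler on a radial finite-volume grid, source as a
# boundary influx into the innermost shell. Returns above-baseline mM at
# radius r_eval_cm on the requested time grid.
fd_rti <- function(times, r_eval_cm, Q_mol_s, alpha, D, k, pulse_s,
                   R_max = 0.12, dr = 5e-4) {
  r_faces <- seq(0, R_max, by = dr)
  n <- length(r_faces) - 1
  r_cent <- (r_faces[-1] + r_faces[-(n + 1)]) / 2
  A_face <- 4 * pi * r_faces^2                 # cm^2
  V_cell <- 4 / 3 * pi * diff(r_faces^3)       # cm^3
  dt <- 0.2 * dr^2 / D
  C <- numeric(n)                               # mol per cm^3 of ECS
  out <- numeric(length(times))
  t_now <- 0
  prev_val <- 0
  ti <- 1
  eval_at <- function(C) stats::approx(r_cent, C, xout = r_eval_cm,
                                       rule = 2)$y
  src <- Q_mol_s / (alpha * V_cell[1])          # mol/(cm^3 ECS s)
  n_steps <- ceiling(max(times) / dt) + 2L
  for (s in seq_len(n_steps)) {
    flux_in <- -D * A_face[2:n] * diff(C) / dr  # outward flux at faces
    dC <- (c(0, flux_in) - c(flux_in, 0)) / V_cell - k * C
    if (t_now < pulse_s) dC[1] <- dC[1] + src
    C <- C + dt * dC
    t_next <- t_now + dt
    while (ti <= length(times) && times[ti] <= t_next + 1e-9) {
      cur <- eval_at(C)
      f <- (times[ti] - t_now) / dt
      out[ti] <- prev_val * (1 - f) + cur * f
      ti <- ti + 1
    }
    prev_val <- eval_at(C)
    t_now <- t_next
    if (ti > length(times)) break
  }
  out * 1e6                                     # mol/cm^3 -> mM
}

# brute-force half-maximum width by 100x oversampled linear interpolation
brute_hwhm_ms <- function(time_s, v, baseline, trough_idx) {
  os <- stats::approx(time_s, v, n = length(v) * 100)
  amp <- baseline - min(os$y)
  half <- baseline - amp / 2
  ipk <- which.min(os$y)
  below <- os$y <= half
  left <- max(which(!below[1:ipk]))
  right <- ipk - 1 + min(which(!below[ipk:length(below)]))
  (os$x[right] - os$x[left]) * 1e3
}
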