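# Integration of the luminal rate equations.
#
# Dynamic states: luminal pH, glutamate (mM) and chloride (mM). pH is the
# single proton state; because every proton pathway in the model is
# electrogenic, the charge-relevant proton pool entering the membrane
# potential is slaved to it: free protons plus the buffer-bound protons
# translocated since t = 0, h_charge = 10^(-pH) + beta_pH (pH_L0 - pH_L).
# The membrane potential is recomputed algebraically from the charge
# balance at every evaluation; its initial pH therefore leaves a lasting
# imprint on the charge budget (an endocytosed acidic lumen has less proton
# charge to gain before the pump stalls).

#' Right-hand side of the vesicle loading model
#'
#' Time derivatives of `(pH_L, c_glut_L, c_cl_L)`:
#' `d glut/dt = J_vglut` (net transporter flux, antiport minus slippage),
#' `d cl/dt = J_vglut_cl`, and
#' `d pH/dt = -(J_hleak + J_vatpase - J_vglut_coupled) / beta_pH`
#' (the antiport exports one proton per glutamate, so coupled loading
#' alkalinizes). Exposed mainly for testing; most users call
#' [simulate_vesicle()].
#'
#' @param t Time (s, unused; the system is autonomous).
#' @param y Named state vector `c(pH_L=, c_glut_L=, c_cl_L=)`.
#' @param parms List with `geom`, `params`, `conditions`, `fluxes`, `B`,
#'   `pH_L0` and `h0_mM` (free protons at t = 0, mM).
#' @return List of derivatives (deSolve convention) with the instantaneous
#'   membrane potential as an auxiliary variable.
#' @export
vesicle_rhs <- function(t, y, parms) {
  beta <- parms$params$beta_pH_mM_per_pH
  h_charge <- .h_free_mM(y[["pH_L"]]) + beta * (parms$pH_L0 - y[["pH_L"]])
  psi <- membrane_potential(
    h_mM = h_charge,
    c_k_mM = parms$params$c_k_L_mM, c_na_mM = parms$params$c_na_L_mM,
    c_cl_mM = y[["c_cl_L"]], c_glut_mM = y[["c_glut_L"]],
    B = parms$B, geom = parms$geom)
  J <- vesicle_fluxes(y[["pH_L"]], y[["c_glut_L"]], y[["c_cl_L"]], psi,
                      parms$fluxes, parms$conditions, parms$params)
  dH <- J$J_hleak + J$J_vatpase - J$J_vglut_coupled
  dy <- c(
    pH_L = -dH / beta,
    c_glut_L = J$J_vglut,
    c_cl_L = J$J_vglut_cl
  )
  if (any(!is.finite(dy)))
    stop("non-finite derivative at t=", t, "; state: ",
         paste(signif(y, 6), collapse = ", "))
  list(dy, psi_mV = psi)
}

#' Simulate glutamate accumulation in a single vesicle
#'
#' Integrates the luminal rate equations with a stiff solver
#' ([deSolve::lsoda]) and reports the trajectories of the glutamate molecule
#' number, luminal pH, chloride and membrane potential, plus a steady-state
#' assessment: the run is flagged steady when the relative change of the
#' glutamate count falls below `ss_rel_per_s` per second over the trailing
#' `ss_window_s`.
#'
#' @param init A [luminal_init()].
#' @param geom A [vesicle_geometry()].
#' @param params A [vesicle_params()].
#' @param conditions A [cytosol_conditions()].
#' @param fluxes A flux model from [default_flux_model()].
#' @param t_end End of integration (s, default 3000).
#' @param dt_out Output grid spacing (s, default 1).
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10).
#' @param ss_rel_per_s,ss_window_s Steady-state criterion (defaults 1e-6 per
#'   second over 10 s).
#' @return An object of class `vesicle_sim`: list with `trajectory` (a
#'   data.frame: `time_s`, `n_glut`, `pH_L`, `c_glut_L_mM`, `c_cl_L_mM`,
#'   `psi_mV`, `h_charge_mM`), `steady_state_reached`, `steady_state_n_glut` (NA if
#'   not steady), `B_mM` and the inputs.
#' @export
simulate_vesicle <- function(init = luminal_init(),
                             geom = vesicle_geometry(),
                             params = vesicle_params(),
                             conditions = cytosol_conditions(),
                             fluxes = default_flux_model(),
                             t_end = 3000, dt_out = 1,
                             rtol = 1e-8, atol = 1e-10,
                             ss_rel_per_s = 1e-6, ss_window_s = 10) {
  if (t_end <= 0) stop("t_end must be positive")
  if (dt_out <= 0 || dt_out > t_end) stop("invalid dt_out")
  if (rtol <= 0 || atol <= 0) stop("solver tolerances must be positive")
  # clamp luminal Na/K to the initial values supplied
  params$c_k_L_mM <- init$c_k_L0_mM
  params$c_na_L_mM <- init$c_na_L0_mM
  B <- impermeant_charge(init, geom, params)
  y0 <- c(pH_L = init$pH_L0, c_glut_L = init$c_glut_L0_mM,
          c_cl_L = init$c_cl_L0_mM)
  parms <- list(geom = geom, params = params, conditions = conditions,
                fluxes = fluxes, B = B, pH_L0 = init$pH_L0,
                h0_mM = .h_free_mM(init$pH_L0))
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::lsoda(y0, times, vesicle_rhs, parms,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")")
  sol <- as.data.frame(sol)
  traj <- data.frame(
    time_s = sol$time,
    n_glut = molecules_from_concentration(pmax(sol$c_glut_L, 0), geom),
    pH_L = sol$pH_L,
    c_glut_L_mM = sol$c_glut_L,
    c_cl_L_mM = sol$c_cl_L,
    psi_mV = sol$psi_mV,
    # cumulative translocated proton charge (mM), slaved to pH
    h_charge_mM = .h_free_mM(sol$pH_L) +
      params$beta_pH_mM_per_pH * (init$pH_L0 - sol$pH_L)
  )
  # steady-state assessment over the trailing window
  tail_idx <- traj$time_s >= (t_end - ss_window_s)
  n_tail <- traj$n_glut[tail_idx]
  t_tail <- traj$time_s[tail_idx]
  scale_n <- max(mean(n_tail), 1)  # avoid 0/0 for empty vesicles
  rate <- abs(stats::coef(stats::lm.fit(cbind(1, t_tail), n_tail))[2])
  steady <- (rate / scale_n) < ss_rel_per_s
  res <- list(
    trajectory = traj,
    steady_state_reached = steady,
    steady_state_n_glut = if (steady) mean(n_tail) else NA_real_,
    B_mM = B,
    init = init, geom = geom, params = params, conditions = conditions,
    fluxes = fluxes,
    solver = list(t_end = t_end, dt_out = dt_out, rtol = rtol, atol = atol,
                  ss_rel_per_s = ss_rel_per_s, ss_window_s = ss_window_s)
  )
  class(res) <- "vesicle_sim"
  res
}

#' @export
print.vesicle_sim <- function(x, ...) {
  cat("Vesicle loading simulation\n")
  cat(sprintf("  t_end: %g s, steady state reached: %s\n",
              x$solver$t_end, x$steady_state_reached))
  if (x$steady_state_reached)
    cat(sprintf("  steady-state glutamate: %.0f molecules (%.1f mM), pH_L %.2f, psi %.1f mV\n",
                x$steady_state_n_glut,
                utils::tail(x$trajectory$c_glut_L_mM, 1),
                utils::tail(x$trajectory$pH_L, 1),
                utils::tail(x$trajectory$psi_mV, 1)))
  invisible(x)
}

#' Steady-state glutamate content of a simulation
#'
#' Returns the glutamate molecule count averaged over the trailing
#' steady-state window. Errors if the run did not meet the steady-state
#' criterion.
#'
#' @param result A `vesicle_sim` from [simulate_vesicle()].
#' @return Molecule count (numeric scalar).
#' @export
steady_state_glutamate <- function(result) {
  stopifnot(inherits(result, "vesicle_sim"))
  if (!isTRUE(result$steady_state_reached))
    stop("simulation did not reach steady state by t_end = ",
         result$solver$t_end, " s")
  result$steady_state_n_glut
}

#' Scenario specification for the vesicle model
#'
#' A named set of parameter overrides applied before simulation. Override
#' names use dotted paths into the model inputs: `cytosol.<field>` (e.g.
#' `cytosol.pH_c`, `cytosol.atpase_scale`), `init.<field>` (e.g.
#' `init.pH_L0`) and `flux.<field>` (e.g. `flux.k_vglut`). An empty override
#' set reproduces the control run exactly.
#'
#' @param name Scenario label.
#' @param overrides Named list of `path = value` pairs (possibly empty).
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("acidic cytosol", list(cytosol.pH_c = 6.8))
#' @export
scenario_spec <- function(name, overrides = list()) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(overrides) && is.null(names(overrides)))
    stop("overrides must be named")
  s <- list(name = name, overrides = overrides)
  class(s) <- "scenario_spec"
  s
}

#' The ischemia-like scenario battery
#'
#' The default scenario set: control, the single-parameter ischemia-like
#' perturbations (cytosolic acidification, raised cytosolic Na+ and Cl-,
#' lowered cytosolic K+, an acidified endocytosed lumen, reduced V-ATPase
#' activity) and cytosolic alkalinization (pH 7.2 to 7.4) as the
#' opposite-direction control. Magnitudes are representative of acute
#' metabolic failure, not fits to any particular recording.
#'
#' @return List of [scenario_spec()] objects.
#' @export
ischemia_scenarios <- function() {
  list(
    scenario_spec("control", list()),
    scenario_spec("acidic_cytosol",  list(cytosol.pH_c = 6.8)),
    scenario_spec("high_Na",         list(cytosol.c_na_c_mM = 30)),
    scenario_spec("high_Cl",         list(cytosol.c_cl_c_mM = 20)),
    scenario_spec("low_K",           list(cytosol.c_k_c_mM = 100)),
    scenario_spec("acidic_lumen",    list(init.pH_L0 = 6.9)),
    scenario_spec("low_ATPase",      list(cytosol.atpase_scale = 0.5)),
    scenario_spec("alkaline_cytosol", list(cytosol.pH_c = 7.4))
  )
}

.apply_overrides <- function(overrides, init, conditions, fluxes) {
  for (path in names(overrides)) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("override path must be '<target>.<field>': ", path)
    target <- parts[1]; field <- parts[2]
    value <- overrides[[path]]
    assign_field <- function(obj) {
      if (!field %in% names(obj))
        stop("unknown override field '", field, "' in ", target)
      obj[[field]] <- value
      obj
    }
    switch(target,
           cytosol = conditions <- assign_field(conditions),
           init = init <- assign_field(init),
           flux = fluxes <- assign_field(fluxes),
           stop("unknown override target '", target,
                "' (use cytosol/init/flux)"))
  }
  list(init = init, conditions = conditions, fluxes = fluxes)
}

#' Run a battery of vesicle-loading scenarios
#'
#' Simulates each scenario against a common base configuration and tabulates
#' the steady-state glutamate content relative to the control scenario. A
#' scenario named `"control"` is required (or added automatically).
#' Scenarios that fail to reach steady state are flagged, not dropped.
#'
#' @param scenarios List of [scenario_spec()]; default [ischemia_scenarios()].
#' @param init,geom,params,conditions,fluxes Base configuration (defaults as
#'   in [simulate_vesicle()]).
#' @param ... Passed to [simulate_vesicle()] (e.g. `t_end`).
#' @return A data.frame with columns `name`, `steady_state_n_glut`,
#'   `relative_change` (scenario/control - 1), `steady_state_reached`.
#' @export
run_scenarios <- function(scenarios = ischemia_scenarios(),
                          init = luminal_init(), geom = vesicle_geometry(),
                          params = vesicle_params(),
                          conditions = cytosol_conditions(),
                          fluxes = default_flux_model(), ...) {
  names_ <- vapply(scenarios, function(s) s$name, character(1))
  if (!"control" %in% names_) {
    scenarios <- c(list(scenario_spec("control", list())), scenarios)
    names_ <- c("control", names_)
  }
  rows <- lapply(scenarios, function(s) {
    cfg <- .apply_overrides(s$overrides, init, conditions, fluxes)
    sim <- simulate_vesicle(init = cfg$init, geom = geom, params = params,
                            conditions = cfg$conditions, fluxes = cfg$fluxes,
                            ...)
    data.frame(name = s$name,
               steady_state_n_glut = if (sim$steady_state_reached)
                 sim$steady_state_n_glut else NA_real_,
               steady_state_reached = sim$steady_state_reached)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ctrl <- out$steady_state_n_glut[out$name == "control"][1]
  out$relative_change <- out$steady_state_n_glut / ctrl - 1
  out[, c("name", "steady_state_n_glut", "relative_change",
          "steady_state_reached")]
}
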