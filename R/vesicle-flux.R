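# Vesicular flux model.
#
# The rate equations for the luminal state need four transport pathways:
# VGLUT glutamate transport, chloride flux through the same transporter, a
# proton leak and the V-type ATPase. Their detailed kinetics are not part of
# this package's contract; a pluggable flux-model interface carries a
# shipped default with thermodynamically consistent forms: every pathway
# flux is driven by the deviation from its own electrochemical equilibrium
# and vanishes there.
#
# The default VGLUT law has three ingredients, each with a physiological
# counterpart: (i) a saturating glutamate/H+ antiport term (one glutamate
# anion in, one proton out per cycle) driven by membrane potential and the
# proton gradient; (ii) a small uncoupled glutamate slippage leak down the
# glutamate electrochemical gradient, which makes the steady state a
# pump-leak balance rather than a pure transporter equilibrium; and (iii) a
# cytosolic regulatory cation site: protons and Na+ inhibit transport
# competitively, K+ activates allosterically. The site gives the model its
# sensitivity to cytosolic pH, Na+ and K+ at steady state.
#
# Sign convention: all fluxes positive INTO the lumen, in mM/s of the
# transported species (luminal concentration change per second).

#' Construct the vesicular flux model
#'
#' Returns the flux model used by [simulate_vesicle()]. The default rate
#' constants are a fixed calibration chosen once so that, under control
#' conditions, luminal glutamate plateaus near 3500 molecules in a 20 nm
#' vesicle with an acidified lumen; they are not fits to experimental
#' vesicle data.
#'
#' @param k_vglut Maximal VGLUT antiport flux (mM/s).
#' @param kappa_vglut Saturation scale of the VGLUT drive (mV).
#' @param g_glut_leak Uncoupled glutamate slippage conductance (mM/s per mV
#'   of glutamate electrochemical driving force).
#' @param K_cat Half-inhibition constant of the cytosolic cation site (mM of
#'   proton-equivalents).
#' @param w_na Weight of Na+ relative to H+ at the cation site
#'   (dimensionless).
#' @param K_act Half-activation constant of the cytosolic K+ site (mM).
#' @param g_vglut_cl Chloride conductance of the transporter (mM/s per mV).
#' @param g_hleak Proton-leak conductance (mM/s per mV).
#' @param k_vatpase Maximal V-ATPase proton flux (mM/s).
#' @param dmu_atpase Proton-motive force at which the pump stalls (mV);
#'   the free energy of ATP hydrolysis over a fixed H+/ATP coupling ratio.
#' @param kappa_vatpase Saturation scale of the pump drive (mV).
#' @return An object of class `flux_model`.
#' @details All rate parameters must be non-negative; a zero rate switches
#'   its pathway off. The flux laws are evaluated by [vesicle_fluxes()].
#' @export
default_flux_model <- function(k_vglut = 8.0, kappa_vglut = 1,
                               g_glut_leak = 6.7e-3,
                               K_cat = 1e-4, w_na = 6e-6, K_act = 600,
                               g_vglut_cl = 0.006, g_hleak = 0.004,
                               k_vatpase = 2.04, dmu_atpase = 110,
                               kappa_vatpase = 10) {
  rates <- c(k_vglut = k_vglut, g_glut_leak = g_glut_leak,
             g_vglut_cl = g_vglut_cl, g_hleak = g_hleak,
             k_vatpase = k_vatpase)
  if (any(rates < 0)) stop("flux rate parameters must be non-negative")
  stopifnot(kappa_vglut > 0, kappa_vatpase > 0, dmu_atpase > 0,
            K_cat > 0, w_na >= 0, K_act >= 0)
  fm <- list(k_vglut = k_vglut, kappa_vglut = kappa_vglut,
             g_glut_leak = g_glut_leak, K_cat = K_cat, w_na = w_na,
             K_act = K_act, g_vglut_cl = g_vglut_cl, g_hleak = g_hleak,
             k_vatpase = k_vatpase, dmu_atpase = dmu_atpase,
             kappa_vatpase = kappa_vatpase)
  class(fm) <- "flux_model"
  fm
}

#' Zero flux model
#'
#' All rate parameters zero; [simulate_vesicle()] leaves the state constant.
#' Useful for conservation tests.
#' @return A `flux_model` with all rates zero.
#' @export
zero_flux_model <- function() {
  default_flux_model(k_vglut = 0, g_glut_leak = 0, g_vglut_cl = 0,
                     g_hleak = 0, k_vatpase = 0)
}

#' Evaluate the vesicular fluxes at a state
#'
#' Computes the instantaneous fluxes (mM/s, positive into the lumen) for a
#' luminal state, cytosolic conditions and membrane potential. Surface
#' charge is taken into account by Boltzmann-correcting the
#' membrane-adjacent concentrations entering the flux laws: luminal species
#' see the inner-leaflet potential, cytosolic species the outer-leaflet
#' potential (a -50 mV outer leaflet enriches cytosolic cations ~6.6-fold).
#'
#' @param pH_L,c_glut_L,c_cl_L Luminal state (pH and mM).
#' @param psi_mV Membrane potential (mV).
#' @param fluxes A `flux_model` from [default_flux_model()].
#' @param conditions A [cytosol_conditions()].
#' @param params A [vesicle_params()].
#' @return Named list with `J_vglut` (net transporter-mediated glutamate
#'   flux: antiport minus slippage), `J_vglut_coupled` (the proton-coupled
#'   antiport component alone), `J_vglut_cl`, `J_hleak`, `J_vatpase` (all
#'   mM/s) and the proton-motive force `dmu_H_mV` (lumen minus cytosol).
#' @export
vesicle_fluxes <- function(pH_L, c_glut_L, c_cl_L, psi_mV, fluxes,
                           conditions = cytosol_conditions(),
                           params = vesicle_params()) {
  Tk <- params$temperature_K
  Z <- nernst_slope(Tk, 1L)  # mV per decade, monovalent
  sc <- function(c, z, psi) surface_corrected_concentration(c, z, psi, Tk)

  # membrane-adjacent effective concentrations
  glut_c <- sc(max(conditions$c_glut_c_mM, 1e-9), -1, params$psi_out_mV)
  cl_c   <- sc(max(conditions$c_cl_c_mM, 1e-9),  -1, params$psi_out_mV)
  na_c   <- sc(conditions$c_na_c_mM,  +1, params$psi_out_mV)
  k_c    <- sc(conditions$c_k_c_mM,   +1, params$psi_out_mV)
  h_c    <- sc(.h_free_mM(conditions$pH_c), +1, params$psi_out_mV)
  pH_c_eff <- -log10(h_c * 1e-3)
  h_L    <- sc(.h_free_mM(pH_L), +1, params$psi_in_mV)
  pH_L_eff <- -log10(h_L * 1e-3)
  glut_L <- sc(max(c_glut_L, 1e-9), -1, params$psi_in_mV)
  cl_L   <- sc(max(c_cl_L, 1e-9),   -1, params$psi_in_mV)

  # proton-motive force, lumen minus cytosol (positive drives H+ out)
  dmu_H <- psi_mV + Z * (pH_c_eff - pH_L_eff)

  # VGLUT antiport: one glutamate anion in, one proton out; drive in mV is
  # minus the cycle free energy
  D_glut <- 2 * psi_mV -
    Z * (log10(glut_L / glut_c) + (pH_L_eff - pH_c_eff))
  # cytosolic regulatory site: H+/Na+ inhibit, K+ activates
  f_cat <- fluxes$K_cat / (fluxes$K_cat + h_c + fluxes$w_na * na_c)
  f_act <- if (fluxes$K_act > 0) k_c / (fluxes$K_act + k_c) else 1
  J_coupled <- fluxes$k_vglut * f_cat * f_act *
    tanh(D_glut / fluxes$kappa_vglut)

  # uncoupled glutamate slippage, down the glutamate electrochemical
  # gradient (positive drive = efflux)
  D_slip <- Z * log10(glut_L / glut_c) - psi_mV
  J_slip_out <- fluxes$g_glut_leak * D_slip

  # chloride through the transporter, down its electrochemical gradient
  D_cl <- psi_mV - Z * log10(cl_L / cl_c)
  J_vglut_cl <- fluxes$g_vglut_cl * D_cl

  # proton leak, down the proton-motive force
  J_hleak <- -fluxes$g_hleak * dmu_H

  # V-ATPase: pumps protons in, stalls when dmu_H reaches dmu_atpase
  J_vatpase <- conditions$atpase_scale * fluxes$k_vatpase *
    tanh((fluxes$dmu_atpase - dmu_H) / fluxes$kappa_vatpase)

  out <- list(J_vglut = J_coupled - J_slip_out,
              J_vglut_coupled = J_coupled,
              J_vglut_cl = J_vglut_cl, J_hleak = J_hleak,
              J_vatpase = J_vatpase, dmu_H_mV = dmu_H)
  if (any(!vapply(out, is.finite, logical(1))))
    stop("non-finite flux; state: pH_L=", pH_L, " glut=", c_glut_L,
         " cl=", c_cl_L, " psi=", psi_mV)
  out
}
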