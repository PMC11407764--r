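# Charge balance of the vesicle lumen.
#
# The membrane potential follows algebraically from the net luminal charge
# over the membrane capacitance,
#   psi = (F V / C) (H_L + K_L + Na_L - Cl_L - Glut_L - B),
# and B, the impermeant luminal charge, is fixed by requiring that the
# initial state produces psi(0) = psi_in - psi_out.

.h_free_mM <- function(pH) 10^(-pH) * 1e3

#' Impermeant luminal charge from the initial conditions
#'
#' Computes `B`, the concentration of impermeant luminal charges, by
#' conservation of charge at t = 0:
#' `B = H0 + K0 + Na0 - Cl0 - Glut0 - (C/(F V)) (psi_in - psi_out)`
#' (all terms in mM). `B` is computed once per simulation and held fixed.
#'
#' @param init A [luminal_init()].
#' @param geom A [vesicle_geometry()].
#' @param params A [vesicle_params()].
#' @return Impermeant charge concentration (mM, may be negative).
#' @export
impermeant_charge <- function(init = luminal_init(),
                              geom = vesicle_geometry(),
                              params = vesicle_params()) {
  B <- .h_free_mM(init$pH_L0) + init$c_k_L0_mM + init$c_na_L0_mM -
    init$c_cl_L0_mM - init$c_glut_L0_mM -
    (params$psi_in_mV - params$psi_out_mV) / geom$mV_per_mM
  if (!is.finite(B)) stop("impermeant charge is non-finite; check parameters")
  B
}

#' Vesicle membrane potential from a luminal state
#'
#' Evaluates the charge-balance membrane potential for explicit luminal
#' concentrations. Glutamate carries one negative charge; the proton term
#' `h_mM` is the charge-relevant proton concentration (free protons plus the
#' buffer-bound protons translocated since t = 0 -- see the package
#' vignette; at t = 0 it is simply the free `10^(-pH)` term).
#'
#' @param h_mM Charge-relevant luminal proton concentration (mM).
#' @param c_k_mM,c_na_mM,c_cl_mM,c_glut_mM Luminal concentrations (mM).
#' @param B Impermeant charge from [impermeant_charge()] (mM).
#' @param geom A [vesicle_geometry()].
#' @return Membrane potential in mV.
#' @export
membrane_potential <- function(h_mM, c_k_mM, c_na_mM, c_cl_mM, c_glut_mM, B,
                               geom = vesicle_geometry()) {
  psi <- geom$mV_per_mM * (h_mM + c_k_mM + c_na_mM - c_cl_mM - c_glut_mM - B)
  if (any(!is.finite(psi))) stop("membrane potential is non-finite")
  psi
}
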