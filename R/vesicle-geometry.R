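#' Synaptic vesicle geometry
#'
#' Builds the geometric description of a spherical vesicle from its radius
#' and specific membrane capacitance. Derived fields (volume, surface area,
#' total capacitance) are computed here once and reused by the charge-balance
#' and flux calculations.
#'
#' @param radius_nm Vesicle radius in nm (default 20).
#' @param specific_capacitance_uF_cm2 Membrane capacitance per area in
#'   uF/cm^2 (default 1).
#' @return An object of class `vesicle_geometry`: a list with `radius_nm`,
#'   `volume_L`, `surface_area_cm2`, `capacitance_F` and `mV_per_mM`, the
#'   membrane-potential increment per mM of net luminal charge
#'   (`F * V / C`, ~64 mV/mM for a 20 nm vesicle).
#' @export
vesicle_geometry <- function(radius_nm = 20, specific_capacitance_uF_cm2 = 1) {
  stopifnot(radius_nm > 0, specific_capacitance_uF_cm2 > 0)
  r_cm <- radius_nm * 1e-7
  volume_cm3 <- 4 / 3 * pi * r_cm^3
  surface_cm2 <- 4 * pi * r_cm^2
  cap_F <- specific_capacitance_uF_cm2 * 1e-6 * surface_cm2
  volume_L <- volume_cm3 * 1e-3
  g <- list(
    radius_nm = radius_nm,
    specific_capacitance_uF_cm2 = specific_capacitance_uF_cm2,
    volume_L = volume_L,
    surface_area_cm2 = surface_cm2,
    capacitance_F = cap_F,
    # psi [mV] = mV_per_mM * net charge [mM]; derivation:
    # Q = F * (c/1000) * V  (C), psi = Q/C (V), * 1000 -> mV
    mV_per_mM = .const$F * volume_L / cap_F
  )
  class(g) <- "vesicle_geometry"
  g
}

#' Fixed vesicle parameters
#'
#' Luminal buffering, surface-leaflet potentials, clamped luminal Na+/K+ and
#' temperature for the vesicle loading model. Luminal Na+ and K+ are treated
#' as clamped parameters (they start at extracellular-like values and are
#' held there); the flux model still senses their gradients.
#'
#' @param beta_pH_mM_per_pH Luminal pH-buffering capacity (mM of protons per
#'   pH unit, default 40).
#' @param psi_in_mV Inner-leaflet surface potential (default 0).
#' @param psi_out_mV Outer-leaflet surface potential (default -50).
#' @param c_k_L_mM,c_na_L_mM Clamped luminal K+ and Na+ (default 5, 145 mM).
#' @param temperature_K Temperature (default 307 K, ~34 C).
#' @return An object of class `vesicle_params`.
#' @export
vesicle_params <- function(beta_pH_mM_per_pH = 40, psi_in_mV = 0,
                           psi_out_mV = -50, c_k_L_mM = 5, c_na_L_mM = 145,
                           temperature_K = 307) {
  stopifnot(beta_pH_mM_per_pH > 0, temperature_K > 0,
            c_k_L_mM >= 0, c_na_L_mM >= 0)
  p <- list(beta_pH_mM_per_pH = beta_pH_mM_per_pH, psi_in_mV = psi_in_mV,
            psi_out_mV = psi_out_mV, c_k_L_mM = c_k_L_mM,
            c_na_L_mM = c_na_L_mM, temperature_K = temperature_K)
  class(p) <- "vesicle_params"
  p
}

#' Cytosolic (extravesicular) conditions
#'
#' Cytosolic concentrations facing the vesicle and the V-ATPase activity
#' scale. These are the knobs moved by the ischemia-like scenarios.
#'
#' @param pH_c Cytosolic pH (default 7.2).
#' @param c_glut_c_mM Cytosolic glutamate (default 10 mM).
#' @param c_cl_c_mM Cytosolic chloride (default 10 mM).
#' @param c_k_c_mM Cytosolic potassium (default 140 mM).
#' @param c_na_c_mM Cytosolic sodium (default 10 mM).
#' @param atpase_scale V-ATPase activity multiplier in `[0, 1]` (default 1);
#'   emulates reduced ATP availability.
#' @return An object of class `cytosol_conditions`.
#' @export
cytosol_conditions <- function(pH_c = 7.2, c_glut_c_mM = 10, c_cl_c_mM = 10,
                               c_k_c_mM = 140, c_na_c_mM = 10,
                               atpase_scale = 1) {
  stopifnot(c_glut_c_mM >= 0, c_cl_c_mM >= 0, c_k_c_mM >= 0, c_na_c_mM >= 0,
            atpase_scale >= 0, atpase_scale <= 1, pH_c > 0, pH_c < 14)
  x <- list(pH_c = pH_c, c_glut_c_mM = c_glut_c_mM, c_cl_c_mM = c_cl_c_mM,
            c_k_c_mM = c_k_c_mM, c_na_c_mM = c_na_c_mM,
            atpase_scale = atpase_scale)
  class(x) <- "cytosol_conditions"
  x
}

#' Luminal initial conditions
#'
#' The endocytosis-like start: the freshly retrieved vesicle lumen resembles
#' the extracellular solution (high chloride, neutral pH, negligible
#' glutamate).
#'
#' @param pH_L0 Initial luminal pH (default 7.2).
#' @param c_glut_L0_mM Initial luminal glutamate (default 0.001 mM = 1 uM).
#' @param c_cl_L0_mM Initial luminal chloride (default 110 mM).
#' @param c_k_L0_mM,c_na_L0_mM Initial luminal K+/Na+ (default 5, 145 mM);
#'   these also set the clamped values used throughout a run.
#' @return An object of class `luminal_init`.
#' @export
luminal_init <- function(pH_L0 = 7.2, c_glut_L0_mM = 0.001, c_cl_L0_mM = 110,
                         c_k_L0_mM = 5, c_na_L0_mM = 145) {
  stopifnot(pH_L0 > 0, pH_L0 < 14, c_glut_L0_mM >= 0, c_cl_L0_mM >= 0,
            c_k_L0_mM >= 0, c_na_L0_mM >= 0)
  x <- list(pH_L0 = pH_L0, c_glut_L0_mM = c_glut_L0_mM,
            c_cl_L0_mM = c_cl_L0_mM, c_k_L0_mM = c_k_L0_mM,
            c_na_L0_mM = c_na_L0_mM)
  class(x) <- "luminal_init"
  x
}

#' Convert a luminal concentration to a molecule count (and back)
#'
#' `molecules_from_concentration` maps mM to absolute molecule numbers in the
#' vesicle volume (`c * N_A * V`); `concentration_from_molecules` is the
#' exact inverse.
#'
#' @param c_mM Concentration in mM (non-negative).
#' @param n Molecule count (non-negative).
#' @param geom A [vesicle_geometry()].
#' @return Molecule count, or concentration in mM.
#' @examples
#' g <- vesicle_geometry()
#' molecules_from_concentration(173.45, g)  # ~3500 molecules
#' @export
molecules_from_concentration <- function(c_mM, geom = vesicle_geometry()) {
  if (any(c_mM < 0)) stop("concentration must be non-negative")
  c_mM * 1e-3 * .const$N_A * geom$volume_L
}

#' @rdname molecules_from_concentration
#' @export
concentration_from_molecules <- function(n, geom = vesicle_geometry()) {
  if (any(n < 0)) stop("molecule count must be non-negative")
  n / (1e-3 * .const$N_A * geom$volume_L)
}

#' Surface-potential correction of a membrane-adjacent concentration
#'
#' Boltzmann partitioning of an ion between the bulk phase and the charged
#' membrane leaflet: `c_mem = c_bulk * exp(-z F psi / (R T))`. Applied to the
#' concentrations that enter the flux laws (a -50 mV outer leaflet enriches
#' cations ~6.6-fold at 307 K and depletes anions by the same factor).
#'
#' @param c_bulk_mM Bulk concentration (mM).
#' @param valence Signed valence z.
#' @param psi_leaflet_mV Leaflet surface potential (mV).
#' @param temperature_K Temperature (K).
#' @return Membrane-adjacent concentration (mM).
#' @export
surface_corrected_concentration <- function(c_bulk_mM, valence,
                                            psi_leaflet_mV,
                                            temperature_K = 307) {
  stopifnot(temperature_K > 0)
  c_bulk_mM * exp(-valence * .const$F * psi_leaflet_mV * 1e-3 /
                    (.const$R * temperature_K))
}
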