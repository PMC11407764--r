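# Physical constants (CODATA), shared by all modules.
.const <- list(
  N_A = 6.02214076e23,   # Avogadro, 1/mol
  F   = 96485.33212,     # Faraday, C/mol
  R   = 8.31446262       # gas constant, J/(mol K)
)

#' Nernstian slope in mV per decade
#'
#' Returns the ideal electrode/thermodynamic slope `2.303 R T / (z F)` used
#' throughout the package: ion-selective electrode calibration and the
#' electrochemical driving forces of the vesicle flux model.
#'
#' @param temperature_K Absolute temperature in kelvin.
#' @param valence Signed ionic valence (non-zero integer).
#' @return Slope in mV per 10-fold concentration change.
#' @examples
#' nernst_slope(298.15, 1)  # ~59.2 mV
#' nernst_slope(307.15, 1)  # ~61.0 mV
#' @export
nernst_slope <- function(temperature_K, valence = 1L) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  if (!is.numeric(valence) || valence == 0)
    stop("valence must be a non-zero integer")
  log(10) * .const$R * temperature_K / (valence * .const$F) * 1000
}
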