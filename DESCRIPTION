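Package: synglu
Title: Simulation and Analysis of Synaptic Glutamate Signaling Under
    Metabolic Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying transient metabolic failure at hippocampal
    synapses. Provides a biophysical ODE model of glutamate accumulation in
    single synaptic vesicles (VGLUT transport, chloride shunt, proton leak
    and V-ATPase over a charge-balance membrane potential), a real-time
    iontophoresis (RTI) forward model and fitting routine for estimating
    extracellular-space volume fraction and tortuosity from TMA+ point-source
    transients, Nernst and Nicolsky-Eisenman calibration of ion-selective
    microelectrodes, extraction of fiber-volley and fEPSP metrics from
    paired-pulse field recordings with outcome classification, iGluSnFR
    line-scan processing (dF/F0, decay kinetics, paired-pulse ratio), and
    seeded synthetic-data generators emulating each recording modality so
    every analysis stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
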