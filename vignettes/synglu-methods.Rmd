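---
title: "Models and methods behind synglu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synglu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synglu)
```

`synglu` bundles the computational machinery needed to study how transient
metabolic failure (a few minutes of blocked ATP production) reshapes
glutamatergic transmission at hippocampal CA3–CA1 synapses: a biophysical
model of glutamate loading into single synaptic vesicles, the real-time
iontophoresis (RTI) method for extracellular-space (ECS) diffusion
parameters, ion-selective microelectrode calibration, field-potential sweep
metrics with outcome classification, and iGluSnFR line-scan kinetics. A
seeded synthetic-data layer emulates each recording modality so that every
analysis stage is testable end to end without experimental data. This
vignette states the models, their assumptions, the tunable parameters and
the numerical choices.

## 1. Vesicular glutamate loading

### State variables and charge balance

The model tracks a single spherical vesicle (radius 20 nm, specific
membrane capacitance 1 µF/cm²) with three dynamic luminal states: pH
$pH_L$, glutamate $[Glut]_L$ and chloride $[Cl^-]_L$ (mM). Luminal K⁺ and
Na⁺ start at extracellular-like values (5 and 145 mM, the composition of
the freshly endocytosed lumen) and are held clamped; the cytosolic bath is
fixed at pH 7.2, 10 mM glutamate, 10 mM Cl⁻, 140 mM K⁺, 10 mM Na⁺.

The membrane potential follows algebraically from the net luminal charge
over the capacitance,

$$\Delta\psi = \frac{F\,V}{C}\,\bigl([H^+]_L + [K^+]_L + [Na^+]_L -
[Cl^-]_L - [Glut]_L - B\bigr),$$

where $B$, the impermeant luminal charge, is fixed at $t=0$ so that
$\Delta\psi(0) = \psi_{in}-\psi_{out} = +50$ mV, the difference of the
leaflet surface potentials (0 and −50 mV). For a 20 nm vesicle
$FV/C \approx 64$ mV per mM of net charge, so only ~mM-scale net charge
displacements are possible at physiological potentials.

**Proton bookkeeping.** Luminal pH is buffered with capacity
$\beta_{pH} = 40$ mM/pH: translocating $J$ mM/s of protons changes pH at
$-J/\beta_{pH}$. Crucially, a pumped proton that binds to the buffer still
carries its charge across the membrane. The charge-relevant proton pool in
the potential equation is therefore the *translocated* pool,
$[H^+]_L = 10^{3-pH_L} + \beta_{pH}(pH_{L,0} - pH_L)$, not the free
concentration alone. This identity is exact here because every proton
pathway in the shipped flux model is electrogenic. It is what allows the
lumen to accumulate ~170 mM of glutamate anions: the ~60–70 mM of
buffer-bound proton charge gained during acidification, plus the chloride
lost, make the anion room. With free protons alone the loading capacity
would be capped by the initial chloride content. A corollary is that the
initial luminal pH leaves a lasting imprint on the charge budget — an
acidified endocytosed lumen (the "low extracellular pH" scenario) has less
proton charge left to gain and loads less.

### Flux model

The transport laws are deliberately pluggable
(`default_flux_model()` constructs the parameter set, `vesicle_fluxes()`
evaluates it); the shipped default uses thermodynamically consistent forms
in which each pathway is driven by the deviation from its own
electrochemical equilibrium and vanishes there. Concentrations entering
the flux laws are Boltzmann-corrected to the membrane-adjacent values
(`surface_corrected_concentration()`): the −50 mV outer leaflet enriches
cytosolic cations ≈ 6.6-fold at 307 K and depletes anions by the same
factor; the 0 mV inner leaflet leaves luminal values unchanged.

* **V-ATPase** pumps protons into the lumen with a saturating drive,
  $J = s\,k_V \tanh[(\Delta\mu_{stall}-\Delta\mu_H)/\kappa_V]$, where
  $\Delta\mu_H = \Delta\psi + Z(pH_c - pH_L)$ is the proton-motive force
  (mV; $Z = \ln 10\,RT/F \approx 61$ mV), $s \in [0,1]$ is the
  `atpase_scale` knob emulating ATP depletion, and the stall force is 110
  mV with a sharp 10 mV saturation scale. The sharp stall pins
  $\Delta\mu_H$ near a set point, which makes the proton subsystem stiff
  against perturbations — a property the scenario behaviour relies on
  (below).
* **Proton leak** is ohmic in the proton-motive force,
  $J = -g_H\,\Delta\mu_H$.
* **VGLUT** exchanges one luminal proton for one cytosolic glutamate
  anion. Its drive is minus the cycle free energy,
  $D = 2\Delta\psi - Z[\log_{10}([Glut]_L/[Glut]_c) + (pH_L - pH_c)]$,
  and the flux is $J = k_G\,f_{cat}\,f_{K}\tanh(D/\kappa_G)$ with a very
  steep saturation scale $\kappa_G = 1$ mV: the transporter behaves as a
  flux-limited switch that runs at its regulated maximum whenever loading
  is thermodynamically downhill. Two regulatory factors implement the
  transporter's documented sensitivity to the cytosolic milieu: a
  cytosolic cation site at which protons and Na⁺ compete as inhibitors,
  $f_{cat} = K_{cat}/(K_{cat} + [H^+]_c + w_{Na}[Na^+]_c)$, and an
  activating K⁺ site, $f_K = [K^+]_c/(K_{act} + [K^+]_c)$.
* **Glutamate slippage** is a small uncoupled leak of glutamate down its
  electrochemical gradient through the transporter,
  $J_{out} = g_{slip}\,[Z\log_{10}([Glut]_L/[Glut]_c) - \Delta\psi]$. It
  turns the steady state into a pump–leak balance instead of a pure
  transporter equilibrium — without it, steady-state loading would be a
  purely thermodynamic quantity and no kinetic regulation (ATP depletion,
  cation-site occupancy) could influence it.
* **Chloride** permeates the transporter ohmically down its
  electrochemical gradient, $J = g_{Cl}[\Delta\psi -
  Z\log_{10}([Cl]_L/[Cl]_c)]$.

The rate equations are then
$d[Glut]_L/dt = J_{VGLUT}$ (net: antiport minus slippage),
$d[Cl^-]_L/dt = J_{VGLUT_{Cl}}$, and
$dpH_L/dt = -(J_{H^+} + J_{VATPase} - J_{VGLUT,coupled})/\beta_{pH}$
(the antiport exports protons, so coupled loading alkalinizes), with
$\Delta\psi$ recomputed algebraically at every evaluation.

### Calibration and scenario behaviour

The rate constants are a fixed calibration, chosen once so that the
control run plateaus close to 3500 glutamate molecules
(≈ 173 mM in a 20 nm vesicle) with an acidified lumen (pH ≈ 5.4,
$\Delta\psi \approx +45$ mV, Cl⁻ ≈ 8 mM), and so that the approach to
steady state completes comfortably within the default 3000 s integration.
They are not fits to experimental vesicle data and the model makes no
claim to reproduce any particular published kinetic scheme.

Three structural choices were needed to make the single-parameter
ischemia-like scenarios move the steady state in the physiologically
expected directions (`run_scenarios()`, `ischemia_scenarios()`):

1. the glutamate slippage leak, so transporter kinetics shape the steady
   state at all;
2. the steep VGLUT voltage saturation, so the transporter is flux-limited
   at steady state and changes of its regulated maximum propagate into the
   loading level instead of being absorbed by a shift of the operating
   point on the drive curve;
3. the stiff (near-stall) V-ATPase, so the proton-motive force does not
   drift and silently compensate the perturbation.

With the shipped calibration, cytosolic acidification (7.2 → 6.8), raised
cytosolic Na⁺ (10 → 30 mM), raised cytosolic Cl⁻ (10 → 20 mM), lowered
cytosolic K⁺ (140 → 100 mM), an acidified endocytosed lumen (7.2 → 6.9)
and halved V-ATPase activity each lower the steady-state count, while
cytosolic alkalinization (7.2 → 7.4) raises it by ~3%. The scenario
magnitudes are representative values for acute metabolic failure, chosen
once; they are configuration, not claims. With the pump disabled entirely
(`atpase_scale = 0`) loading falls to ~850 molecules; note that in this
regime the shipped model's lumen *alkalinizes* (the antiport exports
protons and the leak equilibrates the proton-motive force), so the reduced
loading — not an acidification — is the robust prediction.

### Numerics

`simulate_vesicle()` integrates with `deSolve::lsoda` at `rtol = 1e-8`,
`atol = 1e-10` on a 1 s output grid to `t_end = 3000` s. Steady state is
declared when the fitted relative drift of the molecule count over the
trailing 10 s window falls below $10^{-6}$ per second;
`steady_state_glutamate()` then averages that window and errors otherwise.
Halving the tolerances or doubling `t_end` moves the reported count by
less than 0.1%. Identical configurations give bit-identical trajectories.

## 2. ECS diffusion by real-time iontophoresis

A TMA⁺ point source (iontophoresis current $I = 100$ nA for 30 s,
transport number $n_t = 0.3$, molar rate $Q = I n_t/F$) diffuses through
the ECS, modelled as a porous medium with volume fraction $\alpha$,
effective diffusion coefficient $D^*$ and optional first-order clearance
$k'$. During the pulse the concentration in the ECS at distance $r$ is

$$C(r,t) = \frac{Q}{8\pi D^* \alpha r}\left[
e^{r\sqrt{k'/D^*}}\,\mathrm{erfc}\!\Bigl(\tfrac{r}{2\sqrt{D^* t}} +
\sqrt{k' t}\Bigr) +
e^{-r\sqrt{k'/D^*}}\,\mathrm{erfc}\!\Bigl(\tfrac{r}{2\sqrt{D^* t}} -
\sqrt{k' t}\Bigr)\right],$$

and after the pulse the trace is the exact superposition
$C_{on}(t) - C_{on}(t-T)$. With $k' = 0$ this reduces to the familiar
erfc solution approaching $Q/(4\pi D^* \alpha r)$; for the default source
at 150 µm with $D^* = 5\times10^{-6}$ cm²/s and $\alpha = 0.2$ that
plateau is ≈ 1.65 mM. The tests verify the closed form against an
independently written radial finite-volume solver to better than 1% over
$\alpha \in \{0.1, 0.2, 1\}$, $\lambda \in \{1, 1.6, 2\}$,
$k' \in \{0, 0.005\,\mathrm{s^{-1}}\}$.

`fit_rti()` fits $(\alpha, D^*)$ — and optionally $k'$ — by bounded
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`), multi-started
from three coarse grid points with the lowest residual norm winning;
bounds are $0 < \alpha \le 1$, $0 < D^* \le D$. Tortuosity is derived as
$\lambda = \sqrt{D/D^*}$. Design choices and caveats:

* The free-medium diffusion coefficient of TMA⁺ is configuration
  (default $1.31\times10^{-5}$ cm²/s, appropriate near 34 °C); reported
  $\lambda$ scales as $\sqrt{D}$, so a mis-set $D$ biases tortuosity but
  not the fitted $D^*$.
* Clearance defaults to 0 and is excluded from fitting unless requested.
* The iontophoresis transport number is a required input for absolute
  $\alpha$ accuracy; a mismatch between the true and assumed transport
  number scales the fitted $\alpha$ inversely.
* Distances are µm at the interface and centimetres internally; all
  diffusion math is CGS. Curves are stored above-baseline, or as absolute
  concentrations with the recorded 1 mM bath baseline subtracted before
  fitting.

## 3. Ion-selective electrodes

Calibration against concentration standards uses either the Nernst model
$V = E_0 + S\log_{10} c$ or the Nicolsky–Eisenman form
$V = E_0 + S\log_{10}(c + c_{int})$, in which a single lumped
interfering-background term $c_{int}$ captures the departure from
Nernstian behaviour in the low sub-millimolar range (per-ion selectivity
coefficients are intentionally not resolved — calibration solutions vary
one ion at a time, so only the lumped term is identifiable). The ideal
slope is $2.303\,RT/zF$ (`nernst_slope()`: 59.2 mV/decade at 25 °C, 61.0
at 34 °C). Activities are approximated by concentrations throughout,
matching how the standards are made. Conversion of voltage traces inverts
the calibration analytically, flooring physically impossible negative
concentrations at zero with a warning count. Electrode acceptance follows
the decade rule: a 10-fold concentration step must produce strictly more
than 50 mV (`electrode_qc()`). K⁺ transients are quantified as the
baseline-subtracted maximum inside the insult window, with the baseline
taken over the preceding 60 s (`max_delta()`).

## 4. Field-potential sweeps and outcome classification

Paired-pulse extracellular sweeps (10 kHz, two stimuli 50 ms apart) are
decomposed per pulse: the stimulus artifact is blanked (default 0.5 ms),
the fiber volley is the first negative deflection in a 0.5–3 ms
post-stimulus window (amplitude baseline-to-trough; half width by linear
interpolation at the half-amplitude crossings; delay stimulus-to-trough),
and the fEPSP initial slope is a straight-line fit over the samples
between 20% and 80% of the baseline-to-peak amplitude on the rising limb,
reported as a positive magnitude in mV/ms. The 20–80% window and the
search windows are configuration: the underlying acquisition conventions
vary between laboratories, and all of them are exposed as arguments.
Deflections within 3× the median absolute deviation of the pre-stimulus
baseline are treated as absent (missing fiber volley; zero slope with a
low-confidence flag).

Experiment timelines (one sweep per 20 s) are normalized metric-wise to
the 0–10 min baseline epoch mean, making the baseline mean exactly 1.
The outcome rule operates on the end-epoch mean (default: the final 10
min, configurable because protocols of different lengths use different
windows) of the normalized fEPSP slope: an episode is a postsynaptic
*failure* when that mean does not recover to strictly above 50% of
baseline, and *recovered* otherwise. The rule is deliberately exactly
this threshold comparison — `classify_outcome()` contains no other
heuristics.

## 5. iGluSnFR line scans

Repeats (4–6 per time point) are averaged element-wise first; the signal
is the ROI row-mean minus the background ROI row-mean; $F_0$ is the
pre-stimulus mean; the transient is $\Delta F/F_0$. A non-positive $F_0$
raises an unusable-scan error (the real-world counterpart: indicator
fluorescence lost after severe insults). Per-pulse peaks are maxima in a
30 ms post-stimulus window of the averaged trace. Decay kinetics come from
a mono-exponential least-squares fit $A e^{-t/\tau} + c$ starting at the
post-peak sample (default: of the second pulse) over a 500 ms window; the
offset is fitted, not fixed, because slow baseline drifts otherwise bias
$\tau$. Fits outside (1 ms, 10 s) or non-converged fits are flagged. For
the paired-pulse ratio the second peak is measured above the extrapolated
exponential tail of the first pulse — at 50 ms separation the first
transient ($\tau \approx 40$ ms) still contributes ≈ 30% of its peak.

## 6. Synthetic data

Each generator emits its exact ground truth beside the data and is
bit-deterministic in its seed (the caller's RNG state is preserved):

* `gen_calibration_points()` — forward calibration model plus additive
  Gaussian voltage noise (0.5 mV default).
* `gen_tma_curve()` — RTI forward trace with 2% multiplicative Gaussian
  noise on a 1 mM bath baseline; `tissue_scenario()` provides the
  acute-slice ground truth ($\alpha = 0.19$, $\lambda = 1.54$) and the
  agarose-like free medium ($\alpha = 1$, $\lambda = 1$).
* `gen_sweep()` — biphasic artifact + Gaussian fiber volley +
  alpha-function fEPSP (pulse 2 scaled by the programmed paired-pulse
  ratio) + additive noise; the ground truth includes the analytic 20–80%
  band slope of the alpha function.
* `gen_experiment()` — per-sweep metric timelines following scenario
  templates: `control` (flat), `ischemia` (transient collapse, full
  fiber-volley recovery, late potentiation ×1.3), `ischemia_failure`
  (fiber volley recovers, fEPSP pinned at 5% residual), with 3%
  multiplicative per-sweep noise, plus a matching K⁺ transient (larger
  surge in the failure scenario).
* `gen_linescan()` — position × time arrays at 378.8 Hz with
  stimulus-locked mono-exponential transients, per-pixel Gaussian noise,
  an additive background and an optional multiplicative resting-
  fluorescence decline emulating bleaching.
* `gen_k_trace()` — saturating-rise/exponential-decay K⁺ transient
  confined to the insult window, optionally passed through a forward
  electrode calibration to the voltage domain.

The templates are phenomenological: they emulate the *statistical
structure* each analyzer assumes (noise models are the simplest consistent
ones — additive for voltages, multiplicative for tracer concentrations,
per-pixel Gaussian for fluorescence), not the biophysics of ischemic
tissue. There is no spreading-depolarization model, no indicator-binding
kinetics, no stimulus-artifact physics. Scenario effect magnitudes
(potentiation 1.3, failure residual 0.05, K⁺ peaks 5/10 mM) are defaults
chosen well inside the classifier margins and are explicitly not claims
about experimental effect sizes. Passing round-trip tests therefore
demonstrates correctness of the analysis chain under these assumptions,
not robustness to every artifact real recordings can contain.

## 7. Test problem sizes

The shipped test-suite sizes were chosen to exercise every property at
desk scale: one 3000 s control integration plus an eight-scenario battery
for the vesicle model; an 18-point forward-model grid against the
finite-volume oracle; 100 seeded noisy RTI curves for recovery statistics;
50 seeds × three decay constants for $\tau$ bias; 20 seeds × three
scenarios for the outcome classifier. The whole suite runs in well under
two minutes on one core.

## 8. Known limitations

* The vesicle flux laws are a calibrated default behind a stable
  interface, not a reproduction of any specific published kinetic model;
  quantitative scenario effect sizes depend on that calibration, only the
  signs are asserted.
* Luminal Na⁺/K⁺ are clamped; the K⁺/Na⁺-dependence of loading is carried
  entirely by the cytosolic regulatory site. A dynamic luminal cation mode
  would require additional, experimentally unconstrained permeabilities.
* The RTI model assumes an ideal point source in an isotropic medium: no
  electrode-geometry or finite-source corrections, no anisotropy, no
  dual-probe methods.
* Electrode activities are approximated by concentrations; junction
  potentials and drift beyond the linear baseline handling are not
  modelled.
* Sweep decomposition assumes the canonical artifact → fiber volley →
  fEPSP ordering; heavily overlapping components (e.g. very short-latency
  fEPSPs) will bias the 20–80% slope window.
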