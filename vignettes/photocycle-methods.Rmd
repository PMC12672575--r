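---
title: "Modeling RSFP photoswitching fatigue: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling RSFP photoswitching fatigue: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfatigue)
```

## The kinetic model

Reversibly switchable fluorescent proteins (RSFPs) such as rsEGFP2 are
negative photoswitchers: 488 nm light both excites fluorescence and
drives the emissive *cis* anionic chromophore (`C_MINUS`) to the dark
*trans* neutral off state (`TH`), while 405 nm light drives the reverse,
off-to-on transition. Repeated on-off cycling progressively loses
fluorescence — photoswitching fatigue — through a combination of
reversible dark-state population and irreversible photobleaching.

The package models the chromophore as an eight-state continuous-time
linear kinetic system:

* `C_MINUS` — *cis* anionic, emissive on state (thermodynamically
  stable);
* `C_INT` — an on-like, emissive intermediate of the on-switching
  cascade with a millisecond lifetime;
* `CH` — *cis* neutral, the immediate product of trans-to-cis
  photoisomerization, deprotonating quickly to `C_INT`;
* `TH` — *trans* neutral off state;
* `T_ANION` — *trans* anionic ground-state intermediate of
  off-switching, protonating to `TH` with a ~50 µs characteristic time
  at physiological pH;
* `T1` — the lowest triplet state, fed by intersystem crossing (ISC)
  from the excited on state;
* `D_REV` — a long-lived reversible dark photoproduct seeded by the
  triplet;
* `BLEACHED` — an absorbing sink for irreversible photodestruction.

Excited singlet and upper triplet states live for nanoseconds or less,
far below any illumination window used in switching experiments, so they
are adiabatically eliminated: a photon absorption maps directly onto
per-absorption branching yields between the ground and metastable
states. This keeps the generator linear and free of stiff excited-state
dynamics.

The wiring is:

* off-switching: `C_MINUS` --(488, `phi_off`)--> `T_ANION`
  --(`k_prot`)--> `TH`; each `C_MINUS` absorption also branches to `T1`
  with the ISC yield `phi_isc` and to `BLEACHED` with a small direct
  yield;
* on-switching: `TH` --(405, `phi_on`)--> `CH` --(`k_deprot`)-->
  `C_INT` --(`k_int`, ~1 ms)--> `C_MINUS`; 405 nm absorption by `C_INT`
  drives it back to `TH` (`phi_int_off`) or destroys it
  (`phi_int_bleach`, the on-switching-path bleaching channel);
* the intermediate under excitation light: `C_INT` is an anionic,
  emissive form, so its 488 nm photochemistry mirrors the on state
  (same `phi_off`, `phi_isc` and direct-bleach yields per absorption).
  Without this the intermediate would act as an unswitchable emitter
  that dominates any readout overlapping its lifetime, which is
  inconsistent with the observed second-pulse recovery kinetics;
* triplet: `T1` absorbs at every supported wavelength (405, 488, 592,
  810, 900, 915 nm) with a spectrum peaking in the near infrared; per
  absorption it returns to `C_MINUS` by optically driven reverse
  intersystem crossing (`phi_risc`) or bleaches (`phi_tn`). Thermal
  `T1` decay (lifetime `tau_t`) branches to `C_MINUS`, to the dark
  product `D_REV` (`f_drev`) and to `BLEACHED` (`phi_t1`);
* dark product: `D_REV` relaxes thermally back to `C_MINUS`
  (`k_drev`); while populated it is photolabile, converting to
  `BLEACHED` per 488 nm absorption with yield `phi_drev_bleach`. This
  secondary photo-destruction encodes the observation that the
  triplet-seeded long-lived photoproducts have both reversible and
  irreversible consequences: light arriving before the dark product has
  relaxed destroys part of it, which is why lengthening the inter-cycle
  dark dwell recovers signal beyond the standing dark-state population
  alone.

Within one illumination window the laser set is constant, so the
populations obey `dP/dt = K P` with a fixed generator `K` and can be
propagated exactly. The propagator uses the spectral decomposition of
`K`; when the eigenvector matrix has a 1-norm condition number above
1e12 it falls back to a scaling-and-squaring matrix exponential
(`Matrix::expm`), with the window integral obtained from the standard
augmented-matrix construction. Per-cycle integrated fluorescence is
computed analytically from the same decomposition
(`(exp(lambda*T)-1)/lambda` applied in the eigenbasis), never by
quadrature, so results are independent of the trajectory sampling
density. Populations are clipped at `-1e-12` and renormalized;
anything more negative raises an error.

## Parameters, units and the shipped calibration

Internally: seconds, W/cm², cm², nm. Pulse-scheme configs accept ms/µs
and kW/cm² with mandatory explicit units.

The shipped default set, `rsEGFP2-default-v1`
(`inst/extdata/params/`), was produced by the staged calibration that
`calibrate_model()` exposes, anchored to fixed literature-style values
where available and to the measured switching observables otherwise:

1. `sigma.C_MINUS.488 = 2.34e-16` cm² (from the on-state molar
   absorption of rsEGFP2), `k_prot = 2e4`/s (50 µs protonation),
   `k_int = 1e3`/s (1 ms intermediate lifetime), `k_deprot = 2e5`/s
   (fast), `phi_on = 0.33` are fixed inputs.
2. `phi_off` is calibrated so that 488 nm at 300 W/cm² off-switches the
   fluorescence to 20% in 0.9 ms, the calibrated dose of the
   per-variant comparison.
3. `phi_int_off` (together with `sigma.C_INT.405`) is calibrated so a
   1 ms, 160 W/cm² on-switching pulse from a fully off pool leaves 20%
   of the population trapped in `TH`, the expected photostationary
   trans-neutral fraction at pH 7.5.
4. `f_drev`, `k_drev` and `phi_drev_bleach` are calibrated jointly so
   that (i) extending the inter-cycle dwell from 10 to 100 ms recovers
   20 percentage points of fluorescence loss after 1600 cycles and
   (ii) the 20 ms entry of the constant-dose stretched-activation
   series loses 7% relative to the 488-only reference. The resulting
   dark-product lifetime is ~110 ms.
5. `tau_t` is calibrated so the mono-exponential rise fitted to the
   simulated two-pulse delay scan returns 2.46 ms. The effective
   `tau_t` (1.40 ms) is shorter than the fitted rise because the slow
   dark-product component biases a single-exponential fit upward; it is
   an effective parameter of the reduced scheme, not a direct triplet
   lifetime measurement.
6. `sigma.T1.592` and `sigma.T1.915` are calibrated from the
   recovery-versus-power saturation constants (1.33 and 0.42 kW/cm²);
   `sigma.T1.900` is five times the 592 nm value, encoding the report
   that the triplet absorption at 592 nm is ~20% of its near-infrared
   peak, and 810 nm matches 592 nm.
7. `phi_t1` is calibrated so the maximum 592 nm co-illumination
   recovery over the 0.5–8 kW/cm² sweep is 14 percentage points,
   consistent with the measured "up to ~15%" while remaining below it.

Per-variant sets (`variant_params()`) are derived, synthetic
illustrations: they scale `phi_off`, `phi_on`, brightness and bleach
yields so that slower switchers (rsEGFP(N205S), rsGreen1) fatigue more
and faster ones (rsGreenF, Dronpa(M159T)) less, and so the four-class
multiplexing demonstration is separable. They are labeled
`*-derived-v1` and are not fitted to per-variant measurements.

## Protocol defaults

The experimental protocols are data (`pulse_scheme` objects), with
defaults chosen once:

* standard fatigue cycle: 405 nm, 1 ms at 160 W/cm²; 488 nm, 0.9 ms at
  300 W/cm²; 10 ms dark dwell (the typical dwell of the fatigue
  measurements);
* dwell-time experiment: same cycle, dwell varied (10 vs 100 ms for the
  headline comparison at 1600 cycles);
* co-illumination recovery sweeps and the stretched-activation series
  use a 100 ms inter-cycle dwell. Rationale: with the typical 10 ms
  dwell a substantial reversible dark-product population is standing at
  every cycle; a dwell long relative to the dark-product lifetime lets
  it relax between cycles, so the measured recovery isolates the
  irreversible triplet-mediated component (the quantity the saturation
  fits parameterize) and consecutive stretched-activation cycles probe
  the on-switching response rather than dark-state accumulation;
* co-illumination spans 1 ms starting with the 488 nm pulse (0.9 ms
  overlapped, 0.1 ms co-illumination only), matching the simulated
  recovery protocol;
* two-pulse scan: 5 µs 405 nm burst at 30 kW/cm², 3 ms dark, two
  500 µs 488 nm pulses at 40 kW/cm² separated by a variable delay;
  twenty log-spaced delays between 5 µs and 500 ms
  (`default_twopulse_delays()`); the second-pulse integral is
  normalized to a zero-delay control;
* stretched activation: total 405 nm dose fixed at 64 mJ/cm², power set
  by `dose/time`; one 488-only reference cycle followed by 25 on-off
  cycles, reporting the mean of cycles 2–21 (skipping the first-cycle
  transient) normalized to the reference.

The fatigue metrics follow fixed conventions: the initial drop is
`1 - F(2)/F(1)` (configurable window), the fatigue fraction is
`1 - F(2000)/F(4)`; shorter curves report over the available range with
an explicit `truncated` flag. Recovery is the difference of mean
fluorescence losses (control minus treated) with uncertainty
`sqrt(sigma_c^2 + sigma_t^2)`.

## Numerical choices

* Off-switch-to-20% calibration: bracketing by doubling, then bisection
  to 1e-4 relative tolerance, capped at 10 s of simulated time.
* Exponential and saturation fits: Levenberg-Marquardt
  (`minpack.lm::nlsLM`) with data-driven starting values (half-range
  crossing for the time constant) and two fallback starts;
  non-convergent or flat data are flagged, never reported as estimates.
  Box constraints are avoided because they destabilize the gradient at
  the start; positivity is effectively maintained by the starts.
* `calibrate_model()`: derivative-free simplex (Nelder-Mead; Brent for
  a single parameter) on log-transformed parameters with five seeded
  restarts (seed 1234) and an identifiability pre-check — a 1%
  parameter bump must move the predictions by more than 1e-8
  relatively, otherwise the parameter is rejected by name.
* The two-class rate threshold in `offswitch_classify()` is the
  midpoint of a two-component 1-D Gaussian EM fit; the split is flagged
  degenerate when the bimodality index (Ashman's D) is below 4 or one
  component captures less than 10% of the objects.
* Within-window trajectory output defaults to 64 samples per window;
  end-of-window states and integrated fluorescence are exact
  regardless.

## The synthetic data generator

The generator emulates everything the analyses consume: noisy replicate
fatigue curves (Poisson shot noise at a configurable photon budget plus
Gaussian read noise, reported in camera counts), and bacteria image
stacks — hard-edged random rods with a 1 px Gaussian blur standing in
for the point-spread function, per-object brightness jitter,
non-overlapping placement by rejection sampling, and per-frame object
intensities obtained by simulating each class's photocycle through the
full acquisition history (so photobleaching, dose response and
co-illumination effects propagate into the images). Ground truth (label
mask, class table, noiseless traces, seed) is always returned with the
data; identical seeds give byte-identical outputs.

It deliberately omits: optical diffraction (beyond the 1 px blur),
camera fixed-pattern noise, sample drift and registration errors,
within-object expression heterogeneity, and pixel-level photophysics
(bleaching is tracked per object ensemble). Passing the pipeline tests
on this data therefore demonstrates the correctness of the feature
algebra, classifier and protocol plumbing — not robustness to the
registration and segmentation artifacts of real microscope data.

The four-dose multiplexing acquisition uses 405 nm doses of 0.05, 0.15,
0.5 and 2 ms at 160 W/cm² (the largest, saturating dose is the
normalizer frame), 15 repeats for 60 frames. The decay time-lapse uses
a weak per-frame re-activation (30 µs at 160 W/cm²) before each 0.4 ms,
300 W/cm² readout: the across-frame trace then decays toward a
re-activation/off-switching quasi-steady state at a rate set by the
class's off-switching yield (the classification signature), while
bleaching accumulates across the 50 frames, so 592 nm co-illumination
visibly reduces the measured loss.

## Problem sizes

The shipped experiments use the sizes of the protocols they model:
2000-cycle fatigue runs for the recovery sweeps (seven powers per
wavelength plus a shared control), 1600 cycles for the dwell
comparison, 25-cycle series for stretched activation, 60- and 50-frame
stacks for the unmixing pipelines, and 96×96 px scenes with 8–12
objects per class. Per-window propagation operators are compiled once
per illumination set, so a 2000-cycle experiment is a loop of 8×8
matrix-vector products and runs in tens of milliseconds.

## Known limitations

* The model is an effective, reduced scheme: no explicit excited
  states, no radical intermediates, no pH titration (pH 7.5 behavior is
  baked into the rates), no vibronic structure. Parameters tied to
  eliminated states (e.g. `tau_t`, the per-absorption triplet yields)
  are effective quantities and should not be read as direct
  spectroscopic measurements.
* 592 nm is assumed not to excite the on state
  (`sigma.C_MINUS.592 = 0`); any real crosstalk would add a bleaching
  contribution at high co-illumination powers that the default set does
  not model. The cross-section table is configurable if a value becomes
  available.
* The on-switching cascade is truncated to one `CH` and one `C_INT`
  intermediate — the minimal reading of the published scheme; faster
  intermediates are absorbed into `k_deprot`.
* Ensemble (rate-equation) propagation assumes independent, identical
  molecules; single-molecule blinking statistics beyond the mean are
  out of scope (the test suite's Gillespie simulator is an oracle for
  the ensemble mean, not a feature).
* Per-variant parameter sets are qualitative, derived illustrations
  (see above), adequate for the multiplexing demonstrations but not
  for quantitative per-variant predictions.
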