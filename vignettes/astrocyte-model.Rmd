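---
title: "Modeling calcium signaling and gliotransmitter release in an astrocytic process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling calcium signaling and gliotransmitter release in an astrocytic process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliosim)
```

## The system being modeled

A perisynaptic astrocytic process is a sub-micron compartment wrapped
around a synapse. It carries group-1 metabotropic glutamate receptors
(mGluRs) facing the synaptic cleft, a thin tongue of endoplasmic reticulum
(ER) carrying a small cluster of IP~3~ receptor channels (IP~3~Rs), SERCA
pumps refilling the ER, PMCA pumps extruding Ca^2+^ across the plasma
membrane, and mobile Ca^2+^ buffers in both cytosol and ER lumen. Synaptic
glutamate (or a bath agonist such as DHPG) activates the mGluRs, producing
IP~3~; stochastic opening of the small IP~3~R cluster then releases ER
Ca^2+^ in fast, high-amplitude, strongly fluctuating transients. These
transients drive a vesicular release machine with two Ca^2+^ sensors:
synaptotagmin-4 (one fast, low-affinity site, operational k~d~ ≈ 22 µM)
triggering kiss-and-run (KR) release of docked vesicles, and
synaptotagmin-7 (five slow, high-affinity sites, operational k~d~ ≈ 15 µM)
triggering full-fusion (FF) release of mobile vesicles. Released vesicles
are endocytosed, reacidified into the mobile pool, and re-docked at a
finite rate, so the docked pool is a scarce, slowly renewed resource.

Amyloid-beta (Aβ) pathology is represented purely as two parameter
transforms: enhanced mGluR signaling (half-activation halved, maximal IP~3~
production doubled) and impaired PMCA function (backward rate scaled so the
pump's fitted Ca^2+^ affinity falls by half). The package asks what these
molecular changes do to microdomain Ca^2+^ events, to KR/FF release, and to
the temporal correspondence between them.

## Model structure

### Continuous signaling core

Five continuous variables evolve by mass-action fluxes (all concentrations
in µM, rates in µM/s): cytosolic Ca^2+^, ER Ca^2+^, IP~3~, and the
buffer-bound Ca^2+^ in cytosol and ER. The fluxes are

* IP~3~R channel flux `v_ip3r * n_open * (Ca_ER - Ca_cyt)` plus a passive
  ER leak `v_er_leak * (Ca_ER - Ca_cyt)`;
* SERCA uptake, a Hill function of cytosolic Ca^2+^ with slope 2;
* PMCA extrusion from a one-site cycle,
  `v_pmca * kf * Ca / (kf * Ca + kb)`, whose operational affinity is
  `kb / kf` — scaling the backward rate `kb` shifts the dose-response
  rightward without changing the saturating flux, which is exactly the
  degree of freedom the Aβ-PMCA condition manipulates;
* a constant plasma-membrane leak that balances the PMCA at rest and sets
  the Ca^2+^ concentration of zero net membrane flux (this is why an
  affinity-reduced pump raises resting cytosolic — and, through SERCA, ER —
  Ca^2+^);
* kinetic (on/off) buffers in both compartments, kept explicit rather than
  in the rapid-buffer limit because event rise times of tens of
  milliseconds are a validation target;
* IP~3~ production by mGluR (Hill in the summed glutamate + agonist
  concentration) and by Ca^2+^-activated PLCδ, and degradation by a
  first-order 5-phosphatase and a Ca^2+^-activated 3-kinase.

ER bookkeeping is exact: whatever leaves the ER enters the cytosol, with
the ER-side derivative scaled by the ER/cytosol volume ratio, so with
membrane fluxes disabled total Ca^2+^ (free + bound + volume-weighted ER)
is conserved to integration tolerance — a property the test suite checks on
the compiled integrator directly.

### Stochastic IP~3~R gating

Each of the `n_ip3r` channels (default 10) consists of three identical,
independent subunits carrying one IP~3~ site, one activating Ca^2+^ site
and one inhibitory Ca^2+^ site (eight states per subunit); a channel
conducts while all three subunits are simultaneously in the active state
(IP~3~ bound, activating Ca^2+^ bound, inhibitory site free). Binding
rates are linear in local IP~3~ and Ca^2+^ and the IP~3~ site kinetics
depend on inhibitory-site occupancy, producing the classic bell-shaped
stationary open probability. The whole scheme is configuration: the eight
states and ten rate constants live in the parameter file and can be
substituted without touching code.

Gating is the model's only noise source. At the default 50 µs step each
subunit draws at most one transition per step from its exit rates (the
integrator is hybrid: explicit Euler for the continuous variables plus
independent Markov jumps, the degenerate form of an Euler–Maruyama update
when the diffusion term is a jump process). Any per-step exit probability
above 0.1 is treated as an error ("dt too large"). Clamped-input
occupancies are tested against the null space of the generator
(total-variation distance below 0.02).

### Release machinery

Sensor occupancies are tracked pool-level (mean-field): the Syt4 bound
fraction and the Syt7 occupancy distribution over 0–5 bound ions. Both
master equations are linear at fixed Ca^2+^; they are advanced by a
sub-stepped 4th-order Runge–Kutta update that subdivides until the fastest
rate times the substep is below 0.05, which keeps the trajectory within
10^-4^ of the matrix-exponential solution (tested). Plain explicit Euler at
50 µs would not meet that tolerance for the fast Syt4 rates.

The Syt7 chain uses sequential binding with statistical factors
(5k~on~, 4k~on~, …) and an unbinding cooperativity factor `b < 1` applied
per successive unbinding step: each bound ion stabilizes the remaining
ones. With five independent sites and fusion only from the fully bound
state, the Hill fit of peak release rate against clamped Ca^2+^ would place
the operational half-activation near 100 µM even though each site has
k~d~ = 15 µM; the cooperativity factor reconciles the two, and its default
(`b = 0.567`) is calibrated once so the fitted operational k~d~ lands at
15 µM with per-site off/on ratio still 15 µM.

Release is sampled per mode per 50 µs step: one vesicle is released iff
`rate * dt` exceeds a uniform draw, where the KR rate is
`syt4_gamma * p_bound * n_docked` and the FF rate is
`syt7_gamma * P(fully bound) * n_mobile`. Released vesicles enter a
pathway-specific endocytosed pool and return to the mobile pool at a
single pathway-specific recycling rate (endocytosis and reacidification
collapsed into one first-order step so the four-pool bookkeeping is exact);
mobile vesicles dock at rate `k_dock` into free docking sites only. Total
vesicle number is conserved exactly at every step and docking can never
overfill the docked pool.

## Stimuli

Presynaptic spikes raise perisynaptic glutamate by `glu_max` (200 µM)
instantaneously; between spikes the concentration decays first-order with
`k_glu` = 1/6.25 ms, a single clearance constant absorbing receptor binding
and reuptake. Because the decay is linear, a train is exactly the
superposition of single-spike responses (tested to machine precision).
Train protocols cover 0.4–100 Hz with regular timing by default (the
frequency sweeps are reported without jitter; a Poisson mode exists for
robustness studies). Bath-agonist protocols are rectangular DHPG pulses,
canonically 100 µM for 2 s.

## Analysis chain

**Event detection.** Local maxima whose peak value crosses 300 nM (the
physiological minimum for evoking glutamate release from astrocytes) are
events. A minimum-prominence filter (default half the threshold) prevents
stochastic channel flicker riding on a large transient from being counted
as many events. Widths are measured at half the prominence-referenced
height with linear interpolation (the contract of the standard peak-width
routines), rise time between the 20% and 80% crossings of the peak
deflection, decay time from peak to the 36.8% (e-fold) crossing;
overlapping events are split at the inter-peak minimum, and unresolved
crossings yield `NA` rather than a fabricated number.

**Percentage response** is the ratio of the trapezoidal area under the
Ca^2+^ trace during stimulation to the area in the equally long
pre-stimulus window; it is exactly 1 for a constant trace and invariant
under uniform rescaling.

**Synchrony.** The event-time synchrony across trials follows the
phase-projection recipe: for each reference event and inter-event order
*m*, the intervals from the reference to the *m*-th following event of
every trial are normalized by the reference trial's own *m*-spanning
interval, projected onto the unit circle, and summarized as one minus the
circular variance (the squared resultant length). The published recipe is
ambiguous about how the interval vector is formed; of the three readings we
implemented, only this one satisfies both stated limits — exactly 1 for
perfectly aligned trains and near 0 at every order for i.i.d. random
trains — so it is the default, with a within-trial variant available via
`mode = "within_trial"`. The test suite pins the implementation to an
independent brute-force transcription of the same reading.

**Cross-correlation.** Ca^2+^ and release event trains are binned at 10 ms
over the 11 s analysis window; the joint peristimulus time histogram is
shuffle-corrected (trial-mean product subtracted) and normalized by the
bin-wise standard deviations, and the correlation profile is read along the
diagonal band of lags within ±100 ms; the peak over lags is reported. With
this normalization identical trains give exactly 1 and independent trains
give approximately 0. Bootstrap standard errors use resampling with
replacement (defaults: 100 resamples matching the reported procedure).

## Parameters and calibration

All defaults live in `inst/extdata/default_parameters.json`, one entry per
constant with units and a `calibrated` flag. Fixed values: the 50 µs step,
the 300 nM event threshold, the 200 µM / 6.25 ms glutamate pulse, the
sensor site counts and affinity ratios (22 µM for Syt4, 15 µM per site for
Syt7). Everything else was calibrated once against the printed
physiological targets and then frozen:

* control rest subthreshold (~0.1 µM cytosolic, high-µM-range ER load,
  near-zero spontaneous event rate);
* mean evoked deflection at 0.4 Hz in the nanomolar range (≤ 20 nM);
* mean suprathreshold event amplitude ≥ 5 µM under 100 Hz drive;
* docked-pool recovery to within 5% of its initial size in 15–20 s after a
  2 s DHPG pulse, with KR events well in excess of FF events and the
  mobile pool transiently elevated after stimulus offset;
* fitted sensor affinities of 22 and 15 µM.

The steep mGluR dose dependence (`k_mglur` = 60 µM, Hill slope 2) is what
separates the regimes: single low-frequency spikes barely move IP~3~, while
sustained 100 Hz drive builds it up ~150-fold over rest. PLCδ production is
kept small (`v_plcd` = 0.1 µM/s) so that the DHPG-to-IP~3~ dose-response is
dominated by the mGluR term; a stronger Ca^2+^-feedback production would
distort the fitted half-activation ratio away from the pure parameter
transform (we measured the fitted reduction drop from ~50% to ~40% at
`v_plcd` = 0.4 µM/s).

The Aβ-PMCA backward-rate factor is not hard-coded: `apply_condition()`
runs a one-dimensional search so that the fitted affinity ratio of the
steady-state pump flux is 2.0, because the experiments report the outcome,
not the rate. The transform functions are guarded against double
application and commute.

## Numerical choices and degenerate inputs

* Fixed step 5 × 10^-5^ s for all stochastic runs; event-rate statistics
  are checked to be stable under halving the step (Monte-Carlo tolerance).
* The deterministic (mean-field) limit — subunit master equation plus the
  same fluxes — is integrated with `lsoda` (rtol 10^-8^) and doubles as the
  reference for the fixed-step integrator (peak IP~3~ agrees within 1%).
* Resting states are found by relaxing the mean-field model for 600 s and
  demanding relative derivatives below 10^-5^/s; the slowest mode is ER
  filling (tens of seconds). Non-convergence raises an error naming the
  residual derivative.
* Concentrations are clipped at zero with a warning (explicit Euler can
  undershoot during sharp events); any non-finite state aborts the trial
  with the offending fluxes in the message. Under the default parameters
  no clipping occurs in the tested regimes.
* Seeding: one root seed per batch; trial `i` uses `base_seed + i`. All
  randomness (gating, release draws, pool transitions, Poisson spike
  times, initial channel states) flows through R's RNG inside the compiled
  loop, so trials are bit-reproducible and order-independent.

## Problem sizes used in the tests

The packaged checks run at desk scale: single trials are 1.5–23 s of
simulated time (30k–460k steps), stochastic acceptance checks use 100
trials (docked-pool recovery, low/high-frequency amplitude regimes), and
the directional Aβ comparisons use 8–10 trials per condition at fixed
seeds. The clamped-gating stationarity check uses 30 subunits for 2 × 10^6^
steps. These sizes were chosen so the full suite completes in minutes while
leaving the Monte-Carlo error far from every asserted margin; the original
study's 400-trial (DHPG) and 1000-trial (sweep) batch sizes remain the
defaults a user would pick for publication-quality statistics via
`--trials` or `simulation_config()`.

## What the model does and does not reproduce

Reproduced, and asserted in the test suite: the resting-state ordering and
its shift under Aβ-PMCA (higher cytosolic and ER Ca^2+^); nanomolar
low-frequency responses versus micromolar high-frequency events; KR/FF
kinetic separation (fast, high-rate, docked-pool-limited KR versus slow,
low-rate FF with hundreds-of-milliseconds rise); docked-pool depletion and
15–20 s recovery with a transiently elevated mobile pool; the fitted
halving of mGluR half-activation and PMCA affinity; higher Ca^2+^ event
rates under every Aβ condition, amplitude increases specific to Aβ-mGluR,
kinetic slowing specific to Aβ-PMCA, and the FF boost under Aβ-PMCA; and
the docked-pool depletion gradient across conditions at high stimulation
rates.

Not reproduced under this calibration, and left as a documented red test:
the high-rate *decorrelation* of Ca^2+^ and release events under Aβ (and
the accompanying KR suppression). In this model 2–4 docked vesicles are
still enough to make release reliable within each large event, so at
100 Hz the sparser, larger Aβ events *raise* the normalized correlation
instead of lowering it; the decorrelation direction does appear at low and
moderate rates. Forcing the docked pool to pin near zero (slower
docking/recycling or stronger FF sequestration) breaks the recovery-time
and affinity targets, so the calibration keeps the printed targets and
reports the discrepancy honestly.

The synthetic stimuli emulate clean laboratory protocols: regular or
Poisson spike trains with identical pulse size, rectangular agonist
applications, and no spatial geometry. Real perisynaptic glutamate
transients vary in amplitude, the process has diffusive exchange with the
soma, and mitochondrial uptake and store-operated entry are absent by
design — passing tests therefore validate the model's internal logic and
its calibrated operating points, not quantitative agreement with any
particular imaging data set.

## A worked run

```{r example, eval = FALSE}
params <- astro_parameters()
prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100,
                          onset_s = 0.5, duration_s = 2)
cfg <- simulation_config(params, prot, n_trials = 100, base_seed = 1,
                         duration = 25)
batch <- run_batch(cfg)
summary(batch)
synchrony <- pinsky_rinzel_synchrony(batch$ca_matrix)
xc <- jpsth_cross_correlation(batch$ca_matrix, batch$rel_matrix,
                              duration = 11, t0 = 0.5)
```
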