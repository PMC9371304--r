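# gliosim

Stochastic biophysical simulation of calcium signaling and
gliotransmitter release in a single astrocytic perisynaptic process, with
the analysis chain needed to quantify it: calcium event detection and
kinetics, percentage response, event-time synchrony across trials, and the
joint-PSTH cross-correlation between calcium and release events. The
package also implements amyloid-beta (Aβ) pathology as two parameter
transforms — enhanced mGluR signaling and impaired PMCA pumping — and the
dose-response characterizations used to verify them.

It is intended for computational neuroscientists studying astrocyte–synapse
interaction: how microdomain Ca²⁺ events arise from stochastic IP₃R
gating, how they map onto kiss-and-run versus full-fusion exocytosis
through the dual Ca²⁺ sensors Syt4 and Syt7, and how Aβ-associated
molecular changes reshape both.

## The model in brief

A well-mixed compartment with cytosol and ER evolves by mass action at a
fixed 50 µs step:

```
dCa/dt   = (v_ip3r·N_open + v_leak)(Ca_ER − Ca) − J_SERCA(Ca) − J_PMCA(Ca)
           + v_in − J_buf(Ca)
dCa_ER/dt = [ −(v_ip3r·N_open + v_leak)(Ca_ER − Ca) + J_SERCA ] / ρ − J_buf,ER
dIP3/dt  = v_mGluR·H(Glu + DHPG; K, n) + v_PLCδ·H₂(Ca) − (k_5P + v_3K·H₂(Ca))·IP3
```

with ρ the ER/cytosol volume ratio, J_PMCA = V·k_f·Ca/(k_f·Ca + k_b)
(operational affinity k_b/k_f), and Hill-type SERCA/PLCδ/3-kinase terms.
`N_open` comes from an eight-state Markov subunit scheme (one IP₃ site, one
activating and one inhibitory Ca²⁺ site; three subunits per channel; a
channel conducts when all subunits are active) simulated stochastically per
50 µs step — the model's only noise source. Presynaptic spikes step
glutamate by ~200 µM with a 6.25 ms clearance constant.

Release: Syt4 (one site, k_d ≈ 22 µM, fast) gates kiss-and-run release of
docked vesicles; Syt7 (five sequential sites, per-site k_d 15 µM, slow,
with unbinding cooperativity) gates full fusion of mobile vesicles. A
vesicle is released per mode per step iff `rate·dt > U(0,1)`; released
vesicles recycle through pathway-specific endocytosed pools back to the
mobile pool and re-dock at a finite rate, conserving total vesicle count
exactly.

Aβ conditions: `condition_spec(mglur = TRUE)` halves the mGluR
half-activation and doubles maximal IP₃ production;
`condition_spec(pmca = TRUE)` scales the PMCA backward rate (found by a
1-D search) so the pump's fitted Ca²⁺ affinity falls by 50%.

## Worked example

One hundred seeded trials of the canonical DHPG protocol (100 µM, 2 s),
followed by the clamped-calcium characterization of the two sensors:

```r
library(gliosim)

params <- astro_parameters()                       # versioned defaults
prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100,
                          onset_s = 0.5, duration_s = 2)
cfg <- simulation_config(params, prot, n_trials = 100, base_seed = 1,
                         duration = 25)
batch <- run_batch(cfg)
batch
#> batch of 100 trials (control): 2200 Ca events, 1248 KR + 352 FF releases
summary(batch)
#> condition control, 100 trials
#>   Ca events: 0.88 /s, amplitude 6.24 uM, rise 0.0052 s, fwhm 0.0174 s, decay 0.0187 s
#>   releases per trial: 12.5 KR, 3.52 FF

ch <- characterize_clamped(params,
                           c(1, 2, 5, 8, 12, 15, 20, 30, 50, 100, 200),
                           t_max = 4)
fit_hill(ch$peaks$ca, ch$peaks$peak_kr)
#> Hill fit: Vmax = 71.89, kd = 22.18 uM, n = 0.996 (resid 0.0391)
fit_hill(ch$peaks$ca, ch$peaks$peak_ff)
#> Hill fit: Vmax = 17.9, kd = 14.1 uM, n = 1.66 (resid 1.18)
```

The batch shows micromolar-amplitude, sub-second Ca²⁺ events confined to
the stimulus window, kiss-and-run releases well in excess of full fusions,
and (in `batch$mean_series`) the docked pool depleting and recovering to
its initial size within 15–20 s. The Hill fits recover the two sensors'
operational affinities (22 and ~15 µM). Event matrices feed directly into
`pinsky_rinzel_synchrony()` and `jpsth_cross_correlation()`; results
export to CSV/JSON with `export_results()` and round-trip through
`import_results()`.

A thin command-line front end over the same functions lives at
`inst/cli/gliosim.R` (verbs `simulate`, `characterize-syt`,
`dose-response`, `analyze`, `sweep`; all accept `--condition`, `--seed`,
`--trials`, `--out`).

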