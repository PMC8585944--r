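# hdinephys

Analysis of whole-cell patch-clamp experiments on human stem cell-derived
GABAergic interneurons (hdINs) and the neurons they innervate — with a
ground-truthed simulator for every protocol, so the complete analysis chain
is testable by parameter recovery.

The package is aimed at cellular electrophysiologists who need a
reproducible, scriptable version of the analyses usually spread across
acquisition software and one-off scripts:

* **Spontaneous PSC detection** — sliding-window Pearson correlation of a
  unit-peak template against the 400 Hz zero-phase-filtered trace; events
  with `r >= 0.6` are measured (amplitude against a median pre-peak
  baseline; interpolated 20–80 % rise and decay) and screened by four
  exclusion rules (amplitude < 5 pA, rise > 3 ms, decay > 20 ms,
  decay < 1.5 × rise), then subsampled to equal representation per cell.
  The template is the bi-exponential
  `k(t) ∝ exp(−t/τ_d) − exp(−t/τ_r)` (peak at
  `t* = ln(τ_d/τ_r)·τ_dτ_r/(τ_d−τ_r)`), or an average of recorded events.
* **Intrinsic properties** — RMP with spike masking, series/input
  resistance from a 5 mV test pulse (`Rs = ΔV/I_peak`,
  `Ri = ΔV/I_steady − Rs`), AP features from `dV/dt ≥ 10 mV/ms`
  threshold crossings, per-step spike counts, and Na/K I–V curves with
  scaled −90 mV leak subtraction.
* **Optogenetics** — ChR2 photocurrent characterisation, first-event
  latency histograms (one latency per trial), and a Poisson bin test on
  the fullest bin: `p = P(X ≥ k | λ)`, `λ = r_base·Δt_bin·n_trials`,
  plus a selection-calibrated variant used for decisions.
* **Statistics & composition** — KS (α = 0.01), Mann–Whitney / Wilcoxon
  (exact for small tie-free samples), Fisher exact, Grubbs outlier
  screen, marker percentages over MAP2+ cells, labelled-fraction
  inference, and ΔCt relative expression against ACTB/GAPDH.
* **Simulators** — Poisson PSC trains with log-normal amplitudes on a
  4 pA p-p noise floor, an AdEx spiking neuron for ramp/step protocols,
  Boltzmann-gated Na/K conductances with TTX/TEA toggles, ChR2
  photocurrents and fixed-latency evoked responses, marker count fields
  and triplicate Ct tables — each returning the planted ground truth.

## Worked example

```r
library(hdinephys)

# a 120 s voltage-clamp session at 1.01 Hz, mean amplitude 29.61 pA
sim <- simulatePSCSession(
  kernel = pscKernelParams(amplitudeMeanPa = 29.61),
  train  = eventTrainParams(rateHz = 1.01, durationS = 120),
  seed   = 7)

tmpl   <- buildTemplate(pscKernelParams(), fs = 1e4)
events <- applyExclusions(detectEvents(sim$bundle, tmpl))
summarizeCell(events, analyzedDurationS = 120)
#>   cell_id condition n_events mean_amplitude_pA mean_iei_ms frequency_hz
#> 1  cell01  baseline      146          30.90911    817.8972     1.216667
```

The simulator planted 146 events with a realised mean amplitude of
30.0 pA; the detection chain recovered all of them (frequency
1.22 Hz = 146/120 s, mean amplitude 30.9 pA — the ~3 % excess is the
zero-phase filter's peak transmission). Intrinsic properties from the
same cell model:

```r
cc <- simulateCurrentClampSession(seed = 7)
measureRMP(cc$bundle)                    # -47.19 mV (model EL -47.2)
maxAPCount(cc$bundle)$sustained_rate_hz  # 30 Hz over the -40..200 pA series
```

A one-command demonstration run (baseline vs picrotoxin comparison,
intrinsic profile, light-evoked latency analysis) writes `events.csv`,
`stats.json`, `profile.json`, `opto.json` and a provenance log:

```r
runPipeline(defaultRunConfig(seed = 1, outDir = "demo_run"))
```

or from a shell: `Rscript inst/scripts/hdin-ephys.R demo --seed 1
--out demo_run`.

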