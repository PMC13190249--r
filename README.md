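# thetalink

Analysis of coupled two-region extracellular recordings: low-theta (3–5 Hz)
LFP coherence between prefrontal cortex and amygdala, and entrainment of
single-unit spiking to that rhythm. The package is aimed at developmental
systems-neuroscience work where coupling between the two structures — and
its disruption, e.g. by early-life stress — is quantified from simultaneous
local field potential (LFP) and sorted multi-unit recordings under
urethane anaesthesia.

## What it computes

* **LFP conditioning** — 3rd-order Butterworth low-pass (<1 kHz),
  downsampling to 2 kHz, 50 Hz IIR notch; all filtering zero-phase.
* **Spectra & coherence** — Welch PSD (10-s Hamming windows, 50% overlap)
  and magnitude-squared coherence

  C_xy(f) = |P_xy(f)|² / (P_xx(f) · P_yy(f))

  on 3-s windows of the 0–100 Hz band, with a Monte-Carlo shuffle
  confidence limit (95th percentile of 100 window-permuted surrogates) and
  the trapezoidal area under the curve over 3–5 Hz as the per-animal
  coupling summary, plus cross-sectional fold changes between age groups.
* **Single units** — mean firing rate, Fano factor (variance/mean of 1-s
  spike counts), waveform valley-to-peak time and FWHM with sub-sample
  interpolation, the fast-spiking rule (both features < 0.3 ms), cluster
  quality control (SNR, Isolation Distance > 25, L-ratio < 0.5, refractory
  violations), and logarithmic firing-rate histograms.
* **Spike–field phase locking** — instantaneous phase by complex Morlet
  wavelets (4 cycles) at 3–5 Hz in 0.5 Hz steps (phase 0° = peak), Rayleigh
  tests with Bonferroni correction (0.05/5 = 0.01), preferred angles and
  resultant lengths, Watson-Williams comparisons of group angles, and
  Fisher exact tests of locked proportions.
* **Group statistics** — D'Agostino–Pearson-gated choice between unpaired
  t / Welch t / Mann-Whitney U, with mean ± SEM/SD or median (IQR)
  summaries.
* **Synthetic data** — a generator of coupled two-region LFP (tunable
  coupling c), von Mises phase-modulated spike trains (tunable κ and
  preferred phase), and parametric biphasic waveforms, so every stage is
  validated by parameter recovery.

## Worked example

```r
library(thetalink)

cfg <- synth_config(duration = 120, coupling_c = 0.6, vonmises_kappa = 2,
                    preferred_phase_deg = 120, base_rate_lambda0 = 4, seed = 42)
pair <- generate_lfp_pair(cfg)
coh  <- shuffle_confidence(pair$recA, pair$recB, n_iter = 100, seed = 42)
coh
#> <coherence_result> 3001 freqs (0-1000 Hz), 79 windows, band 3-5 Hz AUC 0.759, shuffle limit attached

train <- generate_locked_spikes(pair$recA, cfg)
lk <- lock_unit(train, morlet_phase(pair$recA))
lk
#> <unit_locking_result> u1: LOCKED (min p 1.4e-102 @ 4 Hz), angle 119.5 deg, R 0.656, n 479
```

The coherence AUC of 0.759 over 3–5 Hz (where 2.0 would be perfect
coherence across the whole band) reflects the configured coupling of 0.6
in the presence of delta, 1/f noise and finite data; the observed MSC
exceeds the shuffle confidence limit at all 7 band frequencies. The unit,
generated with concentration κ = 2 around 120°, is recovered as locked at
4 Hz with a preferred angle of 119.5° and a resultant length of 0.656
(the theoretical value for κ = 2 is I₁(2)/I₀(2) ≈ 0.698; the estimate
carries sampling error at 479 spikes). The Fisher framework reproduces
count-table results exactly, e.g.
`locked_proportion_test(1, 54, 10, 90)$p` = 0.0531.

A full simulate → coherence → units → locking → group-statistics run is a
single call:

```r
groups <- list(
  list(label = "control", n = 10, coupling_c = 0.3, units_per_subject = 4),
  list(label = "stress",  n = 10, coupling_c = 0.6, units_per_subject = 4))
res <- run_pipeline(run_config(cohort = groups, out_dir = "out",
                               base_config = synth_config(duration = 60),
                               seed = 1))
res$comparisons$band_auc   # normality-gated two-group comparison of band AUC
```

See `vignettes/thetalink-methods.Rmd` for the model, parameter defaults,
numerical choices and known limitations.

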