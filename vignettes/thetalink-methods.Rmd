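---
title: "Methods: coupled-region LFP coherence and spike-phase locking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled-region LFP coherence and spike-phase locking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetalink)
```

## What the package computes

`thetalink` analyses simultaneous extracellular recordings from two coupled
brain regions — the setting is developing prefrontal cortex and basolateral
amygdala under urethane anaesthesia, where a low-theta (3–5 Hz) rhythm
dominates and couples the two structures. The pipeline has four analysis
layers plus a synthetic-data generator used for ground-truth validation:

1. **LFP conditioning** (`condition_lfp`): third-order Butterworth low-pass
   below 1 kHz, decimation to 2 kHz, and a biquad 50 Hz notch (Q = 30).
2. **Spectra and coherence** (`welch_psd`, `msc`, `shuffle_confidence`,
   `band_auc`): Welch PSD (10-s Hamming windows, 50% overlap) and
   magnitude-squared coherence
   $C_{xy}(f) = |P_{xy}(f)|^2 / (P_{xx}(f)\,P_{yy}(f))$
   on 3-s windows (50% overlap) of the 0–100 Hz band, with a Monte-Carlo
   shuffle confidence limit and the trapezoidal area under the coherence
   curve over 3–5 Hz as the per-animal summary.
3. **Single units** (`firing_metrics`, `waveform_features`,
   `classify_unit`, `qc_filter`): mean rate, Fano factor
   (variance/mean of 1-s spike counts), trough-referenced waveform features
   (valley-to-peak time, FWHM), the 0.3 ms fast-spiking rule, and cluster
   quality control (SNR, Isolation Distance, L-ratio, refractory
   violations).
4. **Spike–field locking** (`morlet_phase`, `lock_unit`,
   `watson_williams`, `locked_proportion_test`): instantaneous phase by
   complex Morlet wavelets (4 cycles) at 3, 3.5, 4, 4.5 and 5 Hz, a
   Rayleigh test per frequency with Bonferroni correction
   (0.05/5 = 0.01), preferred angles by circular means, Watson-Williams
   comparisons of mean angles, and Fisher exact tests of locked
   proportions.
5. **Group policy** (`compare_groups`): the D'Agostino–Pearson omnibus
   test gates every two-group comparison into an unpaired t-test
   (Welch variant when the variance ratio exceeds 4) or a two-sided
   Mann-Whitney U test.

## Phase convention

Phase 0° is the oscillation **peak**, ±180° the trough, and the descending
flank (peak → trough) spans 0° → +180°. A cosine analysed at its own
frequency therefore has phase 0° at every maximum. The spike generator
computes its modulation phase with the same Morlet machinery the analysis
uses, so generator and analyser agree on the convention by construction;
the recovery tests close the loop through the full pipeline.

## The synthetic generator as the validation instrument

`synth_config()` fixes the study conditions. Region A carries a narrowband
Gaussian theta source $s_A$ (white noise band-passed to 3–5 Hz — a pure
tone would make coherence trivially 1); region B carries
$c\,s_A + \sqrt{1-c^2}\,s_B$, renormalized to equal theta power, so the
coupling coefficient $c \in [0,1]$ is the single ground-truth knob for
coherence recovery. Each region adds an independent-phase delta oscillation,
$1/f^\alpha$ background, and optionally common-phase 50 Hz line noise.

Spike trains are inhomogeneous point processes with von Mises phase
modulation,
$\lambda(t) = \lambda_0 \exp(\kappa \cos(\theta(t)-\phi_{pref}))/I_0(\kappa)$,
realized by time-rescaling a gamma renewal process (shape $k$; $k=1$ is
Poisson) and imposing a 1.5 ms dead time. Because the marginal phase
distribution of a stationary narrowband Gaussian process is uniform, the
resultant length of the spike phases converges to the closed form
$I_1(\kappa)/I_0(\kappa)$, which is what the recovery tests assert
(±0.05 at $n \ge 1000$ spikes). Fano factors above 1 — as observed in vivo —
are produced by an optional slow log-normal rate modulation
(`slow_mod_sd`), since the variability mechanism itself is not part of the
analysed model.

Waveforms are a negative Gaussian trough plus a delayed positive rebound,
calibrated against the package's own feature extractor by damped
fixed-point iteration until the measured FWHM and valley-to-peak match the
configuration within one sample at 30 kHz.

### Default parameter choices

| parameter | default | rationale |
|---|---|---|
| `duration` | 120 s | enough for ~39 coherence windows and >200 spikes at 2 Hz; keeps simulation suites fast |
| `fs_lfp` | 2000 Hz | the analysis rate; the generator emulates conditioned LFP directly, `fs_raw = 30 kHz` is used for waveforms |
| `delta_amp : theta_amp : noise_amp` | 100 : 40 : 20 | slow-wave-dominated spectra with a distinct but smaller low-theta peak; no quantitative amplitude ratios are claimed, all are exposed |
| `base_rate_lambda0` | 2 spikes/s | low cortical rates of the developing cortex (medians around 0.6–1.5 Hz, rounded up for test power) |
| `theta_bw` | 2 Hz | the 3–5 Hz band of interest |
| notch Q | 30 | −3 dB width 1.7 Hz at 50 Hz; narrow enough to leave gamma intact |

## Numerical choices

* **Zero-phase filtering everywhere** (forward–backward `filtfilt`): phase
  locking is meaningless if preprocessing rotates phases; the effective
  order doubles (documented per function).
* **Resampling** assumes an integer decimation factor (30000 → 2000 = ÷15)
  after the anti-alias low-pass.
* **Shuffle null**: per surrogate iteration every 3-s region-A window is
  independently sample-permuted and the full Welch MSC is recomputed
  against intact region B; the 95th percentile of the pooled surrogate
  distribution per frequency is the confidence limit. Permutation destroys
  all temporal structure while preserving the amplitude distribution — the
  strongest null consistent with a "shuffled windows" design. A circular
  time-shift surrogate (preserving the within-window spectrum) is available
  via `method = "timeshift"`.
* **Band AUC**: trapezoidal rule with linear interpolation of the MSC at
  the band edges; exact for piecewise-linear spectra (tested against closed
  forms and an independent summation oracle).
* **Fold change across ages** is cross-sectional: each older-animal AUC is
  divided by the *mean* of the younger group (animals are not paired);
  summarized as median (IQR).
* **Rayleigh p** uses the standard finite-$n$ approximation
  $p = \exp(\sqrt{1+4n+4(n^2-R_n^2)} - (1+2n))$; units with fewer than 5
  usable spikes are excluded with a reason, not tested.
* **Best frequency** for the preferred angle and vector length is the
  minimum-p frequency among the five; ties break toward the lowest
  frequency.
* **Watson-Williams** uses the $1+3/(8\hat\kappa)$ correction; the
  concentration-comparability assumption is checked (pooled mean resultant
  ≥ 0.45, group $\hat\kappa$ ratio ≤ 2) and a warning is logged when it
  fails, but the test still runs, since group comparisons are reported
  unconditionally in this literature.
* **Welch-vs-plain t**: the reporting convention never states when Welch's
  correction applies; the package switches at a variance ratio of 4 and
  records the decision in the result.
* **Log-rate histogram bin width** is 0.3 log10 units (the rate axis is
  logarithmic; an apparent "0.3 s" width makes no sense on that axis and is
  read as 0.3 decades).
* **SNR** is defined as template peak-to-peak over twice the residual-noise
  SD; the acquisition-specific acceptance thresholds (5 OpenEphys,
  11 Neuralynx) are applied as given.
* **Fano bin width** defaults to 1 s: slow enough to integrate theta-scale
  modulation, fast enough to give hundreds of counts per recording.

## Problem sizes used by the test and acceptance suites

Simulation-based checks run at the generator defaults (120 s, 2 kHz LFP,
2 spikes/s) or shorter where the property is size-independent: coherence
calibration uses 120-s pairs with 100 surrogate iterations; coupling
monotonicity uses 60-s pairs across $c \in \{0, .2, .4, .6, .8, 1\}$;
phase recovery uses 150 s at 10 spikes/s to guarantee ≥1000 spikes; the
locking calibration uses 200 simulated null units at the default
conditions.

## Known limitations

* **Family-wise locking calibration.** With the Bonferroni rule
  (5 × 0.01) the false-lock rate for unmodulated units measures ≈ 2.5–3%
  rather than ≤ 2%. The per-frequency Rayleigh level is exact-to-slightly
  conservative (verified separately), but the five per-frequency resultant
  lengths are nearly *independent* once the recording is much longer than
  the low-theta phase-coherence time — the relative phase of bands 0.5 Hz
  apart drifts through a full cycle every 2 s — so the family-wise rate
  approaches $1-(1-\alpha)^5 \approx 5\alpha$ instead of the smaller value
  strong inter-frequency dependence would give. This is a property of the
  published procedure itself, not of its implementation here, and it holds
  at any realistic recording length.
* The generator emulates stationary activity. Real urethane recordings
  alternate brain states, contain heartbeat and movement artifacts, and
  have electrode-distance-dependent amplitude gradients; none of that is
  modelled, so passing recovery tests demonstrates correctness of the
  estimators, not robustness to non-stationary data.
* Spike sorting itself is out of scope: the package consumes sorted spike
  timestamps and mean waveforms, plus a simple amplitude-threshold detector
  (`detect_spikes`) for synthetic raw signal. Cluster quality metrics are
  computed from caller-supplied feature-space points.
* Bimodality of log-rate distributions is reported descriptively
  (histogram modes); no dip test is attached.
* Coherence is undirected; directionality is addressed only through
  cross-region phase locking.

## A minimal end-to-end run

```{r, eval = FALSE}
groups <- list(
  list(label = "control", n = 10, coupling_c = 0.3, units_per_subject = 4),
  list(label = "stress",  n = 10, coupling_c = 0.6, units_per_subject = 4))
res <- run_pipeline(run_config(cohort = groups, out_dir = tempfile(),
                               base_config = synth_config(duration = 60),
                               seed = 1))
res$comparisons$band_auc
```
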