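---
title: "Measuring and comparing vole distress calls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing vole distress calls: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volecall)
```

## The scientific question

When two vole species with acoustically distinct distress calls are crossed,
where do the hybrids' calls fall? If call parameters are inherited
intermediately, hybrid calls should lie between the parental species in a
multivariate acoustic space; if one parental genome dominates, they should
lie nearer that parent. `volecall` implements the full analysis chain needed
to ask this question quantitatively — synthetic call generation, automated
acoustic measurement, and the discriminant/Mahalanobis statistics — for the
Tien Shan vole, the bank vole and their F1 hybrids.

Because no recordings are distributed with the package, the generator is a
first-class component: it emulates the three groups' published parameter
distributions so that every downstream stage can be exercised and tested end
to end.

## The call model

A distress call is modelled as

* a **harmonic stack** of 3–10 partials at integer multiples of a
  time-varying fundamental `f0(t)`. The fundamental follows an arch
  (`∩`-shaped) trajectory: it starts at `f0max - modulation_range`, rises to
  `f0max` at mid-call along a half-cosine arch (`f0min + mod * sin²(πt/T)`),
  and falls back symmetrically. The half-cosine is the simplest concave
  trajectory with stationary endpoints, which also keeps the spectrogram
  frames at the call edges locally stationary;
* a **formant-like spectral envelope** on the partial amplitudes: a Gaussian
  in frequency centered at the call's 50%-quartile target (bandwidth
  1800 Hz), floored at −20 dB of the strongest partial. This is essential
  realism: bank vole calls combine a ~1.5 kHz fundamental with peak energy
  near 7 kHz, which no monotone (e.g. 1/k) roll-off can produce;
* a **broadband noise component**, Gaussian noise with a soft band emphasis
  (unit gain inside the species' noise band, 0.35 outside), mixed with the
  stack on a unit-RMS scale as `(1-nf)·harmonic + nf·noise` where `nf` is
  the call's noise fraction; and
* a **background floor** of white noise at amplitude 0.35 (≈ −9 dB re the
  call), standing in for the recording and aspiration noise that real
  spectra always contain, plus a raised-cosine attack/decay amplitude
  envelope (6% / 8% of the call by default).

Structure classes follow the noise fraction: `harmonic` calls have `nf = 0`,
`noise` calls `nf = 1`, `mixed` calls something in between.

## The generator's statistical targets

`default_profiles()` carries, for each group, the published means and
standard errors of the five tabulated parameters (duration, maximum
fundamental, modulation range, 50% quartile, entropy) together with the
reference call counts n = 118 (Tien Shan), 108 (hybrid) and 78 (bank).
`sample_call_specs()` draws each parameter independently from
`N(mean, SE·√n)`, truncated to its validity range: duration > 2 ms,
`f0max` in [0.35, 9] kHz, `q50` in [0.1, 10.8] kHz, entropy in (0.01, 0.99),
and `modulation_range` at least 200 Hz below the drawn `f0max` so the
minimum fundamental stays positive.

Three deliberate simplifications are worth knowing about:

* **Independence.** No cross-parameter covariance is modelled — none is
  published. Real calls surely correlate duration, modulation and noisiness;
  synthetic populations will therefore be somewhat "too spherical".
* **Truncation bias.** The published SEs imply large per-call SDs (the bank
  f0max SD is ≈ 0.88 kHz on a 1.5 kHz mean), so validity truncation shifts
  some marginal means noticeably. The generator's marginals are exactly
  truncated normals; tests verify sample means against the closed-form
  truncated-normal expectation, and against the raw published mean only
  where the truncated mass is negligible.
* **Pooling.** Each group is treated as one pooled population;
  `run_study()` allocates calls evenly to individuals (optionally with a
  per-animal random intercept, off by default) but the published table does
  not resolve individual-level variance, so the default generator is
  exchangeable within group.

### Entropy calibration

The spectral entropy of a generated call is *emergent* — it depends on the
noise fraction, the harmonic content, the call's frame count and the
measurement settings — so the generator calibrates rather than forces it.
The drawn entropy target `e` is mapped to a noise fraction through a linear
map `nf = scale · (e − 0.10) / (0.90 − 0.10)`, clamped to [0.05, 0.95] for
mixed calls. The per-profile `scale` (`noise_to_harmonic_energy`: 1.33 Tien
Shan, 1.40 hybrid, 0.86 bank) was fitted once against measured
entropy-vs-noise-fraction curves at each profile's typical call shape, and
absorbs how call duration and noise band depress the measured statistic.

One honest limitation: a 23 ms hybrid call yields only two spectrogram
frames, and the entropy of a 2-frame average spectrum saturates near 0.45 at
these settings. The hybrid group's *measured* entropy therefore undershoots
its 0.586 generative target; the ground-truth draws (which is what the
discriminant reproduction statistics consume) carry the published
distributions exactly. The same frame-count effect is why measured group
entropies (≈ 0.46 / 0.47 / 0.62) compress the published spread (0.52 /
0.586 / 0.637) while preserving the parent ordering and separation.

## Acoustic measurement

`measure()` reproduces, in automatic form, the standard desktop-bioacoustics
measurements at their published settings: Hamming window, 512-point FFT,
87.5% overlap. At the default 22 050 Hz sampling rate this gives 43 Hz
frequency resolution and a 2.9 ms frame step. (The rate itself is a package
choice: published spectrogram settings fix only the 43 Hz resolution, and a
quoted 1.45 ms time step is not consistent with 87.5% overlap of a 512-point
window at any rate that gives 43 Hz bins; we document 2.9 ms as the actual
step.)

* **Duration** — first-to-last crossing of the short-time RMS envelope at
  −20 dB re its maximum (1.5 ms smoothing). This automates the manual
  on-screen cursor; the threshold is configurable.
* **Per-call spectrum** — per-bin power averaged over non-silent frames
  (≥ 1% of the loudest frame's energy). Scalar parameters are read from this
  single spectrum rather than averaged per frame; the alternative (the
  spectrum at the loudest frame) is available by slicing the spectrogram
  directly.
* **Peak frequency** — argmax bin, ties to the lowest frequency.
* **Energy quartiles** — smallest bin frequencies at which cumulative power
  reaches 25/50/75% of the total.
* **Spectral entropy** — geometric over arithmetic mean of per-bin power
  (1 = flat/white, → 0 = pure tone), computed on linear power with
  zero-power bins floored at `1e-12 × max` (the ratio is undefined at zero).
* **Fundamental tracking** — per voiced frame, the candidate `f0`
  (quarter-bin grid over 0.8–6 kHz, bracketing the 1.5–3.8 kHz species
  means against octave errors) maximizing a fixed-length harmonic comb
  score: log power relative to the frame maximum, interpolated
  parabolically at `k·f0` (k = 1..5), capped at −10 nats, with
  above-Nyquist partials costing a slightly smaller −8 (their absence is
  not evidence) and a minute high-`f0` bonus (0.3 · f0/Nyquist nats)
  breaking exact sub-octave ties. A 5-point running median enforces track
  continuity. `f0max` is the track maximum and the modulation range its
  max − min.
* **Structure typing** — the harmonicity index: the energy fraction within
  ±2 bins of the fitted comb, rescaled against the fraction a flat spectrum
  would place there by chance, averaged over voiced frames with energy
  weights. ≥ 0.8 → harmonic, ≤ 0.2 → noise, else mixed; thresholds
  configurable. The fundamental of noise calls is not measured (`NA`).

A resolution caveat: a 512-sample window is nearly as long as a 27 ms call,
so a fundamental sweeping 2.5 kHz smears within single frames. Stationary
or long calls are tracked to within one bin (tested over a 1–5 kHz grid);
strongly modulated *short* calls are typed noisier and tracked flatter than
their generative truth. This mirrors the real resolution limits of the
published settings and is why the downstream statistics use duration, q50
and entropy — not the fundamental — as discriminant features.

## The inference chain

All statistics operate on a measurement table (one row per call with
`group`, `individual` and the measured parameters), with the feature set
`{duration_s, q50_hz, entropy}` by default.

* **Group comparisons** — `one_way_anova()` (classical decomposition + Tukey
  HSD at α = 0.05) for normally behaved parameters;
  `kruskal_wallis_median()` (Kruskal–Wallis H, the grand-median χ² test, and
  pairwise mean-rank z with Bonferroni) for peak frequency.
* **Discriminant analysis** — `dfa()` fits the two-group linear discriminant
  from the pooled within-group covariance; coefficients are exactly
  `Σ⁻¹(μ₁ − μ₂)`. Priors are **equal** by default (the legacy
  desktop-statistics convention; with 118 vs 78 the observed chance level
  also sits near the equal-priors expectation rather than the 60.2% an
  always-pick-the-larger-class rule would give). Near-singular covariances
  are ridge-regularized by `1e-8 × trace` with a warning. `classify()`
  reports the confusion matrix, percent correct, and each feature's partial
  Wilks lambda (full-model Λ over leave-that-feature-out Λ) as a
  contribution ranking.
* **Split-half cross-validation** — `split_half_cv()` halves each group at
  random (stratified), fits on one half and classifies the other: the
  reliability check for the discriminant keys.
* **Randomization chance level** — `randomization_null()` permutes the group
  labels (sizes preserved), refits, and records the *resubstitution* percent
  correct, 100 times by default; reported as mean ± SE. Resubstitution per
  replicate is deliberate: the observed value it calibrates is itself a
  resubstitution figure. Label permutation (rather than simulating from
  pooled parameters) was chosen as the cleaner no-information null. Note
  the null mean is ~55%, not 50%: with p = 3 features and n = 196, the
  refitted discriminant overfits each permutation by E[D̂²] ≈ p(1/n₁+1/n₂),
  i.e. Φ(D̂/2) ≈ 0.55 — reproducing this small-sample bias is the point of
  the procedure.
* **Attribution-rate comparisons** — `compare_proportions_chi2()` rebuilds
  the 2×2 correct/incorrect table from two percentages and applies the χ²
  test, Yates-corrected by default (toggleable).
* **Mahalanobis placement** — `mahalanobis_placement()` computes, for one
  mean point per individual, squared Mahalanobis distances to the two
  parental centroids under the parents' pooled call-level covariance.
  `intermediacy_summary()` labels each hybrid by its nearer parent (ties
  reported) and flags it intermediate when, on both axes, it falls in the
  gap between the parent's own scatter and the opposite parent's scatter.

## The end-to-end study

`run_study()` chains everything: draw call specs per group (118/108/78 calls
from 10/4/5 animals by default), synthesize, measure, and analyse. Every
random step derives its seed from the single config seed, so a report is
bit-reproducible (the JSON serialization contains the config MD5 and no
timestamps). The full default study runs in well under a minute on one core.

Two design notes. First, the reference design itself cannot respect the
"10–20 calls per animal" sampling rule for hybrids (108 calls from 4
females is 27 each); `run_study()` allocates evenly and warns rather than
refusing. Second, plots (the D²-vs-D² scatter) are deliverables but never
analysis surfaces — all numbers live in the report object / JSON.

## What the synthetic tests do and do not show

Against synthetic populations at the published group statistics, the chain
reproduces the study's classification landscape: parent-species
resubstitution ≈ 92–95%, split-half cross-validation within a few points of
it, a permutation chance level near 54%, and hybrids placed nearer the bank
vole on every seed — with the bank-like placement driven mainly by the
hybrids' high 50% quartile. The problem sizes used throughout the tests are
the study's own (118/108/78 calls; 100 permutation replicates; 10-seed
medians for the stochastic reproductions).

What passing these tests does *not* show: that the measurement chain is
robust to field recordings (no segmentation, one file = one call, no
reverberation or overlapping callers), that real calls satisfy the
independence and normality the generator assumes, or that the fundamental
tracker handles species outside the 0.8–6 kHz search band. The generator is
a model of the published summary statistics, not of vole physiology; its
role is to make the analysis chain testable, not to replace recordings.
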