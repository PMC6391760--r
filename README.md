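# volecall

Synthesis and multivariate analysis of vole distress calls.

## The problem

Distress calls — short (20–60 ms) vocalizations emitted by restrained
voles — differ between the Tien Shan vole (*Myodes centralis*) and the bank
vole (*M. glareolus*) in duration, fundamental frequency, spectral
quartiles and noisiness. Because these signals plausibly evolve free of
directional selection, their F1 hybrids are a natural probe of how acoustic
traits are inherited: intermediately, or dominated by one parental genome.

`volecall` implements the complete analysis chain for that question, aimed
at bioacousticians and quantitative biologists:

1. **`callsynth`** — a synthetic call generator. Each species is a
   `species_profile` holding the published parameter means ± SE (per-call
   SD reconstructed as SE·√n for n = 118/108/78 reference calls). Calls are
   harmonic stacks of 3–10 partials with an arch (∩-shaped) fundamental
   trajectory, a formant-like spectral envelope, band-emphasized noise and
   a broadband floor.
2. **`acoustics`** — automated measurement at standard desktop settings
   (Hamming window, FFT 512, 87.5% overlap; 43 Hz resolution at 22 050 Hz):
   duration (−20 dB envelope), peak frequency, energy quartiles q25/q50/q75
   (frequencies below which 25/50/75% of spectral energy lies), spectral
   entropy (geometric/arithmetic mean of the power spectrum), harmonic-comb
   fundamental tracking (f0max, modulation range), and harmonic/noise/mixed
   structure typing.
3. **`hybridstats`** — the inference chain: one-way ANOVA + Tukey HSD,
   Kruskal–Wallis + median test, two-group linear discriminant analysis
   with coefficients Σ⁻¹(μ₁−μ₂) and equal priors, split-half
   cross-validation, a label-permutation chance level (mean ± SE over 100
   permutations), χ² comparison of attribution rates, and squared
   Mahalanobis distances D² of each individual to the two parental
   centroids with an intermediacy summary.
4. **`run_study()`** — the whole design end to end (simulate → measure →
   analyse), bit-reproducible from one seed.

## Worked example

```r
library(volecall)

specs <- sample_call_specs(default_profiles()$bank, n = 3, seed = 42)
specs[, c("group", "duration_s", "f0max_hz", "q50_hz", "entropy",
          "structure")]
#>   group duration_s f0max_hz q50_hz entropy structure
#> 1  bank     0.1024     2059   6682   0.543  harmonic
#> 2  bank     0.0341     1857   7362   0.551     mixed
#> 3  bank     0.0668     1406   6549   0.684     noise

w <- synthesize(specs[1, ], seed = 43)
w
#> waveform: 2259 samples @ 22050 Hz (102.4 ms)

measure(w)
#>   duration_s peak_hz q25_hz q50_hz q75_hz entropy f0max_hz modulation_range_hz structure
#> 1     0.0996    8183   5728   6804   7967   0.442     2050                 465     mixed
```

The measured call is 99.6 ms long (the −20 dB envelope trims the synthesis
ramps slightly), carries half its energy below 6.8 kHz with peak energy
near 8.2 kHz — bank-typical despite a ~2 kHz fundamental, which the tracker
recovers within half a bin — and is typed `mixed` (harmonic stack plus
broadband noise).

The full study design (118 Tien Shan, 108 hybrid and 78 bank calls; the
hybrid allocation warns because 108 calls from 4 animals cannot respect the
10–20-calls-per-animal sampling rule):

```r
rep <- run_study()
rep
#> Synthetic distress-call study
#>   bank=78, hybrid=108, tien_shan=118 calls (seed 20190226, config 88d2fd84)
#>   parent DFA: 94.9% resubstitution, 98.0% split-half CV,
#>   randomization chance 54.86 +/- 0.33% (n = 100)
#>   resub vs CV: chi2 = 0.88, p = 0.35
#>   hybrids nearer to: bank (0 of 4 intermediate)
plot(rep)   # individuals in parental Mahalanobis (D², D²) coordinates
```

Read: the parent species separate at ~95% correct attribution on
(duration, q50, entropy), cross-validation confirms the keys are not
overfitted artifacts (χ² comparison non-significant), the permutation
chance level is ~55% (50% plus the small-sample overfitting bias a
196-row, 3-feature discriminant incurs), and every hybrid female lands
nearer the bank-vole centroid — the paternal species — in Mahalanobis
coordinates.

See `vignettes/volecall-methods.Rmd` for the call model, the entropy
calibration, numerical choices and known limitations.

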