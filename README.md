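# ansflow

Evaluating autonomic nervous system (ANS) function from peripheral
blood-flow signals.

Heart rate variability (HRV) is the standard non-invasive window on the
ANS, but it mainly reflects cardiac autonomic regulation. Because skin
blood vessels are innervated almost exclusively by the sympathetic branch,
the microcirculatory perfusion signal carries complementary information
about peripheral vascular control. `ansflow` implements an analysis chain
built around one statistic: the **peak frequency (PF)** of the
magnitude-squared coherence between *simultaneously recorded left and
right* lower-limb skin perfusion signals (laser-Doppler flowmetry, nominal
64 Hz), restricted to the cardiac band:

```
C(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f)),   PF = argmax_{f in [1.0, 1.5] Hz} C(f)
```

with Welch-averaged cross/auto spectra (Hann taper, 4096-sample segments,
50% overlap by default). PF is then related to composite HRV indices of
parasympathetic and sympathetic tone,

* **PNSi** — weighted z-scores of mean RR, RMSSD and Poincaré SD1 (in
  normalized units, 100·SD1/(SD1+SD2)),
* **SNSi** — weighted z-scores of mean HR, √(Baevsky stress index) and
  SD2 (normalized units),

computed after threshold-based artifact correction and smoothness-priors
detrending (λ = 500) of the RR series. A companion electrogastrogram (EGG)
workflow estimates the gastric slow-wave dominant frequency (DF) in
0.033–0.066 Hz (2–4 cpm). The statistical layer provides Spearman
correlation with Benjamini–Hochberg FDR correction, paired t-tests,
one-way ANOVA, frequency-wise group comparison with contiguous-cluster
labelling, and ordinary-least-squares PF→index regression with
external-prediction validation.

Because the package is developed and tested without recording hardware, it
ships seedable synthetic generators for every signal class (bilateral
perfusion with a shared cardiac-band oscillator, sinusoidally modulated RR
series, slow-wave EGG, and cohorts with linearly coupled PF and indices).
They are statistical stand-ins, not biophysical simulations; see the
methods vignette (`vignettes/ansflow-methods.Rmd`) for what they do and do
not emulate.

## Worked example

```r
library(ansflow)

# a 300 s bilateral perfusion recording with a shared oscillator at 1.2 Hz
cfg <- synth_config(seed = 1, duration_s = 300, pf_target = 1.2,
                    shared_fraction = 0.6)
rec <- generate_bilateral_perfusion(cfg)
cs  <- compute_coherence(preprocess_perfusion(rec))
extract_pf(cs)
#> <pf_result> PF = 1.2031 Hz (peak coherence 0.995) in [1.00, 1.50] Hz

# HRV indices from a synthetic RR series
hrv_pipeline(generate_rr_series(cfg))
#> <hrv_metrics> subject synthetic, phase pre
#>   mean RR 848.8 ms (HR 70.7 bpm), RMSSD 37.77 ms
#>   SD1 26.71, SD2 43.32 ms (ratio 0.617), SI 184.8
#>   PNSi -0.144, SNSi 0.559

# a calibrated synthetic cohort recovers the generating regression model
co <- generate_cohort(cohort_spec(n_per_group = 2000, groups = "all",
                                  group_pf_shift = 0), seed = 42)
fit_pf_regression(co, "snsi")
#> <pf_regression> SNSI = 6.495 PF -7.251  (R2 = 0.783, p = 0, n = 2000)
```

The PF estimate sits within one frequency bin (0.0156 Hz) of the injected
1.2 Hz oscillator; the fitted slope/intercept recover the generating model
`SNSi = 6.48 PF − 7.23` within sampling error, with the noise variance
calibrated so the population R² matches the target fit quality.

A full signal-level study can be simulated and analysed end to end:

```r
dir <- tempfile()
sim <- simulate_study(n_per_group = 20, seed = 5, phases = "post", dir = dir)
res <- run_pipeline(dir, out_dir = file.path(dir, "out"))
res$correlations
#>    scope index        rho            p  n        p_fdr
#> 1   post  snsi  0.9975664 8.616106e-69 60 8.616106e-69
#> 2   post  pnsi -0.9979003 1.198736e-70 60 2.397471e-70
#> 3 pooled  snsi  0.9975664 8.616106e-69 60 8.616106e-69
#> 4 pooled  pnsi -0.9979003 1.198736e-70 60 2.397471e-70
```

reproducing the study-level sign pattern: SNSi increases and PNSi
decreases with PF.

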