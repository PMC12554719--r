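---
title: "Methods: blood-flow coherence, HRV indices and the PF-index coupling"
author: "ansflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-flow coherence, HRV indices and the PF-index coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ansflow)
```

## The problem

The autonomic nervous system (ANS) regulates the cardiovascular,
respiratory and digestive systems through its sympathetic (SNS) and
parasympathetic (PNS) branches. Heart rate variability (HRV) is the usual
non-invasive probe of ANS state, but it is a cardiac signal; skin
microvasculature, in contrast, is innervated almost exclusively by the
sympathetic branch, so peripheral blood-flow fluctuations carry
complementary information about vascular autonomic control.

`ansflow` operationalizes one specific idea: the *synchrony* of left and
right lower-limb skin perfusion signals, measured by magnitude-squared
coherence, peaks somewhere in the cardiac frequency band, and the
frequency of that peak (PF) co-varies with composite HRV indices of
sympathetic (SNSi) and parasympathetic (PNSi) tone — positively with SNSi,
negatively with PNSi — tightly enough that a linear model in PF predicts
the indices on external data.

## Coherence and the PF statistic

For bilateral perfusion traces $x, y$ sampled at $f_s$ (nominal 64 Hz),

$$C(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1],$$

with cross- and auto-spectra estimated by Welch averaging over tapered,
overlapping segments (each segment demeaned before tapering). PF is the
frequency of the in-band coherence maximum:

$$\mathrm{PF} = \arg\max_{f \in [1.0,\,1.5]\,\mathrm{Hz}} C(f),$$

band endpoints inclusive, ties broken toward the lowest frequency, no
sub-bin interpolation. The band is interpreted in Hz: 1.0–1.5 Hz is the
cardiac rhythm at 60–90 bpm, the dominant oscillation of laser-Doppler
perfusion signals.

**Estimator parameters.** The source protocol states that coherence
analysis was performed but not with which window or segmentation, so these
are package design choices, all exposed as arguments: Hann window,
segment length 4096 samples (64 s at 64 Hz, frequency resolution
$\Delta f \approx 0.0156$ Hz, i.e. ~32 bins across the 0.5 Hz PF band) and
50% overlap, which yields 8+ segments on an 18-minute baseline recording.
A minimum of two segments is enforced because the single-segment coherence
estimator is identically 1. With $K$ independent segments the coherence of
*unrelated* signals is biased upward to about $1/K$; the test-suite checks
this bias level explicitly, and it is the reason coherence values near the
floor should not be over-interpreted.

Whether to compute coherence on raw or normalized perfusion units is
immaterial: $C(f)$ is invariant to per-channel affine rescaling (a tested
invariant). Preprocessing therefore defaults to mean removal with optional
linear detrending; NaN runs up to 0.5 s are linearly interpolated, longer
gaps are rejected.

## HRV metrics and the composite indices

The RR pipeline is: artifact correction → smoothness-priors detrending →
metrics → indices.

* **Artifact correction.** Each interval deviating from the local median
  (11-beat centred window) by more than a level-specific threshold
  (very-low 0.45 s … medium 0.25 s … very-strong 0.05 s) is replaced by
  cubic-spline interpolation over the surrounding beats. Correcting more
  than 20% of beats raises a quality error. The procedure is idempotent
  on its own output (tested).
* **Detrending.** The trend is $(I + \lambda^2 D_2^\top D_2)^{-1} z$ with
  $D_2$ the second-difference operator and $\lambda = 500$; constants and
  straight lines lie in the null space of $D_2$ and are annihilated. The
  system is solved with a sparse Cholesky factorization on the
  mean-centred vector plus one step of iterative refinement — forming
  $\lambda^2 D_2^\top D_2$ explicitly is ill-conditioned, and the naive
  solve leaves $\sim 10^{-8}$ residuals that would violate the
  annihilation identities.
* **Metrics.** Mean RR and mean HR ($60000/\overline{RR}$) are computed on
  the corrected raw series; RMSSD, SD1 and SD2 on the detrended series
  (the conventional short-term HRV workflow); the Baevsky stress index on
  the corrected raw series, since its histogram mode must live on the
  physical ms scale.
* **Variance convention.** SD1 uses the *uncentred* population second
  moment of successive differences, $SD1^2 = \tfrac{1}{2}\,
  \mathrm{mean}(\Delta RR^2)$, which makes $SD1 = \mathrm{RMSSD}/\sqrt{2}$
  an exact identity rather than an approximation that fails whenever the
  mean successive difference is non-zero. $SD2^2 = \max(0,\,
  2\,\mathrm{var}(RR) - SD1^2)$ with the population variance.
* **Baevsky stress index.** $SI = AMo / (2\,Mo\,MxDMn)$ from a 50 ms
  histogram whose bin *centres* are anchored at integer multiples of the
  bin width; $Mo$ is the modal-bin midpoint in seconds, $AMo$ the modal
  percentage, $MxDMn$ the RR range in seconds. The anchoring is a package
  convention (reference software does not document one). $\sqrt{SI}$
  feeds the sympathetic index because SI has a heavy right tail.

**PNSi and SNSi** are weighted sums of component z-scores against
normative population values:
PNSi over (mean RR, RMSSD, SD1 in normalized units
$100\,SD1/(SD1+SD2)$), SNSi over (mean HR, $\sqrt{SI}$, SD2 in normalized
units), equal weights by default. The reference implementation of these
indices uses a proprietary weighting; `ansflow`'s composite is therefore a
documented, configurable approximation whose absolute values differ from
that software by an affine transform. Every correlation, Spearman rank and
regression analysis downstream is unaffected by affine changes, which is
why no test (and no acceptance quantity) depends on absolute index values.
The shipped norms (`inst/extdata/hrv_norms.yaml`) are synthetic
representative resting-adult values and are fully overridable.

A constant RR series is handled gracefully: mean RR/HR and RMSSD are
defined, while SI and the SD1/SD2 ratio are degenerate there (zero range,
zero SD2) and are reported as `NA` with a warning rather than aborting the
subject.

## EGG dominant frequency

EGG channels are analysed with a single full-record Hann taper and FFT
(no Welch averaging — matching a one-FFT-per-channel protocol), one-sided
power scaled so that summed power equals tapered-signal energy (a tested
Parseval identity). Records shorter than 300 s are rejected: resolving
the 0.033–0.066 Hz gastric band needs at least ~10 slow-wave cycles. DF
is the in-band power argmax per channel (ties to the lowest frequency,
consistent with PF), and the subject-level DF is taken from the channel
with the largest in-band peak — the strongest slow-wave site among the 8
electrodes. Down-sampling from the acquisition rate applies an 8th-order
Butterworth anti-alias filter (cut-off 80% of the target Nyquist) run
forward-backward over an odd-reflection-padded signal, then decimates.

## The statistical layer

* Spearman correlation: exact permutation p for $n \le 9$ without ties,
  t approximation otherwise (checked against full $5!$ enumeration).
* FDR: Benjamini–Hochberg step-up (checked against the brute-force
  definition), Benjamini–Yekutieli selectable.
* Frequency-wise group comparison: one-way ANOVA per frequency bin,
  BH-FDR across bins, and *contiguity labelling* of maximal significant
  runs as clusters. This is deliberately not permutation cluster-mass
  inference — the procedure is transparent and each labelled frequency is
  individually FDR-significant; a permutation option is a natural
  extension point.
* PF regression: ordinary least squares of SNSi/PNSi on PF with
  intercept; external validation predicts indices from new PF values and
  compares with observations by paired t-test plus limits of agreement.
  An exact-agreement input is flagged as degenerate rather than tested.

## Synthetic generators: what they emulate

The deposited study recordings are not needed to exercise the pipeline;
the generators reproduce the *statistical structure* each stage consumes.

* **Bilateral perfusion** = shared cardiac-band oscillator (sinusoid at
  `pf_target` with slow Ornstein–Uhlenbeck amplitude and phase drift,
  weight `shared_fraction`) + per-side independent band-limited noise and
  low-frequency myogenic (~0.1 Hz) and respiratory (~0.3 Hz) components
  (weight `1 − shared_fraction`), on a 50 PU baseline with a 0.9 right/left
  gain asymmetry. This gives a single tunable coherence peak; the OU drift
  keeps coherence < 1 whenever noise is present. At `shared_fraction = 1`
  the sides are exact affine copies (coherence 1 everywhere); at 0 they
  are independent (coherence at the $1/K$ bias floor).
* **RR series**: direct sinusoidal modulation
  $RR_i = \overline{RR} + a_{RSA}\sin(2\pi\,0.25\,t_i) +
  a_{LF}\sin(2\pi\,0.1\,t_i + \varphi) + \varepsilon_i$. Direct
  modulation (rather than integral pulse frequency modulation) is simpler
  and sufficient for the monotonicity properties the tests need: RSA
  depth drives RMSSD/SD1/PNSi, mean RR drives HR/SNSi.
* **EGG**: per-channel slow wave at `egg_df_cpm/60` Hz with gentle
  amplitude modulation and channel-specific amplitudes (one designated
  loudest channel) over 1/f-shaped noise.
* **Cohort tables**: PF ~ Uniform(1.0, 1.5) plus per-group shifts
  (defaults +0.06/+0.03/0 Hz for the 4 °C/10 °C/30 °C groups — arbitrary
  magnitudes mimicking post-stimulus separation, config-exposed), and
  indices from the generating linear models `SNSi = 6.48 PF − 7.23`,
  `PNSi = −5.27 PF + 5.96` with noise variance
  $\sigma^2 = \beta^2\,\mathrm{Var}(PF)\,(1-R^2)/R^2$ so the population
  $R^2$ equals the target (0.779 / 0.686). This calibration identity is
  verified empirically at $n = 10^5$ within ±0.01.
* **`simulate_study()`** couples the signal level to the cohort level:
  each subject's perfusion oscillator sits at their true PF and their RR
  parameters vary monotonically with PF (shorter RR, shallower RSA at
  higher PF), so the full pipeline run end-to-end reproduces the
  qualitative study result — Spearman PF–SNSi positive, PF–PNSi negative,
  both FDR-significant on a 60-subject cohort.

What the generators do **not** emulate: non-stationarity beyond slow
drift, movement artifacts, vasomotion spectra with realistic $1/f$
structure in the cardiac band, ectopic-beat morphology, electrode noise
correlations, or any temperature/TRP-channel physiology. Passing tests
demonstrate correctness of the *estimators and their couplings* under the
assumed signal structure, not fidelity to any particular hardware.

All generator randomness flows from one seed per call through an isolated
RNG scope (the global RNG stream is untouched), making every output
byte-reproducible.

## Numerical choices and degenerate inputs

* Coherence is clipped to $[0,1]$ (floating-point can overshoot by
  rounding); bins with zero spectral mass report 0.
* Argmax ties (PF and DF) resolve to the lowest frequency —
  deterministic and conservative.
* Welch demeans each segment, so the DC bin carries no power by
  construction.
* `correct_artifacts` needs ≥ 3 beats; detrending ≥ 3; Poincaré ≥ 3;
  stress index ≥ 20 beats and a non-degenerate histogram.
* Classed conditions (`ansflow_parameter_error`, `ansflow_data_error`,
  `ansflow_degenerate_error`, `ansflow_quality_error`, …) let batch
  drivers isolate per-subject failures; `pf_for_cohort()` and
  `run_pipeline()` continue past failing subjects and report them.

## Problem sizes used by the test-suite

Simulation-based checks use fixed seeds and these sizes, chosen to make
sampling error negligible relative to the tested effect: closed-loop
PF/DF recovery over 100 seeds of 300 s recordings; regression-coefficient
recovery at n = 2000 within 3 standard errors; R² calibration at
n = 100 000 within ±0.01; the frequency-wise detection property at 20
seeds × 3 groups × 12 subjects of 120 s records; the end-to-end sign
pattern on one 60-subject simulated study. The reduced record lengths in
the frequency-wise check trade frequency resolution for simulation count;
the detection property is unchanged.

## Known limitations

* The composite indices approximate the reference software's proprietary
  weighting by documented equal-weight z-scores; absolute PNSi/SNSi
  values are comparable only up to an affine transform.
* The cluster procedure controls the per-frequency FDR, not a
  cluster-level error rate.
* The generators are assumption-bearing stand-ins; conclusions about
  real recordings require the real data.
* Frequency-domain HRV (LF/HF power) is deliberately out of scope: the
  pipeline this package implements does not use it.
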