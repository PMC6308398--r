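---
title: "Classifying negative emotion from peripheral physiology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying negative emotion from peripheral physiology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physioaffect)
```

## The problem

Negative affect (fear, anxiety) produces a stereotyped autonomic response:
heart rate rises (RR intervals shorten), electrodermal activity increases in
both its tonic level (skin conductance level, SCL) and its phasic event rate
(skin conductance responses, SCRs), and peripheral skin temperature falls.
`physioaffect` implements a *user-customized* two-class classifier — negative
versus basic (neutral) emotional state — built from exactly these signals:
a subject watches two hour-long stimuli, one neutral and one fear-inducing,
while ECG, skin temperature (SKT) and electrodermal activity (EDA) are
recorded at 1 kHz; the pipeline then extracts windowed features, cleans
outlying windows, selects the per-subject most informative features, and
evaluates a small neural network by leave-one-out cross-validation (LOOCV).

"User-customized" is load-bearing: which physiological features carry the
emotion signal varies across people, so feature selection is refit per
subject rather than fixed globally.

## Pipeline stages

### Windowing

Features are computed over 5-minute sliding windows stepped by 30 s — five
minutes is the standard short-term HRV analysis length, and a 30-s step
yields 111 windows over a 60-minute recording. Assuming the emotion is not
yet induced at the start of a stimulus, the **last 100 windows** of each
recording are retained, giving 100 feature vectors per condition (200 per
subject).

### The 16 features

*ECG (9).* R peaks are detected with a Pan–Tompkins-style chain (zero-phase
5–15 Hz Butterworth band-pass, derivative, squaring, 150-ms moving
integration, adaptive signal/noise thresholding, 200-ms refractory period);
RR intervals outside (300, 2000) ms are rejected as artifacts. Time-domain
features over a window's intervals \(RR_1..RR_N\):

- Mean HRV \(= \frac1N\sum RR_i\) (ms)
- \(SDNN = \sqrt{\frac{1}{N-1}\sum (RR_i - \overline{RR})^2}\)
- \(RMSSD = \sqrt{\frac{1}{N-1}\sum_{i=2}^{N} (RR_i - RR_{i-1})^2}\)
- \(NN50 = \#\{|RR_i - RR_{i-1}| > 50\,\mathrm{ms}\}\), and
  \(pNN50 = NN50/N \times 100\).

Frequency-domain features come from the RR tachogram, cubic-spline resampled
at 4 Hz and analyzed by Welch averaging (256-sample Hann segments, 50%
overlap): total power TP over 0.003–0.4 Hz, LF over 0.04–0.15 Hz, HF over
0.15–0.4 Hz, the ratio LF/HF, and the normalized powers
\(nLF = LF/(LF+HF)\), \(nHF = HF/(LF+HF)\). By construction \(nLF + nHF = 1\),
so these two features are mirror images of each other.

*SKT (2).* Mean and sample SD of the windowed signal after downsampling to
50 Hz and zero-phase 1-Hz low-pass filtering.

*EDA (5).* The windowed 50-Hz signal is resampled to 32 Hz and decomposed
with a level-10 db3 discrete wavelet transform; the tonic component (SCL) is
the reconstruction of the level-10 approximation band, whose width is
\(32/2^{11} = 0.015625\) Hz, and the phasic component (SCR activity) is the
residual, so tonic + phasic reproduces the working signal exactly. Features:
phasic zero crossings and SD; tonic mean, SD and amplitude (max − min).

All 16 features are min-max normalized to \([0,1]\) per subject over the
pooled 200 windows.

### Outlier removal

Motion artifacts and stretches where the emotion was simply not induced
produce windows that do not belong to either class distribution. Each
class's windows are modeled as multivariate normal (ridge-regularized
covariance, \(\lambda = 10^{-6}\) of the mean diagonal), and a window is
removed when its squared Mahalanobis distance to *its own* class exceeds the
\(\chi^2_{16}\) quantile threshold (default 0.975). Removal is a single
pass, one fit per class.

### Feature selection

Per feature, the class-conditional distributions on \([0,1]\) are estimated
with 10 equal-width histogram bins and one pseudo-count per bin (smoothing
keeps the divergence finite), and features are ranked by

\[ D_{KL}(p \,\|\, q) = \sum_x p(x)\log_2 \frac{p(x)}{q(x)} \]

with \(p\) the negative-emotion class and \(q\) the basic class. Features
are then added one at a time in ranking order; after each addition the
cumulative information gain \(IG_k = H(S) - \sum_t p(t) H(t)\) is computed
over the cells \(t\) of the **joint median-split partition** of the top-k
features (each feature binarized at its pooled median). This partition
refines as k grows, so \(IG_k\) is non-decreasing and bounded by the label
entropy \(H(S)\). The set is cut at the convergence point: the smallest k
whose forward difference \(IG_{k+1}-IG_k\) falls strictly below half the
maximum forward difference, provided \(IG_k\) has climbed at least a quarter
of the curve's total range above its minimum; a flat curve selects k = 1,
and if no k qualifies all features are kept.

### Classifier and evaluation

The classifier is a one-hidden-layer perceptron: hidden width = (number of
input features − 1, floor 1), sigmoid activations throughout, trained by
full-batch backpropagation on the summed binary cross-entropy with constant
learning rate 0.01 for exactly 2000 iterations, weights initialized
uniform(−0.5, 0.5) from a seed. Evaluation is leave-one-out
cross-validation with per-fold seeds (base + fold index), aggregating
confusion counts over folds into accuracy, sensitivity, specificity, PPV
and NPV; the positive class is negative emotion. Linear and quadratic
discriminant comparators (equal priors, ridge-regularized pooled or
per-class covariance) are evaluated under the same folds.

## The synthetic-recording simulator

No public recordings exist for this protocol, so the package ships a
seedable simulator that reproduces the *directions* of the autonomic
effects; none of the magnitudes below come from measured data — they are
deliberately clear-cut choices, fixed once, so that downstream stages have
an unambiguous recovery target.

| parameter | basic | negative | rationale |
|---|---|---|---|
| RR mean (ms) | 850 | 750 | heart rate rises under fear |
| RR SD (ms) | 50 | 40 | modest variability change |
| SCR rate (/min) | 2 | 6 | more phasic events under arousal |
| SCR amplitude (µS) | 0.3 | 0.6 | larger responses |
| tonic SCL (µS) | 4 | 8 | higher conductance level |
| SCL drift (µS/min) | 0.005 | 0.02 | slow electrode/arousal drift |
| SKT base (°C) | 33.5 | 33.0 | peripheral vasoconstriction |
| SKT drift (°C/min) | 0 | −0.01 | cooling under sustained fear |

RR intervals are i.i.d. truncated normal (no autocorrelation structure) —
enough to drive the time-domain HRV features, but *not* a realistic
tachogram: real RR series carry respiratory sinus arrhythmia and baroreflex
rhythms, so the LF/HF-type features see only broadband noise here. The ECG
is a 1-mV Gaussian R-spike template at each beat (no P/T waves), EDA is
tonic level + drift plus biexponential SCRs (rise 0.75 s, decay 4 s) at
Poisson times, SKT is baseline + drift; channels carry white Gaussian noise
and are synthesized at 1 kHz to mirror the acquisition rate. Consequently,
passing tests demonstrate correct *mechanics* (formulas, band splits,
calibration, recovery of programmed effects), not performance on real
physiology: with effect sizes this clear, near-perfect LOOCV accuracy is
expected and observed, whereas real recordings put accuracy far from 100%.

## Numerical choices and degenerate inputs

- **Mean HRV** is the arithmetic mean of the intervals: the SDNN definition
  centers its variance on Mean HRV, which is only coherent for the
  arithmetic mean.
- **NN50** counts successive differences exceeding 50 ms in magnitude (the
  verbal definition of the quantity), and pNN50 divides by N.
- **Welch settings** (4-Hz tachogram, 256-sample Hann, 50% overlap) are a
  conventional choice; no estimator is canonical for this feature set.
- **EDA working rate 32 Hz**: a level-10 approximation band of width
  0.015625 Hz corresponds to a 32-Hz signal (\(32/2^{11}\)), not a 50-Hz
  one, so the signal is resampled 50→32 Hz before decomposition. Boundary
  handling is half-point symmetric extension.
- **Zero crossings** are strict sign changes; zero samples attach to the
  previous sign.
- **Zero-phase filtering** uses forward-backward Butterworth passes over
  reflection-padded signals, so a constant is reproduced exactly and
  low-frequency content is not delayed; anti-alias filtering always
  precedes decimation.
- **Constant features** cannot be min-max scaled and are set to 0.5 with a
  warning. Windows with zero HF power (undefined LF/HF) are dropped with a
  warning.
- **Ties at the output unit** (probability exactly 0.5) go to the positive,
  negative-emotion class.
- **Flat IG curves** (maximum forward difference 0) select k = 1: the
  strict-inequality convergence test cannot fire, and a curve that never
  rises has converged at the start.

## Design decisions that were genuinely open

- **Loss normalization.** Only the learning rate (0.01) and iteration count
  (2000) are fixed by the protocol; with a *mean* cross-entropy gradient
  those settings barely move the weights (effective step 1/n), so the
  package uses the classic summed-over-samples batch gradient, under which
  separable data reach 100% training accuracy within the budget.
- **Per-class outlier fitting.** The normality assumption is stated per
  emotion class, so one Gaussian per class is the default; a pooled mode
  exists as an option.
- **KLD direction.** \(p\) = negative, \(q\) = basic. The divergence is
  asymmetric and no canonical assignment exists; the direction is surfaced
  in the diagnostics and configurable in effect by relabeling.
- **Selection leakage.** Normalization bounds, outlier fits and feature
  selection are computed once per subject on all 200 windows, before LOOCV —
  matching the original protocol but leaking label information into the
  folds. `runPipeline(strictCV = TRUE)` refits selection inside every fold
  for an honest comparison.
- **Known limitation of the convergence rule.** For conditionally
  independent signal features at a 3-SD class shift, the population value of
  the second-to-first IG-difference ratio is ≈ 0.494 — a hair under the
  rule's ½ threshold — so the rule stops at k = 2 about half the time at
  n = 200 even though three informative features exist. The cut is
  conservative by design; users wanting a fuller set can inspect the
  ranking and IG curve directly, both of which are returned.

## Problem sizes used in the shipped checks

Unit tests run on seconds-to-minutes of synthetic signal; the end-to-end
checks use one subject at the full study geometry (two 60-minute
recordings, 111 windows per condition, last 100 kept, 200 feature vectors)
and verify: structural counts (16 features = 9 + 2 + 5; 100 windows per
condition), exactness of the closed-form feature/divergence/metric
formulas, wavelet band-split quality, \(\chi^2\) calibration of outlier
removal, planted-signal selection behavior across 20 seeds, LOOCV
separation of the simulated conditions, a shuffled-label null at chance
level, and bit-identical reproduction of the whole pipeline under a fixed
seed (determinism is checked at a 15-minute problem size). The
`scripts/acceptance.R` script reruns the full-scale pipeline from scratch
and writes every headline number it computes as JSON.
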