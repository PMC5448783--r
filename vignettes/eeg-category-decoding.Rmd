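---
title: "Decoding stimulus categories from EEG: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus categories from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdecode)
```

# The decoding problem

A participant views grayscale photographs from K balanced categories;
each image appears for one second and each presentation is recorded as a
`channels x samples` epoch (128 channels at 250 Hz in the emulated
design, so a 128 x 250 matrix per trial, with both presentations of an
image averaged before analysis). The task is multivariate pattern
analysis: decode the category from the joint spatio-temporal pattern, not
from any single channel. This vignette explains the model implemented by
the package, the choices that were genuinely open, and what the test
suite does and does not establish.

# Feature extraction: a random convolutional bank

Every channel row `y` is processed independently by one convolutional
layer and one pooling layer:

* valid cross-correlation with M kernels of length f:
  `σ_m(p) = Σ_j W[m, j] y[p + j − 1] + b_m`, giving map length
  `L = N_s − f + 1`;
* a pointwise nonlinearity, by default the classical sigmoid
  `g(σ) = 1/(1 + e^{−σ})` (a `tanh` switch is provided because both
  nonlinearities are conventional for such layers);
* non-overlapping pooling of width w (block mean by default, max by
  flag), discarding the `L mod w` trailing samples.

At the reference geometry (`N_s = 250`, `f = 130`, `w = 11`, `M = 100`)
each channel row yields exactly `100 · floor(121/11) = 1100` features;
“valid” convolution is the only boundary convention that reproduces this
count, which is why padding is not offered. Features carry provenance
(channel, map, pooled position) end to end.

The kernels are drawn once from N(0, `init_sd`²) with `init_sd = 0.1`
and never trained: the extractor is a seeded random projection bank. No
training loss is defined anywhere in the pipeline, which keeps the
feature stage strictly independent of the labels — an important property
for the leakage guarantees below. Cross-correlation rather than flipped
convolution is used; with symmetric-law random kernels the two are
distributionally identical, so the choice is recorded only for
reproducibility.

# Feature selection

For a class pair, every feature is scored with the Welch two-sample
statistic (unequal variances, Welch–Satterthwaite degrees of freedom)
and two-sided p-value. Features at p ≥ α (α = 0.05) are excluded;
the rest are ranked by ascending p, ties broken by descending |t| and
then feature index. Ranking by p versus |t| differs only across unequal
degrees of freedom; p was chosen because the exclusion rule is itself a
p-value screen. Subset sizes run 50, 100, …, 5000 (100 nested levels) by
default.

Two design rules matter more than the statistic:

* **Selection is fitted inside every training fold.** Selecting on the
  full data set before cross-validation would leak test information and
  inflate accuracy; the suite verifies by mutation that corrupting test
  trials cannot change the fitted ranking.
* **Multiclass selection** takes the union of the per-pair top-n sets,
  the least committal reading when only pairwise contrasts are defined.

If nothing passes the screen (possible in tiny folds), the single
smallest-p feature is used so the classifier stays defined.

# The LRBSF classifier

For class c and selected feature k, a Gaussian KDE
`f̂_{c,k}` is fitted on the training values of that class with
Silverman's rule `h = 0.9 · min(s, IQR/1.34) · n^{−1/5}`. A test vector
is scored by the summed log marginal densities
`S_c = Σ_k log f̂_{c,k}(x_k)`; a pair is decided by
`log LR = S_1 − S_0 ≥ log η` (boundary to the alternative class), K > 2
by `argmax_c S_c` with ties to the smallest class index.

Assumptions and numerical choices:

* **Class-conditional independence across features.** Scores sum log
  *marginal* densities — a naive-Bayes-with-KDE reading, the only one
  consistent with treating the per-feature densities as univariate. The
  selected features are correlated in reality (neighbouring pooled
  positions overlap), so the scores are a working approximation, not a
  true joint likelihood.
* **Density floor.** Densities are floored at 1e−300 before the log, so
  far-out test points give large-but-finite penalties rather than −∞,
  and ties fall through the stated tie rules.
* **Degenerate features.** A zero-spread training sample would give
  h = 0; the bandwidth falls back to 1e−6 times the feature's scale so
  the model stays proper.
* **Threshold η.** Default 1 (log-threshold 0), the neutral point at
  which the two-class rule coincides with argmax. Optionally η is tuned
  by maximising training accuracy over midpoints of consecutive sorted
  training scores (ties resolved toward η = 1); tuning buys training
  accuracy by construction, so the suite checks that it does not move
  held-out accuracy off chance under the null. The likelihood-ratio
  testing literature would instead fix η by a nominal level α; that
  construction is recorded in the decision rule but unused, since
  accuracy-maximising thresholds are what the evaluation protocol needs.

# Evaluation protocol

Monte-Carlo cross-validation: 100 repetitions of a stratified random
90/10 split (proportional per class, remainder round-robin over a
randomly rotated class order so 1-trial folds are not biased toward one
class). The split stream is a pure function of the seed, labels and test
fraction, so LRBSF and SVM runs under one seed share identical splits.
Per-pair sweeps report an accuracy-versus-subset-size curve; the
headline accuracy is the curve maximum, which matches the reporting
convention the package emulates but is optimistically biased across
sizes — the curve itself is always retained so readers can judge.

Two standard errors are reported for the mean accuracy: the naive
`sd/√R` over repetitions, and a cluster-robust version that first
aggregates correctness per distinct test trial. Repetitions reuse
trials, so rep accuracies are positively correlated and the naive SE is
too small; calibration assertions in the suite use the cluster-robust
SE.

Chance levels: the empirical threshold is the (1−α) quantile of accuracy
over 1000 draws of uniform random guessing against balanced labels
(equivalent to label permutation for an uninformative classifier and far
cheaper than refitting; a `refit` hook accepts the full refit variant).
The analytic threshold is the binomial (1−α) quantile m/n, the smallest
m with `pbinom(m, n, 1/K) ≥ 1−α` — 58% at n = 100, K = 2, α = 0.05,
approaching 100/K as n grows. Method comparison uses paired two-sided
t-tests against a reference method and one-way ANOVA across methods.

Baselines: full multilevel DWT coefficient vectors per channel row
(implemented in-package: analysis/synthesis filter-bank cascade for
haar/db2/db4 with zero-padding and periodization boundaries — the former
retains every coefficient of the padded signal and so conserves energy at
any length, the latter is the textbook orthogonal transform at dyadic
lengths), and a one-vs-one soft-margin SVM (linear kernel, C = 1) under
the identical CV protocol. No wavelet/level choice is canonical for this
pipeline; db4 at the maximum feasible depth is the default.

# The synthetic generator

`generate_epochs()` emulates the study design: K = 5 categories, 52
images each, presented twice, 128 channels at 250 Hz, 1-s epochs. Each
class adds a Gaussian-windowed half-sine bump (peak-normalised so the
maximum sample equals the stated amplitude) on a fixed "posterior"
channel block, with class-staggered latencies (0.10 s + 0.05 s per
class, width 80 ms); the background is a per-channel mixture of
spectrally shaped 1/f noise (random phases, zero DC) and white noise.
Defaults: amplitude 5 µV, noise 10 µV with pink fraction 0.7 — amplitudes
and SNR are not pinned down by the emulated design, so these were chosen
once as typical visual-ERP magnitudes against ongoing EEG, for
testability rather than biological fidelity.

What the generator does *not* model: eye-blink/muscle artifacts,
electrode drift, inter-subject variability, trial-order effects, or any
spatial covariance beyond the shared bump. Passing tests therefore show
that the pipeline is correct and calibrated — unbiased at chance under
the null, able to detect injected class differences — not that any
particular accuracy is attainable on real recordings.

# Problem sizes used by the suite

Test and acceptance runs use reduced but structurally faithful scales,
chosen so the complete suite exercises every path at full statistical
fidelity: null-calibration runs use 16 channels and 20 images per class
(40 or 100 averaged trials, 17 600 features) with 100 MC-CV repetitions,
replicated over independent simulations (3 in the tests; 20/12 in the
acceptance script) because the per-dataset CV mean under the null has
substantial dataset-level variance at 40 trials — averaging replicates
estimates the same chance-level quantity with smaller Monte-Carlo error.
Oracle-equivalence tests (convolution, KDE scoring, wavelet cascades)
run on tiny instances where brute force is exact.

# Known limitations

* Random (untrained) kernels mean feature quality rests entirely on the
  bank size M; there is deliberately no gradient training hook.
* The score model ignores feature dependence; strongly correlated
  features double-count evidence.
* Maximising the accuracy curve over subset sizes inflates the headline
  relative to a pre-registered size.
* The EDF reader supports one sampling rate across ordinary channels
  and reads annotations from a single "EDF Annotations" signal, which
  covers the common single-rate recording layout.
* Bandwidths are per-feature Silverman rules; heavy-tailed or
  multimodal feature distributions would warrant cross-validated
  bandwidths, not provided here.
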