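---
title: "Sub-band entropy and ensemble learning for seizure detection: methods"
author: "episeizer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-band entropy and ensemble learning for seizure detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episeizer)
```

## The problem and the model

Ictal (seizure) EEG is dominated by high-amplitude rhythmic discharges,
while interictal background activity is irregular and broadband.
`episeizer` turns that contrast into a binary classifier for
single-channel records through four stages:

1. **Wavelet sub-band decomposition.** Each record is decomposed with a
   five-level discrete wavelet transform using the orthonormal
   Daubechies-4 (db4, 8 taps) filter pair, giving detail sequences
   $d_1,\dots,d_5$ and a final approximation $a_5$. At the 173.61 Hz
   sampling rate of Bonn-style records, $d_3$, $d_4$ and $d_5$ jointly
   cover roughly 3–25 Hz — the band where ictal rhythms concentrate —
   while $d_1$/$d_2$ carry mostly high-frequency noise and $a_5$ slow
   drift. Keeping only $d_3$–$d_5$ *is* the denoising step; no
   coefficient shrinkage is applied.
2. **Entropy features.** For each selected sub-band, two regularity
   statistics are computed: approximate entropy
   $\mathrm{ApEn} = \phi^m(r) - \phi^{m+1}(r)$ and sample entropy
   $\mathrm{SampEn} = -\log(A/B)$, with embedding dimension $m = 2$, time
   delay $t = 1$ and tolerance $r = 0.2\,\mathrm{SD}$. Rhythmic ictal
   sub-bands are self-similar, so their entropies are low; irregular
   interictal sub-bands score high. Six features per record result.
3. **Ranking and selection.** Features are ranked by the one-way ANOVA
   $F$ statistic (between-class over within-class mean square; for two
   groups, the square of the pooled two-sample $t$). Forward sequential
   feature selection then grows a prefix of the ranking, scoring each
   candidate subset by the cross-validated error of the full ensemble,
   and stops at the first strict error increase.
4. **Ensemble classification.** Three base learners — a least-squares SVM
   with linear kernel, 3-nearest-neighbours with Euclidean distance, and
   Gaussian naive Bayes — are trained on the selected, z-scored features;
   the record label is their majority vote. With three voters and binary
   labels a tie is impossible.

Performance is estimated by stratified 10-fold cross-validation:
per-fold accuracies, pooled sensitivity $TP/(TP+FN)$ and specificity
$TN/(TN+FP)$, and the area under the ROC curve of the ensemble score.

## Entropy conventions

Published ApEn/SampEn definitions differ in small but consequential
details; the package fixes them as follows.

* **Template matching** uses the Chebyshev (maximum-coordinate) distance
  with the **strict** inequality $d < r$; ties $d = r$ do not match. The
  same rule applies to both estimators.
* **ApEn includes the self-comparison** $j = i$, so every per-template
  correlation count is positive and all logarithms are defined. With
  this convention a constant sequence has ApEn exactly 0. Small negative
  ApEn values are possible for short, match-poor sequences; the test
  suite flags them everywhere except for frozen-oracle equality checks.
* **SampEn excludes self-matches** and counts unordered template pairs
  over the same $N-m$ start positions at lengths $m$ and $m+1$, so
  $A \le B$ and $\mathrm{SampEn} \ge 0$. If $B = 0$ the statistic is
  undefined and a typed error carrying the counts is raised; if $A = 0$
  with $B > 0$, `Inf` is returned as a documented sentinel. Records
  producing non-finite entropies are excluded from a feature matrix with
  a warning.
* **Tolerance** is $r = 0.2 \times$ the **population** SD (divisor $N$)
  of the sequence actually analysed — each sub-band by default — making
  the features amplitude-invariant. Both choices are configurable
  (`sdType = "sample"`, `toleranceSource = "signal"`); at $N \approx
  4000$ the SD divisor is immaterial, but the contract should be exact.
* **Natural logarithms** throughout; entropies are reported in nats.
* Entropies are computed on the decimated detail **coefficient**
  sequences by default. The alternative reading — full-length
  single-sub-band reconstructions — is available via
  `representation = "reconstructed"`; the two are different statistics
  of the same band and the default was chosen because the per-level
  filter-bank outputs are the natural objects of the pyramidal
  algorithm.

## Wavelet numerics

The filter bank is implemented directly (no wavelet package is
required): per level, correlation with the scaling/wavelet pair followed
by dyadic decimation. Two boundary policies are provided:

* `symmetric` (default) — half-sample signal extension, the common
  convention in EEG denoising; per-level length $\lfloor (L+7)/2
  \rfloor$ for the 8-tap filter. The inverse operator is the exact
  adjoint, and reconstruction is exact to floating-point rounding
  (tested at $10^{-8}\,\max|x|$).
* `periodization` — circular convolution; the transform matrix is
  orthogonal, so squared coefficients sum to the signal energy (tested
  at $10^{-6}$ relative). Requires even lengths at every level.

The test suite checks both modes against an independent naive
convolve-and-decimate oracle with its own hard-coded taps.

## Classifier details

* **LS-SVM.** Training solves the KKT system
  $\bigl[\begin{smallmatrix}0 & y^\top\\ y & \Omega + I/\gamma
  \end{smallmatrix}\bigr](b,\alpha)^\top = (0,\mathbf 1)^\top$ with
  $\Omega_{ij} = y_i y_j \langle x_i, x_j\rangle$, and the decision value
  is $f(x)=\sum_i \alpha_i y_i \langle x_i,x\rangle + b$. The
  regularization weight $\gamma$ has no canonical reference value; the
  default is $\gamma = 10$, and the acceptance tests verify the
  end-to-end result is unchanged across $\gamma \in \{1, 10, 100\}$ —
  on well-separated entropy features the solution is insensitive to it.
* **KNN.** $k = 3$ (odd, so binary votes cannot tie), Euclidean
  distance, distance ties broken towards the lower training index.
* **GNB.** Per-class, per-feature Gaussian likelihoods with priors from
  training frequencies. Variances are floored at $10^{-9}$ times the
  largest overall feature variance so constant features never produce
  degenerate densities.
* **Tie policy.** `sign(0)` and all exact ties resolve to $+1$ (ictal),
  uniformly and deterministically — for a screening tool the
  conservative direction is towards the positive class.
* **Scores.** The ensemble is a hard voter; its ROC score is the
  fraction of base learners voting $+1$ (values $\{0, \frac13, \frac23,
  1\}$). A `"calibrated"` mode (mean of a logistic squash of the LS-SVM
  decision value, the KNN neighbour fraction and the GNB posterior)
  gives a finer-grained score for ROC plots.

## Evaluation protocol choices

* **Stratified folds** are the default: with balanced classes they fix
  the per-fold class ratio and stabilise fold accuracies.
* **Selection placement.** The reference workflow ranks and selects
  features once on the full dataset and then cross-validates the
  selected subset (`selectionMode = "full"`). This leaks selection
  information into the CV estimate; `selectionMode = "nested"` re-runs
  ranking and FSFS inside every training fold and is the honest
  generalization estimate. The default reproduces the reference
  workflow; the vignette flags the distinction rather than hiding it.
* **FSFS evaluator.** The stopping rule needs a classification error;
  the package uses the CV error of the *full voting ensemble* on the
  candidate subset (the system's own classifier), on folds drawn once
  per selection run so all candidate subsets see identical splits. Equal
  error does **not** stop the search — only a strict increase does.
* **Pooled metrics.** Sensitivity, specificity and the confusion matrix
  are pooled over folds (single numbers, not per-fold means); fold SD is
  computed over the 10 fold accuracies with divisor $k - 1$.

## The synthetic world

`generateDataset()` exists so that every stage is testable without any
download. Defaults state the emulated world once: 50 records per class,
4096 samples at 173.61 Hz (~23.6 s);

* *ictal-like*: $3.0 \times \sum_h w_h \sin(2\pi h f_0 t + \varphi_h)$
  with $f_0 = 5$ Hz, harmonic weights $(1, 0.4, 0.2)$, random phases,
  plus white noise of SD 0.3 — a regular, high-amplitude rhythm inside
  the 3–25 Hz band;
* *interictal-like*: unit white noise through the recursion
  $y_n = 0.9\,y_{n-1} + e_n$ (lag-1 autocorrelation ≈ 0.9, a crude 1/f
  rolloff) plus a weak 10 Hz alpha component of amplitude 0.3.

The generator plants exactly the effect the method detects — low
sub-band entropy for rhythmic records — so a green end-to-end test
establishes that the pipeline recovers a planted, well-separated
contrast; it does **not** establish clinical performance. Known
non-realism: no spike-wave morphology, no artifacts, no non-stationarity
within a record, and stationary Gaussian noise. One consequence worth
stating: even with the oscillation amplitude set to zero the two classes
remain distinguishable (white vs. AR(1)-filtered noise differ in
sub-band entropy), so chance-level behaviour is verified by permuting
labels, not by degrading the generator.

Records shorter than ~2000 samples leave the $d_5$ band with only a few
dozen coefficients; irregular records can then have $A = 0$ (SampEn
infinite) and are excluded with a warning. The default record length
never triggers this.

## Degenerate inputs and numerical tolerances

* Constant sequences: tolerance $r = 0$ is undefined; feature extraction
  maps constant sub-bands to entropy 0 (a constant signal is perfectly
  regular) instead of failing.
* Zero within-class variance makes the ANOVA $F$ infinite (flagged with
  a warning); infinite $F$ values rank first, which is the intended
  ordering.
* The LS-SVM system is solved densely; a singular system (exactly
  duplicated samples with conflicting labels at extreme $\gamma$) raises
  an error suggesting a different $\gamma$.
* Oracle-equality tests run at $10^{-12}$ (entropies, GNB log-odds),
  $10^{-9}$ (LS-SVM decisions, ANOVA-$F$ vs $t^2$) and $10^{-10}$
  (wavelet coefficients vs the naive filter bank).

## Limitations

* Single-channel only; no EDF/BDF readers, no artifact rejection.
* Only the db4 wavelet is built in, matching the reference
  configuration; the module boundary accepts a wavelet name so further
  filters can be added without interface changes.
* The default protocol's full-dataset feature selection is optimistic by
  construction (see above); use nested mode for unbiased estimates.
* Reported headline accuracies on real ictal/interictal corpora depend
  on unstated reference choices ($\gamma$, fold seeds); the package
  documents its own defaults and exposes all of them in
  `pipelineConfig()`.

## A worked run

```{r example, eval = FALSE}
ds <- generateDataset(synthConfig())        # 50 + 50 records, seed 42
res <- runPipeline(ds, seed = 42)
res$ranking                                  # ANOVA-F ordering
res$selection                                # FSFS trace and subset
res$metrics                                  # 10-fold CV report
```
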