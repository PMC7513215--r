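---
title: "Entropy features and kernel PCA for two-state EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy features and kernel PCA for two-state EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Mental-state recognition from EEG — the motivating case is driver fatigue —
faces two obstacles: raw multichannel recordings are high-dimensional and
strongly nonlinear, and the discriminative information is carried less by
amplitude than by the *irregularity* of the signal. `eegkpca` implements a
three-stage pipeline that addresses both:

1. **Complexity features.** Each channel of each short epoch (1 s at
   1000 Hz by default) is summarized by sample entropy, producing an
   epochs-by-channels feature matrix (600 × 30 for ten subjects, 60 s each,
   over 30 electrodes).
2. **Kernel PCA.** The feature matrix is reduced by principal component
   analysis in a kernel-induced feature space, with the number of retained
   components chosen by cumulative variance contribution (CVC).
3. **SVM classification.** A soft-margin support-vector classifier is
   trained on the reduced scores under stratified cross-validation.

# Sample entropy

For a length-$N$ epoch $x(1),\dots,x(N)$, embedding dimension $m$ and
tolerance $r$, let $B$ be the number of unordered template pairs
($i \neq j$) whose $m$-length templates are within Chebyshev distance $r$,
and $A$ the analogous count at length $m+1$. Then

$$\mathrm{SampEn}(m, r, N) = -\ln\frac{A}{B}.$$

We use the canonical Richman–Moorman counting convention: self-matches are
excluded, templates run over $i = 1,\dots,N-m$ at both lengths, and the
distance is the true Chebyshev distance
$\max_k \lvert x(i+k) - x(j+k)\rvert$. Defaults are $m = 2$ and
$r = 0.25\,\mathrm{SD}$, the standard choices for EEG; the SD is the
epoch's own *population* standard deviation (divide by $N$), computed per
epoch, so the tolerance rescales with the data and SampEn is invariant
under affine amplitude transforms. Degenerate epochs (zero variance) and
undefined ratios ($A = 0$ or $B = 0$) raise typed conditions instead of
returning numbers, because silent zeros would poison the downstream
eigenanalysis; an opt-in median-imputation policy exists for batch
extraction.

Fuzzy entropy replaces the hard threshold by the graded membership
$\exp(-d^{n}/r)$ on mean-centered templates. Combination entropy is only
*cited* in the driving-fatigue literature without a reproducible formula,
so the package exposes it as a pluggable slot whose shipped default — the
mean of sample and fuzzy entropy — is a clearly labelled stand-in, not a
reimplementation of that estimator.

# PCA, kernel PCA and component selection

Linear PCA follows the correlation-matrix convention: standardize each
feature (sample SD, $n-1$), eigendecompose
$R = Y^\top Y/(m-1)$, and report contribution rates
$C_i = \lambda_i / \sum_q \lambda_q$. Kernel PCA solves the dual problem
$M\lambda a = \tilde K a$ on the double-centered Gram matrix

$$\tilde K = K - 1_M K - K 1_M + 1_M K 1_M, \qquad (1_M)_{ij} = 1/M,$$

normalizes the dual vectors so each feature-space axis has unit length
($a_k^\top \tilde K a_k = 1$), and projects new samples through the
test-versus-train kernel centered with the *training* statistics — the
choice that keeps cross-validation leak-free. Four kernels are provided:
linear, $P$-order polynomial $[(x \cdot y) + 1]^P$, Gaussian RBF, and the
sigmoid (MLP) kernel $\tanh(v (x \cdot y) + c)$.

Components are selected as the smallest $k$ whose cumulative contribution
reaches the CVC threshold (0.90 / 0.95 / 0.99 are the conventional
operating points). The cumulative sum is taken over the rates as given,
*without* renormalizing by their total: this is how published
per-component tables are read, and it is the only convention that
reproduces the component counts stated for the bundled reference tables
(`contribution_rate_table()`).

## Numerical choices

* **RBF exponent.** The bandwidth form is
  $k(x, y) = \exp(-\lVert x-y\rVert^2/\delta^2)$, the standard
  squared-distance Gaussian; $\delta$ is the protocol's $\sigma$
  (preferred value 0.2).
* **Standardization before KPCA** is *off* by default. The KPCA procedure
  takes the entropy matrix directly and performs its centering in feature
  space, and the $\sigma = 0.2$ bandwidth is meaningful on the raw entropy
  scale (nats): typical within-state epoch-to-epoch distances are a few
  tenths of a nat, comparable to $\sigma$, while between-state distances
  are much larger. Standardizing first would rescale columns so that
  *every* pairwise distance dwarfs $\sigma$, the Gram matrix would
  collapse toward the identity, and out-of-sample projections toward zero.
  A `standardize` flag restores the other behaviour.
* **Indefinite kernels.** The sigmoid kernel is not Mercer; negative Gram
  eigenvalues are truncated (relative threshold $10^{-10} \cdot
  \lambda_{\max}$, count recorded in `n_dropped`) and contribution rates
  are computed over the retained non-negative spectrum.
* **CVC threshold comparison** uses a `1e-9` epsilon so that exact
  decimal thresholds are not missed through binary accumulation
  (`0.6 + 0.3 < 0.9` in floating point).
* **Extended-precision accumulation** in the fuzzy-entropy membership
  sums: the two sums have on the order of $N^2/2$ terms and feed a log,
  so plain double accumulation would cost ~$10^{-12}$ relative accuracy
  on 1000-sample epochs.
* **Sign convention.** Eigenvectors are sign-fixed so their first nonzero
  coefficient is positive, making fits reproducible; score comparisons
  across routes are still done up to sign.

# Classification protocol

The reference protocol states both 3-fold cross-validation and a 70/30
split; these are inconsistent (a 3-fold split tests on one third). The
default here is stratified 3-fold CV, with a single stratified 70/30
holdout available as `protocol = "holdout"`; every report names the
protocol used. SVM settings are unstated in the source protocol, so the
package fixes documented defaults: RBF kernel with bandwidth
$\sqrt{p}$ on $p$ input features (kernel scale $1/p$ on the squared
distance) and $C = 1$, all exposed in `pipeline_config()`. The SMO solver
is deterministic, so identical seed, data and configuration give bitwise
identical reports. Accuracy is the arithmetic mean of fold accuracies,
rendered at two decimals. Fold assignment is stratified by row; subjects
contribute contiguous blocks of epochs, so a subject-grouped split would
be the conservative alternative — rows from one subject can fall in
training and test folds here, which is also true of the protocol being
emulated.

# The synthetic generator

Real two-state EEG from driving-fatigue studies is not publicly
deposited, so `simulate_eeg()` provides a stated world in which every
stage is testable: each subject contributes 30 s of an alert state
(broadband Gaussian noise, high irregularity) followed by 30 s of a
fatigue state (a subject-specific 9–11 Hz alpha-band oscillation at twice
the noise SD, plus noise reduced to 30%), across 30 channels at 1000 Hz.
The state contrast is a single dial: at `contrast = 1` the fatigue recipe
is fully applied (mean SampEn drops from ≈ 1.97 to ≈ 0.70 nats at the
defaults), at `contrast = 0` both states share the alert recipe and the
pipeline must fall to chance. Amplitude gain is jittered log-normally per
subject and channel, which leaves sample entropy untouched by design —
the two states differ *systematically in irregularity only*, which is
precisely the assumption the entropy-feature method rests on.

What the generator does **not** emulate: 1/f background spectra, artifact
and eye-movement contamination, inter-channel correlation structure,
non-stationary drift, or realistic per-subject variability in entropy
level. A green end-to-end test therefore establishes that the pipeline
recovers a complexity-mediated state difference under clean conditions —
not that it reaches any particular accuracy on clinical recordings.

# Known limitations

* Sample entropy is $O(N^2)$ per epoch (with first-coordinate pruning);
  a 600-epoch, 30-channel extraction takes tens of seconds.
* The combination-entropy default is a stand-in (see above).
* The EDF reader covers continuous, equal-rate EDF only (no EDF+
  annotations, no per-signal rates).
* The built-in SVC is binary; multi-state problems would need a
  one-vs-one wrapper.
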