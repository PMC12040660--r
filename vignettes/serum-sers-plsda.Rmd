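---
title: "Classifying serum SERS spectra with PLS-DA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying serum SERS spectra with PLS-DA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersclass)
```

# The problem

Surface-enhanced Raman spectroscopy (SERS) of blood serum records, in one
quick optical measurement, a fingerprint of the small molecules and
proteins circulating in a patient. A typical diagnostic study collects a
few replicate spectra per subject for a patient ("Target") group and a
healthy donor ("Control") group, and asks whether a classifier built on
the spectra separates the groups — and, if it does, *which vibrational
bands* carry the separation, because those point at the underlying
metabolites.

`sersclass` implements that complete workflow: preprocessing of raw
spectra, partial least squares discriminant analysis (PLS-DA) written
from scratch, a repeated subject-level split validation protocol, and
variable-importance band reporting. A seeded synthetic cohort generator
stands in for patient sera, so every stage of the pipeline is testable
end to end without instrument data.

# Preprocessing

Raw serum SERS spectra are sharp vibrational peaks riding on a smooth,
intense autofluorescent background, plus detector noise. Preprocessing
runs three stages per spectrum, in a fixed order:

1. **Savitzky–Golay smoothing** (`savgol_smooth()`), window 15 channels,
   polynomial order 1, no derivative. Each point is replaced by the
   center value of a least-squares line fitted over the sliding window.
   Edges are handled by point-symmetric (odd) reflection about the first
   and last samples. This convention — rather than even mirroring — is
   deliberate: odd reflection continues a locally linear signal exactly,
   so the filter reproduces affine spectra to machine precision all the
   way to the boundary, a property the test suite asserts at `1e-10`.

2. **Baseline removal** (`baseline_correct()`), polynomial degree 15.
   A degree this high is enough that a naive monomial fit at
   raw wavenumbers is numerically singular; the fit therefore uses an
   orthogonal polynomial basis on the axis rescaled to $[-1, 1]$. A
   plain least-squares polynomial would be dragged upward by the peaks,
   so the default scheme is the iterative *modified polyfit*: after each
   fit, points above the current fit are clipped down to it and the
   polynomial is refitted, until the residual standard deviation changes
   by less than `tol = 1e-3` (relative) or `max_iter = 100` rounds pass.
   On peak-free input the clipping never activates and the scheme
   degrades gracefully to the plain fit (available as
   `method = "plain"`). The function returns both parts, and
   `corrected + baseline` reconstructs the input to float round-off.

3. **Standard normal variate** (`snv()`): each spectrum is centered to
   mean zero and scaled to unit sample standard deviation (the $n-1$
   convention, used everywhere in the package). SNV removes the
   per-measurement global intensity scale, which in SERS varies strongly
   with substrate enhancement.

The order matters and is part of the contract — SNV last guarantees
every preprocessed row has mean 0 and sd 1, which the suite checks.

A per-spectrum signal-to-noise ratio is defined as the peak-to-peak
range of the smoothed signal divided by the sample standard deviation of
the smoothing residual (`estimate_snr()`); a noise-free spectrum returns
`Inf` by contract. One caveat: at the default 2 cm⁻¹ channel spacing the
15-channel window spans 28 cm⁻¹, wider than many serum bands, so the
smoothing residual contains systematic peak distortion on top of the
noise and the estimate reads below the true amplitude-to-noise ratio.
It is reported as a quality indicator, not used by the classifier.

# PLS-DA

The classifier is univariate-response partial least squares (PLS1)
on the dummy coding Target = 1, Control = 0, fitted by NIPALS with
X-deflation (`pls_fit()`). For each latent component $a = 1, \dots, A$:

$$
w_a = \frac{X_a' y}{\lVert X_a' y \rVert}, \quad
t_a = X_a w_a, \quad
p_a = \frac{X_a' t_a}{t_a' t_a}, \quad
q_a = \frac{y' t_a}{t_a' t_a}, \quad
X_{a+1} = X_a - t_a p_a',
$$

with $X_1$ the column-centered predictor matrix and $y$ centered.
Because the response is univariate, each weight vector is available in
closed form and no inner iteration is needed. Regression coefficients on
the original centered predictors are assembled as
$b = W (P'W)^{-1} q$, and prediction is
$\hat y = \bar y + (x - \bar x)' b$ with the class rule
Target $\iff \hat y \ge 0.5$ (ties to Target; both the coding and the
threshold are isolated in one place). The suite verifies the standard
identities — unit-norm weights, orthogonal scores, monotone training
residual, equality with OLS at full rank — and checks coefficients
against an independent reference implementation (mixOmics).

**Variable importance in projection** (`vip()`) is the canonical
weight-based form,

$$
\mathrm{VIP}_j = \sqrt{\; p \cdot \frac{\sum_a SS_a \, w_{ja}^2}
                          {\sum_a SS_a}}, \qquad
SS_a = q_a^2 \, t_a' t_a,
$$

with $p$ the channel count, so $\operatorname{mean}(\mathrm{VIP}^2) = 1$
by construction and 1 is the conventional more-important-than-average
cutoff used by `band_report()`. Descriptions of VIP as a "weighted sum
of squared correlations" are sometimes read as using literal
component–variable correlations instead of the normalized weights; for
components extracted by NIPALS the two agree closely, and the canonical
weight-based formula is the one implemented because it is the one with
the exact normalization identity.

**Component selection** (`select_components()`) uses k-fold
cross-validation with k = 7 by default, over a candidate grid 1–15
capped at the rank bound. Two choices deserve emphasis:

- *Folds are formed from subjects, never spectra*, stratified by class.
  Replicate spectra of one subject are correlated; letting them straddle
  a fold would leak information and overstate accuracy.
- *Exact ties go to the smallest component count.* Accuracy on a modest
  held-out set is a coarse (stepped) criterion, so ties are common, and
  parsimony is the guard against overfitting.

# The validation protocol

`run_protocol()` repeats, 30 times by default: split subjects of each
class 80/20 into training and test (`floor(0.8 n)` per class, so 38
Target and 24 Control subjects train by default); select the component
count by subject-grouped CV *on the training set only*; fit; score both
subsets; record specificity (Control recall), sensitivity (Target
recall), accuracy, and ROC AUC. AUC is the exact Mann–Whitney statistic
— the probability that a random Target spectrum outscores a random
Control spectrum, ties counting one half — computed via midranks
(`roc_auc()`). Results are aggregated as mean (min–max) per metric per
subset, the customary reporting shape rendered by `table3_render()`.

Metrics are computed per spectrum: each replicate counts separately,
matching how cohort sizes are usually reported (144 and 88–90 spectra
rather than 48 and 30 subjects), and no subject-level vote rule needs to
be invented. A subject-level mean-score vote is available behind
`subject_vote = TRUE` but is not the default.

All randomness in iteration $i$ derives from `base_seed + i`, so any
prefix of the protocol is bit-reproducible, which the suite asserts.

The single-band comparator (`single_band_accuracy()`) mirrors the
common clinical question "would one band suffice?": the feature is the
mean preprocessed intensity over a band, classified by an
accuracy-optimal threshold chosen on the training subjects of the same
repeated splits. It exists to show the gap between a univariate rule and
the full multivariate model.

# The synthetic cohort generator

`generate_cohort()` emulates the structure of a near-infrared serum
SERS case–control study: 48 Target and 30 Control subjects with 3
replicate spectra each, on a 400–1800 cm⁻¹ axis at 2 cm⁻¹ steps (701
channels). Each spectrum is

$$
s(\nu) = b(\nu) + f \sum_k a_k \, L_k(\nu) + \varepsilon(\nu),
$$

where $L_k$ are Lorentzian lines at common serum SERS positions
(`default_serum_peaks()`), $b$ is a smooth background (low-order
polynomial plus one wide Gaussian) scaled per subject, and
$\varepsilon$ is i.i.d. Gaussian channel noise. The group effect
multiplies the amplitudes of peaks inside the effect bands — 632,
721–735 and 1048–1076 cm⁻¹ by default — by `effect_ratio` in the Target
group (`effect_ratio = 1` produces an exchangeable null cohort).

The amplitude factors are the part that carries the cohort's
correlation structure, and they were designed deliberately:

- **Per-peak subject factors** (`subject_sd = 0.30`, log-normal, shared
  across a subject's replicates). A *scalar* per-subject factor would be
  removed entirely by SNV and contribute nothing to the features the
  classifier sees; per-peak factors give each subject a persistent
  spectral phenotype, which is exactly what makes subject-level
  splitting (rather than spectrum-level splitting) matter.
- **Per-peak replicate factors** (`replicate_sd = 0.25`, log-normal,
  independent per spectrum). Replicate SERS acquisitions of one dried
  serum drop differ substantially in relative band intensity because
  enhancement is heterogeneous across the substrate. Omitting this made
  the subject phenotype implausibly persistent: single bands classified
  almost perfectly, and the no-effect cohort showed inflated
  cohort-level chance separation under repeated resplitting.
- **Noise** `noise_sd = 0.02` puts the additive-noise SNR
  (peak-to-peak signal over noise sd) near 65, i.e. on the order of
  50 as such instruments deliver. Shot-noise scaling is deliberately
  omitted — it is not identifiable from summary SNR statements.
- The **effect peaks are a modest share of total intensity**
  (amplitudes 0.26–0.30 against a tallest band of 0.8). Because SNV
  rescales whole spectra, doubling a *large* share of intensity shifts
  the normalization and smears the group difference onto unrelated
  strong bands; keeping the share modest keeps the planted difference
  concentrated at the planted bands, which is the structure the
  generator is meant to emulate.

What the generator does **not** emulate: real metabolite band shapes
and overlaps, wavenumber calibration drift, cosmic-ray spikes,
heteroscedastic (shot) noise, substrate chemistry, or any clinical
covariate structure (age, sex, disease activity). Consequently, passing
the pipeline's recovery tests on synthetic cohorts demonstrates that the
*software* is correct and leakage-free — it does not validate the
published diagnostic performance on patient sera, which would require
the original (undeposited) measurements.

Cohort sizes note: 30 Control subjects × 3 replicates gives 90 spectra;
published control arms sometimes report slightly fewer (e.g. 88) after
acquisition drop-outs, so the generator exposes `drop_spectra` (default
0) to trim trailing control spectra.

# Numerical choices and degenerate inputs

- Sample (n−1) standard deviations everywhere.
- SNV errors on constant spectra; `estimate_snr()` returns `Inf` for a
  zero residual; `baseline_correct()` requires `degree < n − 1` and
  finite input; `savgol_smooth()` requires an odd window no longer than
  the spectrum.
- `band_report()` accepts any threshold ≥ 0; at 0 every channel
  qualifies and the whole axis is one interval.
- Preprocessing failures are reported with the offending
  `spectrum_id`; protocol iterations whose test fold would lack a class
  abort with a clear message (impossible at the default cohort sizes).
- Model JSON serialization writes 17 significant digits, and the
  spectra CSV writer uses `%.17g`, so both round-trip doubles exactly.

# Problem sizes used in the tests

Unit tests run on reduced cohorts (10 + 8 subjects, 2 replicates,
201 channels) chosen to exercise every code path in seconds. The
end-to-end acceptance tests and `scripts/acceptance.R` run the full
study-scale design — 48 + 30 subjects × 3 replicates × 701 channels,
30 protocol iterations, both the strong-effect and the null cohort —
which completes in about a minute on one core.

# Known limitations

- PLS-DA here is strictly two-class (PLS1); no multiclass, sparse or
  kernel variants.
- The accuracy-optimal single-band threshold is a stepwise criterion;
  with few test subjects its iteration-to-iteration variance is large.
- The null protocol's test accuracy concentrates near the majority
  class share (0.625 at 48/30 with threshold 0.5), not 0.5; chance
  behavior should be judged primarily by AUC.
- With 78 subjects resampled 30 times, cohort-level chance structure
  makes the null protocol's mean test AUC vary by roughly ±0.1 across
  cohort draws; this is a property of the design, not a bug, and is the
  reason the no-signal check uses a wide band around 0.5.
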