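---
title: "Methods behind the bloodscore ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the bloodscore ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodscore)
```

This vignette records how the Abnormal Blood Profile Score is modelled in
`bloodscore`: the procedure and its assumptions, the defaults and why they
were chosen, the numerical decisions, and what the synthetic cohorts can
and cannot tell you about real athlete data.

## The scoring pipeline

A profile is scored in a fixed order: **validate → clip → component scores
→ ensemble average → calibrate → band**. Each stage is exposed as its own
function, so intermediate quantities are inspectable
(`predict(fit, x, type = "components")`).

**Validation and clipping.** All seven markers must be finite and strictly
positive. Each marker is then restricted to an allowed range; out-of-range
values are moved to the nearest bound and a warning reports every modified
value. The hemoglobin bounds, 12.9 and 18.2 g/dL, are fixed by the method's
published description. The other six pairs are wide physiological ranges
chosen here (HCT 35–55 %, MCH 24–36 pg, MCHC 30–38 g/dL, MCV 75–105 fL,
RBC 3.5–6.5 × 10⁶/µL, RETP 0.1–3.0 %) and are deliberately overridable via
`marker_ranges()`: the originally used bounds for these six markers are not
public, so the defaults are stand-ins, not claims. Clipping applies to the
ensemble inputs only; the OFF-score is computed on raw values, since range
restriction is documented as part of the ABPS algorithm, not of the
OFF-score.

**Naive Bayes component.** The method's description names a naive Bayesian
classifier without fixing a density family. We use one-dimensional Gaussian
kernel density estimates per marker per class — the standard nonparametric
choice for continuous markers, able to follow the bimodal reticulocyte
distribution that ON/OFF-phase doping produces. Bandwidths follow
Silverman's rule of thumb (`bw.nrd0`). Densities are evaluated by exact
summation over the stored training sample with log-sum-exp, so far-tail
profiles get finite log densities instead of underflowing to −∞. Class
priors are equal by default: the 402:189 composition of a training cohort
is a sampling artifact, not a population prior; priors are a parameter for
users who disagree.

**SVM component.** A soft-margin SVM with Gaussian RBF kernel in
standardized marker space; `C = 1` and the median-pairwise-distance width
heuristic are the defaults because the original kernel and hyperparameters
are likewise unpublished. The quadratic program is solved by
`kernlab::ksvm` (tolerance 10⁻⁷); the support vectors, signed dual
coefficients, and intercept are extracted, the decision orientation is
fixed so doped profiles score positive, and all subsequent decision values
are computed by package code from those stored quantities. Duplication of
training data is equivalent to rescaling `C` by the duplication factor
*when the standardization constants and kernel width are held fixed*, which
is why `train_svm()` accepts them as explicit arguments.

**Ensemble averaging.** The published description names "ensemble
averaging" without weights. We standardize each component score by its
mean and standard deviation over the training controls and take the
unweighted mean — the canonical reading; the standardization constants are
stored in the model, so alternative weighting can be layered on the
component scores if needed.

**Calibration.** Whether the original score is explicitly calibrated or its
reference statistics are simply empirical is not documented; here
calibration is explicit and optional. A strictly monotone piecewise-linear
quantile map is fitted from the empirical quantiles of a reference raw
score sample (the training controls by default, or any sample of ≥ 100
scores) to the target quantile function of a `reference_spec()`. The target
is a normal backbone (mean −0.67, sd 0.87 for `reference_all`) deformed by
a piecewise-linear correction in probability space so the published
anchors — 2.5th percentile −2.35 and 97.5th percentile 1.0 — are hit
exactly; the correction vanishes at p = 0, ½, 1 so the centre and tails
stay normal-shaped. The two published tail statements (the 95% interval of
the all-athletes reference collection, and the 1-in-1,000 exceedance for
clean males) describe *different populations* and are mutually inconsistent
for a single normal distribution, so they are shipped as two separate
presets that are never merged: `clean_male` keeps the mean at −0.67 and
derives its sd from the q₀.₉₉₉ = 1 anchor, since no clean-male moments are
published. Note a consequence of honouring the printed anchors exactly:
pinning q₀.₉₇₅ to 1.0 (slightly inside the normal value 1.035) compresses
the upper tail, so a calibrated population's sd comes out near 0.855 rather
than exactly 0.87 — within the sampling tolerance we accept, and the price
of exact anchor reproduction.

**Bands.** Literal reading of the published wording: suspicion is the
closed interval [0, 1]; abnormal is strictly above 1; anything below 0 is
typical. OFF-score flagging is likewise strict (`> 133`), since values
"over" the threshold are what the source describes; the threshold is a
parameter because other populations have other published thresholds.

## Numerical choices

* Calibration knots: 47 probabilities spanning 0.001–0.999 plus the spec
  anchors. Duplicate empirical quantiles (possible in very discrete
  samples) are collapsed; a non-strictly-increasing knot sequence is a hard
  error rather than a silent repair. Beyond the outermost knots the map
  extrapolates linearly with the terminal segment slopes, keeping it
  strictly increasing on all of ℝ.
* Kernel rows and KDE sums are computed with elementwise operations and
  row-wise summation (no BLAS matrix products) in chunks of 4,000 rows:
  threaded BLAS kernels can round an entry differently depending on its
  position in the batch, which would break exact invariance of scores under
  row permutation. The chunking bounds memory at ~10 MB per chunk while
  keeping 100,000-profile scoring in well under a minute.
* Model files are JSON with 17 significant digits, the minimum that
  round-trips IEEE-754 doubles exactly; a reloaded model reproduces scores
  bit-identically. Files are schema-versioned and marker order is
  canonicalized on load.
* Randomness exists only in cohort generation and the SVM solver; both
  take explicit seeds, and `simulate_cohort()` restores the caller's RNG
  state.

## The synthetic cohort generator

The generator emulates the *structure* the ensemble assumes, not any real
athlete database (whose marker distributions are unpublished — no attempt
is made to match them beyond physiological plausibility). Defaults:

* Cohort sizes 402 control / 189 doped, matching the size of the original
  training database; sex ratio 0.5.
* Clean primaries (HGB, RBC, MCV, RETP) are multivariate lognormal per
  sex — medians 14.5/13.2 g/dL HGB (male/female), 5.0/4.6 × 10⁶/µL RBC,
  90 fL MCV, 1.0 % RETP; log-sds 0.055, 0.06, 0.045, 0.35; correlations
  HGB–RBC 0.65, RBC–MCV −0.35, HGB–MCV 0.10. The log scale guarantees
  positivity; RETP's larger log-sd reflects its strong right skew.
* Derived markers come from the hematological identities HCT = MCV·RBC/10,
  MCH = HGB/RBC·10, MCHC = HGB/HCT·100, times lognormal noise (log-sd
  0.012, 0.010, 0.008) truncated at 4 sd — so the identities hold to within
  the coherence bounds (|MCHC − HGB/HCT·100| ≤ 2 g/dL,
  |MCV − HCT/RBC·10| ≤ 8 fL) for every generated profile, preserving the
  marker dependencies the classifiers implicitly exploit.
* Doped profiles multiply the HGB and RBC medians by 1.10 and 1.07,
  inflate the log-scale covariance by 1.3, and split 50/50 into an ON
  phase (RETP × 2.2) and an OFF phase (RETP × 0.35), reflecting rhEPO
  pharmacodynamics: stimulated reticulocyte production during
  administration, suppression after withdrawal.

These effect sizes are configuration, chosen once to produce a
well-separated but overlapping cohort; they are not measurements of real
doping effects. Consequently, passing tests demonstrate that the machinery
discriminates, calibrates, and stays coherent under the stated
distributional assumptions — they do **not** establish sensitivity or
specificity on real athletes, where analyzer drift, pre-analytical
variation, altitude, sport and sex structure, and doping regimes beyond
rhEPO all intrude. The `doping13` fixture is likewise a constructed
longitudinal illustration, not data from any real case.

## Problem sizes used in validation

The test suite and the acceptance script use 100,000-profile synthetic
reference populations for calibration-recovery checks (large enough that
the 2.5th-percentile estimate has sampling error well below the 0.05
acceptance band), 10 seeded replicates with 70/30 held-out splits of the
591-profile default cohort for the discrimination comparison, and
exhaustively enumerable toy problems (8-sample KDE cohort, 4-point SVM)
for oracle equivalence, where brute-force recomputation is exact.

## Known limitations

* Scores from models trained on synthetic cohorts are not comparable to
  official ABPS values: the original trained parameters and training
  database are unpublished, and reproducing them is out of scope.
* The 12-marker score variants, population correction factors, and
  longitudinal passport modelling are not implemented.
* KDE naive Bayes assumes conditional independence of markers given class;
  the derived-marker identities violate this, which in practice costs
  calibration of the NB log odds but little discrimination — one reason
  the ensemble averages it with the SVM, which models the joint space.
* The clipping ranges for the six non-HGB markers are this package's
  documented defaults, not the original implementation's values.
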