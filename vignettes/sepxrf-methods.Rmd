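---
title: "Methods: pXRF seafood elemental profiling, QC statistics, and provenance models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pXRF seafood elemental profiling, QC statistics, and provenance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and scientific setting

`sepxrf` implements the statistical side of a portable X-ray fluorescence
(pXRF) soft-tissue profiling protocol for seafood: instrument calibration
against a reference assay, the protocol's quality-control statistics, a
paired comparison of drying treatments, chemometric pre-treatment, and
preliminary provenance modelling of multi-element concentration profiles.
The motivating application is authenticating the origin (harvest site,
farmed vs wild production, raw vs cooked preparation) of prawns from a
14-element fingerprint (P, S, Cl, K, Ca, Mn, Fe, Ni, Cu, Zn, As, Sr, Zr,
Th), with major elements above 1000 ppm and minors below 100 ppm.

Real datasets of this kind are typically commercial-in-confidence, so the
package ships a first-class synthetic-data generator whose defaults encode
the emulated study design: 8 provenance groups of 5 specimens across 6
sites (two collections at one site, cooked and uncooked groups at another),
counting-statistics instrument errors, and a heavily zero-inflated As
channel. Every downstream module is exercised and tested against this
generator.

# The synthetic world

## Concentration model

For sample $i$ in group $g$ and element $e$, the true concentration is

$$
C_{ie} = \mu_e \cdot s_{\mathrm{site}(g),e} \cdot b_{g,e}
         \cdot \kappa_e^{[\mathrm{cooked}]} \cdot \pi_e^{[\mathrm{wild}]}
         \cdot \varepsilon_{ie},
\qquad \varepsilon_{ie} \sim \mathrm{logN}(-\sigma_e^2/2,\ \sigma_e^2),
$$

with $\mu_e$ the baseline (ppm), $s$ per-site and $b$ per-group
("collection", i.e. batch/seasonal) multiplicative effects, $\kappa$ the
cooking and $\pi$ the production multipliers, and lognormal biological
scatter parameterised by a coefficient of variation
($\sigma_e^2 = \log(1 + \mathrm{cv}_e^2)$). The lognormal choice keeps
concentrations strictly positive and right-skewed; the noise mean
correction makes all effect multipliers act on expectations, so with all
effects equal to one the group means coincide exactly.

Defaults and why:

* `noise_cv = 0.2`: 20% biological scatter is typical of trace-element
  variation among conspecific tissue samples.
* Cooking raises Cl, Zn, Th, Cu, Mn by 1.5x and lowers Zr to 0.6x; wild
  production raises S by 1.3x and lowers Ni to 0.7x. These directions are
  the emulated narrative; the magnitudes are **illustrative, not
  estimated** — no quantitative effect sizes exist to copy.
* Site and collection effects are deterministic log-normal patterns drawn
  once from a frozen stream (independent of the user's seed) and scaled by
  `site_effect_scale` (default 0.15) and `collection_effect_scale`
  (default 0.1). The collection effects are what distinguish two groups
  sharing a site and preparation (two collection dates); without them such
  groups would be distributionally identical and no classifier could ever
  separate them.
* Planted correlations: Ca loads on K (0.92) and P (0.25), Fe on S (0.92)
  and K (0.25), in both the within-group noise and the auto-built
  site/collection patterns. Coupling the between-group patterns is
  necessary — if only the within-group noise were correlated, any
  appreciable between-group variance would dilute the pooled Pearson
  correlation below the 0.8 filter threshold. The interpretation is that
  geochemically coupled elements carry a coupled provenance signal.
* Zero inflation: As has a zero probability of 37/40 and, by default
  (`zero_exact = TRUE`), the zero count is planted exactly, so exactly 3
  of 40 readings are nonzero. Zeroing happens after noise and zeroes the
  instrument error too: the instrument reports a non-detect, not a noisy
  zero.

## Instrument model

Instrument errors follow counting statistics,
$\mathrm{err}_{ie} = k_e \sqrt{C_{ie}} / \sqrt{t}$ for exposure time $t$
(default 60 s per beam). Default $k_e$ gives roughly 3% relative error for
major and 10% for minor elements at 60 s, comfortably inside the
one-third detection rule. Percent error therefore decays as
$c_e/\sqrt{t}$, which is the exposure-time curve the slope-improvement
rule is applied to.

Instrument bias is a pure per-element slope: the uncalibrated reading is
$C/b_e$ (no intercept), so the correction-factor fit has a known truth
$b_e$. Defaults plant realistic factors (0.18–2.2), including negative
slopes for Ni and As — instruments can report inverted factory-calibrated
channels — and missing values for Zr and Th, whose concentrations sit
below the reference assay's detection limit. `generate_profile_table()`
returns true-scale concentrations by default; the pipeline's simulate
stage sets `apply_bias = TRUE` so its calibrate stage corrects genuinely
biased readings.

What the generator does **not** emulate: energy spectra, matrix/moisture
attenuation physics, detector heat retention across consecutive
exposures, or inter-element spectral interferences. A green test
establishes that the statistics behave as designed on data with this
structure — not that the instrument behaves.

# Calibration

`fit_correction_factors()` regresses reference concentrations (response)
on instrument readings (predictor), per element, with an intercept; only
the slope is kept as the correction factor, since a single factor per
element is the published convention. A through-origin option exists. The
axis assignment is genuinely ambiguous in the field; this orientation
makes "corrected = factor x reading" exact and is configurable upstream
via the generator's bias definition.

Noise lives on the instrument readings, i.e. on the predictor, so the OLS
slope is attenuated by errors-in-variables. Generated calibration sets
deliberately span a wide concentration range (reference CV 0.5), which
keeps the attenuation near 1% at 5% instrument noise — inside the 2%
recovery tolerance the package tests. With narrow-range calibration sets
the attenuation would dominate; that is a property of the design, not of
the estimator.

Negative factors are applied as-is with a warning; negative corrected
concentrations are floored at zero and counted. An absent (N/A) factor is
never silently 1: the element passes through flagged "uncalibrated".

# QC statistics

* **Detection rule**: a reading is confidently quantified iff
  `error < concentration / 3`, strictly. Zero readings abstain. Element
  inclusion from per-reading passes is not defined anywhere precisely, so
  the package requires a strict majority of the nonzero readings to pass
  (configurable); this is deterministic and monotone in data quality.
* **Exposure-time rule**: consecutive slopes $S_k$ of the percent-error
  curve; improvement rate $100\,|S_k - S_{k+1}|/|S_k|$; the selected time
  is the boundary point shared by the first slope pair whose rate falls
  strictly below 33% ("no longer improves by at least 33%" is read as a
  strict comparison). On the noiseless $1/\sqrt{t}$ curve sampled at
  15–90 s this selects 60 s, between the third and fourth slopes. A zero
  leading slope defines a 0% improvement (immediate stop, flagged); a
  never-converging series returns the last time flagged.
* **Repeatability delta**: $\Delta = \overline{\mathrm{err}} - \mathrm{se}$
  with $\mathrm{se} = \hat\sigma/\sqrt{n}$, $\hat\sigma$ the $n-1$ sample
  SD of the $n$ replicate readings. The printed form of this statistic in
  the protocol literature sometimes loses the radical ("$\sigma/n$"); the
  standard-error definition is implemented and flagged here. Positive
  $\Delta$ means replicate scatter is within the instrument's
  self-reported error. When scatter is generated at the instrument-error
  scale, $\Delta > 0$ for the vast majority of simulated elements
  ($P(\hat\sigma > \sqrt{5}\,\sigma) \approx 5\cdot10^{-4}$ at $n=5$).

# Moisture comparison

Treatments (towel vs heat-gun drying) are compared per element with a
two-sided paired Wilcoxon signed-rank test, stratified by preparation.
Zero differences are dropped before ranking (the classical treatment and
the default of the R reference implementation). The exact p-value is
computed by dynamic programming over the sign-flip distribution of the
(possibly tied, mid-ranked) rank sums for up to 25 usable pairs. This
matters: with tied absolute differences the reference implementation
falls back to a normal approximation, but the exact sign-flip
distribution is still well defined — five pairs all shifted by +1 give
exactly $p = 2/32 = 0.0625$. Beyond 25 pairs a tie-corrected normal
approximation with continuity correction is used. Elements that are
all-zero in a stratum (non-detects under both treatments) are reported as
the literal `"*"`, not tested. No multiple-testing correction is applied
by default, mirroring raw per-element reporting; Holm is available.

# Pre-treatment

Fixed order: zero-fraction filter (strictly more than 80% zeros removes
the element), correlation filter ($|r| \ge 0.8$, inclusive), z-scaling
(sample SD). Pearson correlation is used; absolute value, since the sign
of a redundant association is irrelevant to redundancy. Which member of a
correlated group to keep is undefined in the field convention; the
package repeatedly drops the element with the largest mean absolute
correlation to the remaining elements (ties: the later element in table
order), until no pair reaches the threshold. Note this can retain two
members of a loosely chained group whose own correlation is below the
threshold — the iterative rule is the precise statement of intent, and
correlation decisions are provably invariant to the later scaling. Both
filters are computed on the full dataset before the train/test split,
exactly as the emulated procedure orders its steps; this is a (mild,
deliberate) leakage inherent to that procedure and is documented rather
than repaired.

# Provenance models

* **Split**: per group, round-half-up of 80% to training; a guard moves
  one random sample to test if rounding empties a group's test cell. For
  8 groups of 5 this yields exactly 32/8 with one test sample per group.
* **Random forest**: authored in-package (no forest package is assumed
  available): CART trees grown to purity with Gini splits, `mtry`
  candidate features per node, bootstrap aggregation, OOB permutation
  importance (mean decrease in accuracy) and split-based mean decrease in
  Gini. Tuning scores every (mtry, ntree) cell by stratified 5-fold CV on
  the training set; one forest of max(ntree) trees is grown per fold and
  mtry and accuracies are read off cumulative votes at each ntree
  checkpoint, so the grid costs one forest per (fold, mtry). Ties prefer
  smaller ntree, then smaller mtry. The default grid includes the
  (mtry 3, ntree 600) cell. The headline accuracy is the 5-fold CV figure
  (tuning is tied to CV); resubstitution and OOB accuracies are also
  reported.
* **LDA** via `MASS::lda`, reporting resubstitution ("training") accuracy,
  which is the convention the emulated analysis uses for its LDA figure.
* **PCA** via `prcomp` on scaled elements; variance explained sums to
  100% over all components.
* **NMDS** via `vegan::metaMDS` on Euclidean distances of scaled
  concentrations by default (Bray–Curtis available), seeded random
  starts, Kruskal stress-1 reported. The distance choice is not fixed by
  the emulated analysis; Euclidean-on-scaled matches the other models'
  geometry.
* **CDA** as classical canonical variates of between- vs within-group
  scatter (at most groups − 1 axes), computed via a Cholesky-whitened
  symmetric eigenproblem; structure coefficients are the correlations
  between each element and each canonical axis. A singular within-group
  scatter produces an error advising the correlation filter.

## What the acceptance checks establish

The emulated study's headline numbers (81% RF/LDA accuracy, its exact
correction factors and p-values) are not recomputable without its
confidential data. The package instead verifies design arithmetic exactly
(32/8 split, 60 s selection, 40 samples, filter boundaries, exact
Wilcoxon p) and parameter recovery stochastically (slope recovery within
2%, delta positivity, chance-level collapse under permuted labels, >= 90%
test accuracy under strongly separated sites). "Axis 1 splits cooked from
raw" is asserted as a standardized separation greater than one pooled SD
between preparations on the first canonical axis, together with the
planted elements dominating its structure coefficients: under biological
noise, strict separability of every sample is not implied by a
narrative-level "split", and the first axis of an 8-group CDA legitimately
mixes cooking with site contrasts.

# Numerical choices and degenerate inputs

* Exact-zero readings abstain from the detection rule; all-zero elements
  are excluded from the roster with a flag.
* A constant instrument channel cannot be regressed on: the element is
  flagged "degenerate" and the remaining elements still fit.
* Constant columns have no defined correlation; they are kept, warned
  about, and never removed by the correlation filter.
* Zero-SD columns abort scaling with the element named (they should have
  been filtered).
* Forest ties (equal votes, equal split gains) resolve deterministically
  to the first candidate, making runs reproducible at fixed seeds.
* All randomness flows from one master seed through fixed derived
  streams (kept below $2^{31}$), so whole-pipeline runs are bit-identical
  across machines.

# Known limitations

* The generator's effect magnitudes are stated, not estimated; absolute
  accuracies on synthetic data do not transfer to any real instrument.
* The pure-slope bias model cannot represent additive offsets; a real
  calibration with intercepts would need matrix-matched standards, which
  are out of scope.
* The in-package forest grows trees to purity (no depth/min-node tuning)
  and is O(n^2) per node in the worst case — appropriate for tens of
  samples, not thousands.
* NMDS stress comparisons across k use the same seeded starts but are
  still local optimisations; monotonicity in k holds up to optimiser
  noise.
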