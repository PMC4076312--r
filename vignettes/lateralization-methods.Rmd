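---
title: "Modeling hemispheric language lateralization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hemispheric language lateralization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateralize)
```

This vignette documents the statistical model behind `lateralize`, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## The inference chain

The package implements a four-stage chain, from individual task-fMRI
contrast maps to population-level statements about handedness and language
dominance:

1. a per-subject **hemispheric functional lateralization index (HFLI)**
   computed by bootstrap resampling of suprathreshold t-values per
   hemisphere;
2. a **univariate Gaussian mixture model** of the HFLI distribution per
   handedness group, with the number of components selected by **AICc**;
3. **lateralization types** (Typical / Ambilateral / Strongly-atypical)
   derived from the fitted density's local minima;
4. **chance-corrected association** between hand dominance and language
   dominance (Cohen's kappa, Fisher exact tests, Spearman correlation, an
   atypical-occurrence regression).

## Bootstrap HFLI

For a t-map with left/right hemisphere masks (an exclusion mask — in real
data, the cerebellum — is removed first), voxels with t strictly above the
threshold (default 0, the "positive t-map") enter per-hemisphere value
lists, canonically sorted. Per hemisphere we draw `n_iter = 100` resamples
with replacement of size `clamp(round(k·n), min_sample, max_sample)` with
`k = 0.25`, `min_sample = 5`, `max_sample = 1000`; all
`n_iter²` pairwise combinations of resample sums give laterality indices
`100(L−R)/(L+R)`, of which the lowest and highest 25% are discarded and the
rest averaged. The threshold, `k` and the two sample-size bounds are the
published operating point of the underlying bootstrap procedure; the
iteration count and symmetric 25% trimming follow the cited toolbox's
defaults, and all are configurable.

Design choices worth stating explicitly:

* **Sums, not counts.** The index weights voxels by t-value magnitude
  (resample sums), matching the "weighted mean" variant of the published
  procedure; a count-based mode is available (`weighting = "count"`) and
  reduces to the suprathreshold voxel-count ratio.
* **Per-hemisphere seeding.** Each hemisphere's resample index stream is
  restarted from the user seed, so the schedule depends only on the seed,
  the hemisphere's voxel count and the resample size. This makes three
  invariants exact rather than approximate: swapping the hemisphere masks
  negates the index; rescaling all t-values by a positive constant leaves
  it unchanged; permuting voxel storage order leaves it unchanged.
* **Degenerate hemispheres.** A hemisphere with fewer than `min_sample`
  suprathreshold voxels invalidates the index (there is too little signal
  to resample), with one exception: a completely empty hemisphere opposite
  a well-populated one is purely unilateral activation and the index is
  ±100 by definition.
* **Threshold ladder.** A multi-threshold variant (per-threshold indices
  averaged with weights proportional to the threshold) exists but is off by
  default; the single-threshold t > 0 path is the reference analysis.

## Gaussian mixture modeling and AICc selection

The HFLI density is modeled as \(f(x)=\sum_{i=1}^{n}\pi_i\,
\varphi(x;\mu_i,\sigma_i)\). Parameters are estimated by EM; the free
parameter count is \(p = 3n - 1\) (n means, n SDs, n−1 weights), which is
the convention required to reproduce the single-Gaussian AICc from its
printed sample moments. Model selection minimizes
\(\mathrm{AICc} = -2\ell + 2p + 2p(p+1)/(N-p-1)\), and each model's
relative likelihood versus the optimum is reported. The default convention
is `exp(AICc_best − AICc_i)`: it is the only convention consistent with the
published selection tables this package reproduces; the conventional
`exp(Δ/2)` is available via `mode = "akaike"`.

Numerical choices:

* **Stability.** Per-point mixture densities are computed in linear space
  with a log-sum-exp fallback for points that underflow under every
  component, so the log-likelihood never spuriously hits −∞. The E/M loop
  is compiled (Rcpp); the log-likelihood is checked to be non-decreasing at
  every iteration and a violation is flagged, not repaired.
* **Convergence.** Absolute tolerance 1e-8 on the log-likelihood, at most
  1000 iterations per restart.
* **Degeneracy.** A component SD falling below `sigma_floor = 0.5` index
  units marks the restart degenerate and it is discarded; if every restart
  degenerates the fit is flagged failed and excluded from ranking.
* **Restarts.** 50 restarts by default. The first uses quantile-spaced
  means; the rest use sorted random data points as means. We initially used
  quantile-spaced means with small random jitter for all restarts, but all
  such starts fall into one basin of attraction: validated per-sample
  against an independent multistart fitter, that scheme left up to ~12 nats
  of log-likelihood unclaimed for overlapping components and distorted
  model selection. With random-point starts the attained optima match the
  independent fitter to < 0.01 nat for n ≤ 4.
* **n = 1** is fit in closed form (sample mean, ML standard deviation).
  Reported summary SDs elsewhere use the n−1 convention; the likelihood
  internally uses the ML convention.
* **Confidence intervals** for mixture parameters are nonparametric
  bootstrap percentiles (resample subjects, refit, match components by
  descending mean); the upstream report did not document its CI procedure,
  so this is the package's own choice, flagged as such.

## From mixture to types

Interior local minima of the fitted density are natural cutpoints. They are
located by scanning the analytic density derivative on a 0.1-step grid for
sign changes and refining by bisection to 1e-3; exact zeros of the
derivative at grid points (symmetric mixtures) and flat stretches where the
density underflows between far-apart components are handled explicitly
(a flat zero run resolves to its midpoint).

Adjacent components whose separating dip is shallow are pooled: the minimum
is dropped when the mixture density there is at least `dip_ratio = 0.8` of
the lower of the mixture densities at the two flanking component means. Two
remarks. First, "modal density" is evaluated at the component means rather
than at the exact local maxima of the mixture; for the reference
right-hander model the top-two-component dip ratio is 0.805 against
component means but 0.7999 against exact modes — the component-mean
convention is what makes the 0.8 default pool the two heavily overlapping
highest-mean components in both handedness groups, which is the behavior
the typing is designed to have (the margin is razor-thin either way, and
`dip_ratio` is configurable). Second, for the reference 4-component
left-hander model the density has *three* interior minima — two deep ones
near −47.5 and 22.1 and a shallow one near 57.8 between the overlapping
top components — and pooling removes exactly the shallow one.

The derived cutpoints for the reference models fall near 22 and −48, close
to but not identical with the operational cutpoints 18 and −50 used for
classification in the upstream study (whose exact derivation was not
published). The package ships the operational pair as a preset
(`hfli_type_cutpoints()`), uses it for all reproduction runs, and reports
the numerically derived minima alongside (`pool_components()`).

Boundary rules: Typical requires HFLI strictly above the upper cutpoint;
Strongly-atypical strictly below the lower one; values exactly at a
cutpoint are Ambilateral. The binary zero-threshold classification calls
strictly positive HFLI "typical", so HFLI = 0 is atypical.

## Association statistics

* **Kappa.** \(\kappa = (P_o - P_e)/(1 - P_e)\) on matched-category square
  tables; significance uses the Fleiss large-sample SE of κ under the null
  of chance agreement with a two-sided normal test (the upstream study
  cites Fleiss without a formula; this is that book's standard choice).
  The 3×3 type × MPS3 kappa is unweighted, with the alignment
  Typical↔Strong R, Ambilateral↔Moderate, Strongly-atypical↔Strong L.
* **Fisher exact tests** delegate to the exact network algorithm
  (`stats::fisher.test`), with a seeded ≥1e5-table Monte-Carlo fallback for
  tables too large to enumerate; the method used is always reported.
* **Edinburgh categorizations.** MPS3: Strong L at score ≤ −55, Strong R
  at exactly 100, Moderate otherwise. MPS7 has single-point extreme
  categories at ±100; published interior interval boundaries overlap at
  −75, 25 and 75, which this package resolves by assigning a boundary score
  to the *lower* category (interior intervals half-open, closed on the
  right) — the resolution that keeps categories mutually exclusive and
  matches the published category examples.
* **Occurrence regression.** Per MPS7 category, the percentage of atypical
  subjects (Ambilateral + Strongly-atypical) is regressed by OLS on the
  category mid-values (−100, −87, −50, 0, 50, 87, 100). The per-category
  atypical counts behind the upstream study's printed slope were not
  published, so this regression is validated structurally (exact recovery
  on noiseless linear input; negative slope on the majority of synthetic
  cohorts), not against a printed value.

## The synthetic-data generator

`generate_cohort()` encodes the study conditions as defaults: 144
right-handers and 153 left-handers; HFLI drawn from the published
3-component (RH) or 4-component (LH) mixture (weights renormalized from
their 3-decimal printed values to sum to 1) and clipped to the index range
[−100, 100]; a lateralization type taken from the generating mixture
component (top two components = Typical); and a manual preference score
drawn from the (handedness, type)-conditional normal with the published
cell moments, clipped to [−100, 100].

What it does *not* emulate, and what that means for the tests: the joint
distribution of MPS and HFLI within a cell is independent (only cell
moments are published), so tests exercise the marginal structure and the
cross-tables, not any residual within-type correlation real data may have.
Clipping a normal at a bound it has real mass beyond shifts the cell mean —
for the RH-Typical cell (93 ± 11, ~26% above 100) the clipped mean is
91.25, and tests assert that closed form, not the nominal 93; clipping is
still the right emulation because roughly a third of real right-handers
score exactly 100, i.e. the observed distribution genuinely has a point
mass at the bound. `generate_tmap()` produces hemisphere-lateralized
Gaussian t-value grids with a posterior exclusion slab; it emulates the
input contract of the HFLI stage (masks, threshold, exclusion), not any
spatial structure of real activation maps. Passing tests therefore
demonstrate correctness of the inference chain under the assumed
distributional structure, not robustness to real-data violations of it.

## Problem sizes

Simulation-based checks use sizes chosen to make Monte-Carlo error
comfortably smaller than the asserted tolerances: 1e5 draws for
law-of-large-numbers and tail-fraction checks (5-SE bounds), 2e4 draws for
large-sample EM consistency, and 100–200 seeded cohorts of n = 153 for the
model-selection recovery study (the acceptance script's 200-replicate run
takes a few minutes on one CPU; the test suite uses the 100-replicate
version).

## Known limitations

* EM with many restarts is an exhaustive ML optimizer: at n ≈ 150 it
  routinely finds genuine but fragile 5-component optima (including
  near-degenerate components just above `sigma_floor`), so AICc selection
  at this sample size picks 5 components in a sizable minority of
  replicates. The modal choice is the statistic to rely on.
* The Fleiss null-SE kappa test is asymptotic; for very sparse tables an
  exact or bootstrap test would be preferable.
* No modeling of covariates (sex, age, education), no regional (per-lobe)
  laterality indices, and no fMRI preprocessing: inputs are assumed to be
  registered t-maps with masks, or precomputed HFLI values.
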