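# lateralize

Tools for studying hemispheric functional lateralization of language — and
its relationship with handedness — from task-fMRI t-statistic maps.

Most people produce language with their left hemisphere, and most people are
right-handed. Whether those two asymmetries share a common cause is a
long-standing question: answering it requires (i) a per-subject index of
language lateralization, (ii) a principled way to classify subjects into
lateralization types from the shape of that index's distribution, and (iii)
association statistics that correct for the agreement expected by chance
alone (with ~90% right-handers and ~90% left-dominance, ~81% concordance
arises from chance). This package implements that full inference chain for
cohorts of healthy volunteers, together with a seeded synthetic-data
generator so every stage is testable without access to subject data.

## What it computes

**Bootstrap HFLI.** The hemispheric functional lateralization index of a
t-map with left/right hemisphere masks (cerebellum excluded) is built from
suprathreshold voxel values (t > 0 by default). Per hemisphere, `n_iter =
100` bootstrap resamples of size `clamp(round(0.25 n), 5, 1000)` are drawn;
all 100 × 100 pairwise indices

```
LI = 100 (L − R) / (L + R)
```

are formed from the resample sums, the top and bottom 25% are trimmed, and
the retained mean is the HFLI (+100 purely left, −100 purely right).

**Gaussian mixture modeling with AICc selection.** The HFLI distribution is
multimodal; it is fit by maximum-likelihood EM as

```
f(x) = Σᵢ πᵢ φ(x; μᵢ, σᵢ),   i = 1..n
```

for n = 1..5 components, with the corrected Akaike information criterion

```
AICc = −2ℓ + 2p + 2p(p+1)/(N − p − 1),   p = 3n − 1
```

selecting n. Each model's evidence versus the optimum is reported as a
relative likelihood, `exp(AICc_best − AICc_i)` by default (an
`exp(Δ/2)` convention is available).

**Typing.** Local minima of the fitted density are classification
cutpoints; heavily overlapping components are pooled (dip-ratio rule).
Subjects are classified as Typical, Ambilateral, or Strongly-atypical —
the operational cutpoints are HFLI > 18, [−50, 18], and < −50 — plus the
classical binary zero-threshold classification.

**Association.** Edinburgh laterality quotient `100(R − L)/(R + L)` with
3- and 7-level categorizations, contingency tables, Cohen's kappa
`κ = (Pₒ − Pₑ)/(1 − Pₑ)` with the Fleiss large-sample null SE, Fisher exact
tests, Spearman rank correlation, and an OLS regression of atypical
occurrence on manual-preference category mid-values.

## Worked example

```r
library(lateralize)

co  <- generate_cohort(seed = 101)                     # 144 RH + 153 LH
sel <- select_mixture(co$hfli[co$handedness == "LH"], 1:5, seed = 101)
sel
#> Mixture model selection (AICc, exp-delta relative likelihood)
#>   n    loglik n_params n_obs     aicc converged n_restarts_used      rel_lik
#> 1 1 -771.1386        2   153 1546.357      TRUE               1 6.758060e-62
#> 2 2 -706.6716        5   153 1423.751      TRUE              50 1.193676e-08
#> 3 3 -694.2538        8   153 1405.508      TRUE              50 1.000000e+00
#> 4 4 -691.9231       11   153 1407.719      TRUE              50 1.096028e-01
#> 5 5 -689.5947       14   153 1410.233      TRUE              50 8.869488e-03
#> Selected: n = 3 components

typed <- assign_types(co)        # preset cutpoints (-50, 18) + 0-threshold
type_summary(typed)
#> # A tibble: 5 × 8
#>   handedness lat_type              n   pct hfli_mean hfli_sd mps_mean mps_sd
#> 1 LH         Typical             124 81.0      60.2    13.4     -53.8  35.9
#> 2 LH         Ambilateral          20 13.1      -6.15   13.2     -63.8  20.7
#> 3 LH         Strongly-atypical     9  5.88    -64.2     4.72    -71.0  16.2
#> 4 RH         Typical             125 86.8      59.7    12.6      91.2   8.25
#> 5 RH         Ambilateral          19 13.2      -6.99   16.2      91.7   9.03

cohen_kappa(collapse_dominance(typed))
#> Cohen's kappa = 0.0564 (Po = 0.5185, Pe = 0.4897, n = 297)
#>   z = 1.348, two-sided p = 0.1778 (Fleiss null SE 0.0418)
```

The selection table reads as in a model-comparison report: the
3-component fit minimizes AICc for this replicate (at n = 153 the rare
lowest-mean component is not always resolved — across many seeded
replicates the modal selected count is 4, matching the generator). In the
summary, ~6% of left-handers are Strongly-atypical with mean HFLI near −64
and strong left-hand preference, while the hand/language dominance kappa is
small — concordance barely above chance — which is exactly the structure the
generator encodes.

For a single end-to-end run (`synthetic`, `cohort` file, or t-map manifest
input), see `run_lateralization()` / `write_report()`; `autoplot()` methods
cover fitted mixtures, selection profiles and occurrence regressions.

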