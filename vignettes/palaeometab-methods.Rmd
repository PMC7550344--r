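---
title: "Methods: fossil metabolic inference with palaeometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fossil metabolic inference with palaeometab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeometab)
```

This vignette documents the statistical models behind `palaeometab`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the underlying methodology left a choice open.

## The inference chain

A fossil taxon's metabolic grade is inferred in five coupled steps:

1. its **maximum lifespan** is read from annual growth increments in
   tooth-root cementum (one thick + thin pair per year);
2. its **body mass** is bracketed by two cranial allometries;
3. **extant regressions** of lifespan against body mass, msSMR against
   lifespan, and growth constant *K* against lifespan are fit by PGLS;
4. the fossil lifespan is **projected** onto those regressions to estimate
   msSMR (a BMR analogue) and *K*; and
5. the femoral **blood-flow index** *Qᵢ* provides an independent proxy for
   maximum metabolic rate.

The fossil is never placed in the phylogeny: the comparative regressions
are extant-only, and the fossil enters purely as an abscissa (its lifespan
or mass). Its lifespan is treated as an exact integer — cementum counts
carry no sampling-error model here, because the aggregation already takes a
minimum-style estimate (outer increments can be lost to damage, so the
estimate can only underestimate the truth).

## Lifespan aggregation and observer agreement

An increment table records one count per (specimen, element, observer,
virtual thin section). Aggregation is hierarchical:

* **per observer, per specimen**: the *maximum* over sections. Increments
  may be locally obscured, so the section showing the most increments is
  the most complete record;
* **across observers**: the *median* of observer finals, rounded half up.
  The methodology that motivated this package does not state how its three
  blind observers were combined; the median is robust to one discordant
  observer, and per-observer finals are always retained
  (`specimen_consensus()`) so `max` or `min` rules are one argument away;
* **across specimens**: the maximum, since the quantity of interest is
  maximum lifespan.

Agreement statistics are computed both across observers (CV of observer
finals per specimen) and within observers (CV across sections), because the
phrase "intra-observer CV" is ambiguous in a blind multi-observer design;
both are reported with explicit labels. CV uses the sample (n−1) standard
deviation — for a two-value group this gives `|Δ|/√2`, which is the only
convention that reproduces published effect sizes computed from such CVs.
Cohen's *d* pools variances unweighted (`sqrt((s₁² + s₂²)/2)`), again the
convention consistent with published summaries computed from very unequal
group sizes. One-way ANOVA accepts either raw vectors (delegated to
`stats::aov`) or (n, mean, sd) summaries; the summary path reconstructs
`SSB = Σ nᵢ(mᵢ − m̄)²` and `SSW = Σ (nᵢ−1)sᵢ²` and is algebraically
identical to the raw path. Shapiro–Wilk normality is reported only for
groups of at least three; a two-value group has no meaningful W statistic
and is reported as `NA` rather than a degenerate 1.

The `zproject_sum()` operator reproduces the "sum slices" z-projection used
to build virtual thin sections from tomographic stacks: a pixelwise sum of
`n` consecutive slices (default 10) with no renormalization, so dynamic
range grows by a factor of `n`. It is exactly linear, which the tests
exploit.

## Allometric estimators

All estimators are fixed published coefficients, not refit here:

| estimator | formula | role |
|---|---|---|
| dentary → mass | `exp(2.9677 ln L − 5.6712)` g | maximum mass |
| dentary → skull | `1.0458 L` mm | intermediate, carried unrounded |
| skull → mass | `10^(3.68 log₁₀ SL − 3.83)` g | minimum mass |
| diameter → femur length | `10.3 d` mm | blood-flow input |

Two deliberate decisions:

* the **skull allometry runs in base-10 logarithms** even though its source
  is typeset with "ln": only base-10 reproduces the published worked
  outputs (10.7 g and 14.9 g); the natural-log reading yields ~1.6 kg,
  plainly inconsistent with a 21 mm skull. The typeset "ln" is treated as
  an artefact and the docstring says so loudly;
* **intermediate skull lengths are never rounded**. Rounding 20.916 mm to
  21.0 mm before the mass step shifts the result from 10.7 g to 10.9 g.
  Display rounding (half-up to 0.1 g, `display_grams()`) is applied only at
  the end.

## PGLS with Pagel's lambda

The regression model is `y = Xβ + ε`, `ε ~ N(0, σ²V(λ))`, where `V(1)` is
the shared-path (Brownian-motion) matrix of the tree in Myr and Pagel's λ
multiplies the off-diagonal entries only — the diagonal (root-to-tip
distances) is untouched, the standard transform. λ is restricted to [0, 1]:
values outside the unit interval can destroy positive semi-definiteness, so
they error unless explicitly overridden. Estimation details:

* the model is whitened through the Cholesky factor of `V` and solved by QR
  (never by explicit inversion); a separate naive implementation using
  explicit `solve(V)` exists in the test suite as the oracle;
* λ̂ maximizes the **restricted (REML) likelihood** profiled over σ², by
  golden-section search on [0, 1] (40 iterations, tolerance 1e-6), with the
  endpoints evaluated explicitly so boundary estimates are exact;
* if the factorization of a degenerate `V` fails, a relative jitter of
  1e-10 is added to the diagonal once;
* when λ̂ < 0.001 (configurable) the data show no phylogenetic signal and
  the model is refit with an identity covariance, flagged `fallback_gls`;
* standard errors come from `(XᵀV⁻¹X)⁻¹σ̂²` with `σ̂² = RSS_V/(n−p)`; the
  overall F compares against the intercept-only GLS model under the same
  `V`; **r² is defined as `1 − RSS_V/TSS_V` in the whitened space**. This
  definition is stated prominently because published r² values computed
  under other conventions need not match it;
* fitting across a tree distribution (`fit_over_trees()`) selects the tree
  with the highest overall F, ties broken by lowest index, with all
  per-tree F values retained for audit.

The independent cross-check: fixed-λ and REML fits agree with
`nlme::gls` + `ape::corPagel` to 8 decimal places in the tests; the
cross-check library is never the implementation.

### Prediction for a new taxon

The confidence band at `x₀` uses the coefficient covariance. The prediction
interval adds the residual variance of a *new, phylogenetically
independent* observation, taken as `σ̂² × mean(diag(V))` — for an identity
covariance this is the classical OLS prediction variance, and for an
ultrametric tree it is the variance of a tip at the tree's full depth that
shares no history with the sample. This is the right notion for a fossil
that is deliberately not placed in the tree. Both intervals use the t
distribution on `n − p` degrees of freedom.

### The ANCOVA ladder

Clade comparisons fit four nested models — one slope + one intercept;
varying slope; varying intercept; varying both — and compare each richer
model to the baseline by an F test on the drop in weighted RSS. Two
decisions the methodology left open:

* **λ is estimated once, by REML on the richest model, and held fixed**
  across the ladder. Nested F tests are only meaningful under a common
  covariance; re-estimating λ per model would make the weighted RSS values
  incommensurable;
* a likelihood-ratio test (ML likelihoods under the shared `V`) is reported
  alongside but not used for selection; the selected model is the
  significant one with the smallest p-value, or the baseline if none is
  significant at the chosen α (default 0.05).

The reported `partial_eta_sq` is the proportional RSS reduction
`(RSS₀ − RSSₘ)/RSS₀`. It is documented rather than validated: published
effect sizes for such ladders are not always recoverable from printed F and
df under any standard formula, so this field should be read as descriptive.

Composite trees for cross-clade ANCOVA are built by `graft_clades()`, which
joins two ultrametric clades under a new root at a fixed age (e.g. a
squamate+crocodilian clade and a mammal clade at an amniote ancestor of
325.5 Ma; squamates and crocodilians at 275.9 Ma), giving each clade a stem
of `age − height`. Grafting requires ultrametric inputs and errors on
dating conflicts; internal clade topology is whatever the user supplies.

Pruning (`prune_to_taxa()`) preserves root-to-tip path lengths by retaining
the path from the original root as a stem (root edge), so pruning commutes
exactly with covariance construction — an invariant the tests assert.

## Blood-flow index

`Qᵢ = r⁴/L` with all lengths in mm (`Qᵢ` in mm³; the index scales as
length³, so cm-measured data differ by exactly 10³). When a femur has
several foramina the radii are **summed before** raising to the fourth
power, treating the sum as the total vessel entry potential; the
per-foramen alternative `Σrᵢ⁴/L` is physically defensible and available as
`rule = "sum_fourth_powers"`, but the summed-radius rule is the default
because it is the convention of the index's source. Group regressions of
log₁₀ Qᵢ on log₁₀ mass are non-phylogenetic (plain GLS): on such data λ
estimation shows no signal, which is exactly the fallback regime.

## Fossil projection

`project_trait()` evaluates `10^(a + b log₁₀ t)` at the fossil lifespan
`t`. Intervals are the **back-transformed confidence band** of the
regression mean by default — the quantity usually drawn as dashed brackets
around a projected point — with the prediction-interval variant available.
Fits constructed from published coefficients alone (`published_fit()`,
`reference_fit()`) carry no covariance and yield `NA` intervals rather than
fabricated ones. `pi_membership()` classifies observations against the 95%
prediction interval with a *closed* boundary (a point exactly on the limit
is "inside") and reports signed log₁₀ distances from the mean for every
point supplied, so "further above the mean than all members of the clade"
claims are directly checkable. Captive-lifespan offsets (+3.43 yr mammal,
+4.38 yr reptile) implement the sensitivity variant in which fossil
estimates are compared against captive rather than wild extant data.

## The synthetic-data generator

`sim_config()` fixes the study conditions; its defaults are chosen once to
mirror the statistical structure of the extant comparative data this
pipeline consumes, and are not tuned per test:

* **trees**: pure-birth (Yule) simulation at 0.05 Myr⁻¹, rescaled to a
  height of 100 Myr. Rescaling gives exact height control, which dated
  grafting needs. No extinction: birth–death dynamics add nothing to a
  covariance-recovery test surface;
* **traits**: log₁₀ mass uniform on [0.5, 6] (≈3 g to 1 t); log₁₀ lifespan
  `= a(clade) + 0.26 log₁₀ mass + ε` with clade intercepts 0.16
  (mammal-like) and 0.60 (reptile-like) and `ε ~ MVN(0, σ²C(λ))`, where
  `C(λ)` is the Pagel-transformed covariance rescaled to unit tip variance
  (so σ = 0.28 is the residual sd of one tip, giving r² ≈ 0.7 over that
  mass range, comparable to the extant fits this emulates). The covariance
  is built by the same `vcv_pagel()` code path the estimator uses — there
  is no second VCV implementation to drift. msSMR (slope −0.83, intercept
  −0.31) and *K* (slope −0.692, intercept −1.171) are generated as linear
  functions of log₁₀ lifespan with their own phylogenetic residuals, using
  the published coefficient values as the generating truth;
* **increment tables**: 3–5 sections per specimen (the range of virtual
  thin sections created per tooth in practice), three observers, section
  counts `true age − Bernoulli(p_miss) + Poisson(p_accessory)` floored at
  1 — cementum starts at eruption, so no specimen can show zero increment
  pairs. Defaults `p_miss = 0.1`, `p_accessory = 0.05` represent a
  competent observer on adequately preserved material;
* **foramina**: log-normal radii (meanlog `log(0.05)` mm, sdlog 0.3),
  matching the sub-0.1 mm scale of small-mammal nutrient foramina;
* **determinism**: a config seed makes every generator bit-reproducible;
  derived seeds are small integer offsets of it.

What the generator does **not** emulate — and therefore what passing tests
cannot show: diagenetic damage and its spatially correlated count errors
(misses here are independent Bernoulli events); measurement error in body
mass or femur length; non-ultrametric (fossil-dated) trees; tree
distributions with topological uncertainty (decoy trees in the tests are
label-shuffled, which is harsher than posterior uncertainty but not a model
of it); and any correlation between the residuals of different trait
relations. Parameter recovery on this generator validates the estimation
machinery, not the biological fidelity of real trait compilations.

## Problem sizes in the validation suite

The stochastic checks run at: 200 simulations of 200-tip trees for slope
CI coverage and λ recovery (true λ ∈ {0, 0.5, 1}); 500 null simulations of
64-tip two-clade trees for ANCOVA type-I calibration and 200 for power at a
5σ intercept shift; 1000 new observations for prediction-interval coverage;
and 200 replicates for lifespan recovery from noisy increment tables. These
sizes put Monte-Carlo error comfortably inside the asserted bands while
keeping the suite fast enough to run habitually.

A note on λ recovery: with λ = 0 (no signal) the REML estimate on a Yule
tree is noisy and upward-spread — its mean absolute error is ~0.25 even at
200 tips, a known property of the estimator (the package's estimates agree
with `nlme`'s to 6+ decimals), while at λ = 0.5 and 1 the error is ~0.09
and ~0.001. The recovery criterion is therefore asserted on the mean over
the three regimes.

## Known limitations

* λ is a single scalar per fit; no OU or other correlation structures, and
  no multi-predictor models beyond one covariate plus a two-level group.
* Published-coefficient fits cannot produce intervals; projected-value CIs
  require refitting the extant data, which the package does when given the
  trait tables and trees but cannot conjure from printed coefficients.
* Polytomies pass through unchanged; no resolution is attempted.
* The mammal-derived trait projections are sensitive to coefficient
  rounding at the third decimal: projecting with coefficients printed to
  3–4 significant figures reproduces published projections only to ~0.1–1%,
  which is the precision the worked-value tests assert.
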