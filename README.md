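# palaeometab

Inferring the metabolic physiology of fossil mammaliaforms from tooth
cementum, cranial allometry and phylogenetic comparative regression.

## The problem

Basal metabolic rate (BMR) and maximum metabolic rate (MMR) cannot be
measured in a fossil, but both leave quantitative proxies. In extant
amniotes, maximum lifespan correlates negatively with mass-specific standard
metabolic rate (msSMR, mL O₂ h⁻¹ g⁻¹) and with the postnatal growth constant
*K* (day⁻¹); and the femoral nutrient-foramen blood-flow index
*Qᵢ = r⁴/L* (summed foramen radius *r*, femur length *L*, both mm; *Qᵢ* in
mm³) tracks MMR. A fossil taxon whose maximum lifespan is known from annual
growth increments in tooth-root cementum — one thick + thin increment pair
per year — can therefore be placed on extant lifespan–trait regressions to
estimate its metabolic grade.

This package implements that inference chain for shrew-sized Early Jurassic
mammaliaforms and for synthetic data with known ground truth:

1. **Cementochronology** — multi-observer increment-count tables are
   aggregated (max over sections per observer, median consensus across
   observers, max across specimens) into a minimum estimate of maximum
   lifespan, with observer-agreement statistics (CV, one-way ANOVA from raw
   data or summary statistics, Cohen's *d*, Shapiro–Wilk) and the
   "sum-slices" z-projection operator used to build virtual thin sections.
2. **Allometry** — body mass from dentary length
   (`ln m = 2.9677 ln L − 5.6712`, an upper bound), from skull length
   (`log₁₀ m = 3.68 log₁₀ SL − 3.83`, a lower bound, with
   `SL = 1.0458 × L` carried unrounded), and femur length from mid-shaft
   diameter (`10.3 × d`).
3. **Comparative regression** — PGLS with Pagel's λ: GLS with residual
   covariance σ²V(λ), λ estimated by REML profile on [0, 1]; fitting across
   a tree distribution with F-maximizing tree selection; a four-model
   phylogenetic ANCOVA ladder (common slope+intercept, varying slope,
   varying intercept, varying both) compared by F tests on the weighted
   residual sum of squares under a shared λ; automatic fallback to plain GLS
   when λ̂ < 0.001. Composite trees are built by grafting clades at dated
   ancestor nodes.
4. **Fossil projection** — trait estimates `10^(a + b log₁₀ t)` at the
   cementum-derived lifespan *t*, with back-transformed confidence bands,
   captive-lifespan sensitivity offsets (+3.43 yr mammals, +4.38 yr
   reptiles), and classification against 95% prediction intervals.
5. **Blood flow** — *Qᵢ* from foramen sets and per-group log–log GLS
   regressions positioning a fossil relative to mammal, reptile and varanid
   means.

A synthetic-data module simulates ultrametric pure-birth trees, trait tables
with phylogenetically correlated residuals (multivariate normal with
covariance σ²V(λ)), observer-noisy increment tables and log-normal foramen
sets, so every stage has a parameter-recovery test surface.

## Worked example

```r
library(palaeometab)

# lifespan from the published increment-count table (dentulous specimens)
tab <- read_increment_table(system.file("extdata",
  "morganucodon_increment_counts.csv", package = "palaeometab"))
taxon_max_lifespan(tab)
#> [1] 9

# full inference chain for Morganucodon (dentary 20 mm, lifespan 14 yr)
fossil_profile("Morganucodon", lifespan_yr = 14, dentary_mm = 20)
#> Fossil physiological profile: Morganucodon
#>   max lifespan: 14 yr (cementum increment counts)
#>   body mass: 10.7-25.0 g (mean 17.9 g)
#>   mssmr_mammal: 0.4419
#>   mssmr_reptile: 0.05479
#>   k_mammal: 0.01086
#>   k_reptile: 0.0004855
```

The mass range comes from the two allometries (skull-based minimum,
dentary-based maximum); the reptile-derived msSMR of ~0.055 mL O₂ h⁻¹ g⁻¹
is roughly an order of magnitude below the mammal-derived value, the
signature of a reptile-grade basal metabolism for a 14-year lifespan at
~18 g.

PGLS on simulated data with known truth (slope 0.26, λ = 1):

```r
cfg <- sim_config(n_tips = 80, lambda = 1, seed = 42)
tr  <- simulate_tree(cfg)
tt  <- simulate_traits(tr, cfg)
fit_pgls(setNames(tt$log_mass, tt$species),
         setNames(tt$log_lifespan, tt$species), tr)
#> PGLS (lambda = 1.000, REML)
#>   log10(y) = 0.2596 * log10(x) +0.4045
#>   n = 80, r^2 = 0.992, F(1, 78) = 10192.670, p = 1.97e-84
```

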