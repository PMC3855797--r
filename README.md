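# twinglyco

Genetic and environmental control of IgG N-glycosylation in the classical
twin design.

The glycans attached to immunoglobulin G at Asn-297 modulate antibody
effector function, and their relative abundances — 24 UPLC peaks expressed as
percent of total integrated area, plus derived ratio traits averaging
galactosylation, fucosylation, bisecting-GlcNAc and sialylation features —
behave as quantitative traits. `twinglyco` implements the full inference
chain used to ask how much of the variation in such traits is genetic, and
whether the weakly heritable ones are instead associated with DNA
methylation:

1. **Synthetic twin cohorts** with known ground truth: paired trait values
   with exact ACE covariance structure, pair-shared covariates, Dirichlet
   glycan peak compositions, and standardized methylation matrices with a
   family-shared intercept and planted trait effects
   (`simulate_cohort()`).
2. **Derived glycan traits** from an annotation-driven grammar over the 24
   peaks — the shipped definitions yield the standard 76 traits
   (`compute_all_traits()`).
3. **Twin ACE variance decomposition** by maximum likelihood
   (`twin_ace()`), with model selection among ACE/AE/CE/E, profile-likelihood
   confidence intervals, double-entry intra-class correlations,
   heritability classification, and simulation-based power
   (`twin_power()`).
4. **Epigenome-wide association** of traits with standardized methylation
   probes through a family random-intercept linear mixed model with
   Bonferroni array-wide control (`run_ewas()`).
5. **Enrichment** of array-wide hits in low- versus high-heritability
   traits by a one-sided exact hypergeometric test (`build_contingency()`,
   `compare_proportions()`).

## The model

For a trait standardized after adjustment for age and batch, each twin pair
contributes a zero-mean bivariate normal likelihood with total variance
a² + c² + e² and cross-twin covariance

- MZ pairs: a² + c²
- DZ pairs: ½·a² + c²

where a² is additive genetic variance (heritability h²), c² shared
environment and e² unique environment plus measurement error. Submodels fix
components at zero; the best model is chosen by sequentially dropping
components from ACE with likelihood-ratio tests (α = 0.05) and AIC
arbitration among the surviving models. In the infinite-data limit the ACE
estimate equals the Falconer form a² = 2(rMZ − rDZ).

## Worked example

```r
library(twinglyco)

# a strongly heritable trait in a 220 MZ + 310 DZ pair cohort
tw <- simulate_twin_trait(220, 310, a2 = 0.7, c2 = 0, seed = 42)
pairs <- data.frame(zygosity = rep(c("MZ", "DZ"), c(220, 310)),
                    value_1 = c(tw$mz[, 1], tw$dz[, 1]),
                    value_2 = c(tw$mz[, 2], tw$dz[, 2]))
fit <- twin_ace(pairs)
fit
#> Twin ACE variance decomposition (220 MZ / 310 DZ pairs)
#> Best model: AE
#>   A = 0.71[0.65,0.76]
#>   E = 0.29[0.24,0.35]
#>   ICC(MZ) = 0.69[0.61,0.75]
#>   ICC(DZ) = 0.35[0.25,0.44]
```

The true heritability (0.7) is recovered with a profile-likelihood interval,
and the MZ/DZ intra-class correlations show the 2:1 pattern expected of an
additive trait. Power of this design to detect h² = 0.4 by the
likelihood-ratio test dropping A from the full model:

```r
pw <- twin_power(220, 310, a2 = 0.4, c2 = 0.1, n_reps = 500, seed = 1)
#> power = 0.86 (MC se 0.015)
```

Enrichment of array-wide methylation hits among weakly heritable traits,
from published hit counts (5 of 12 low-h² traits vs 4 of 64 high-h² traits):

```r
tab <- matrix(c(5L, 7L, 4L, 60L), 2, byrow = TRUE,
              dimnames = list(c("low", "high"), c("hits", "rest")))
compare_proportions(tab)
#> low 41.6% vs high 6.2%, exact one-sided p = 0.0038
```

An end-to-end synthetic run — simulate, derive traits, screen heritability,
scan methylation, test enrichment, render a report:

```r
res <- run_pipeline(demo_pipeline_config(seed = 1), out_dir = "demo_run")
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/twinglyco.R` (`simulate`, `traits`, `heritability`, `power`,
`ewas`, `enrich`, `run` subcommands).

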