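---
title: "Methods: twin variance decomposition and methylation association for IgG glycan traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin variance decomposition and methylation association for IgG glycan traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `twinglyco`, the
design decisions that were genuinely open, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## The twin ACE model

The classical twin design contrasts monozygotic (MZ) pairs, who share all
segregating genes, with dizygotic (DZ) pairs, who share half on average.
Under the equal-environment assumption, excess MZ similarity is attributed
to additive genetic variance. For a standardized trait the phenotypic
variance decomposes into additive genetic (A), shared environment (C) and
unique environment plus measurement error (E). Each complete pair
contributes a zero-mean bivariate normal log-density with total variance
`va + vc + ve` and cross-twin covariance `va + vc` (MZ) or `va/2 + vc`
(DZ); the reported components are the standardized shares `a2, c2, e2`
summing to one.

Assumptions worth keeping in mind: bivariate normality of adjusted trait
values, no dominance or epistatic variance (an ADE branch is out of scope;
the cohort emulated is all-female so sex-limitation models are moot), equal
environments across zygosities, and independence across pairs.

**Means and covariate adjustment.** Trait means carry no information about
variance shares, so they are profiled out: traits are adjusted for age and
batch by least-squares residualization and rescaled to zero mean and unit
variance (`residualize_trait()`) before the pair likelihood, which then has
no free mean parameters. Joint estimation of fixed effects inside the twin
likelihood would triple the parameter count for no benefit at this cohort
size; residualization is the standard, testable choice. Whether nonlinear
age terms belong in the adjustment is an open modelling question; the
default is linear age plus batch indicators.

**Estimation.** Each submodel (ACE, AE, CE, E) is fitted by constrained
maximum likelihood over nonnegative variance components using `optim`
(L-BFGS-B, components bounded below at zero) from three fixed starting
points — equal shares (1/3, 1/3, 1/3), genetic-leaning (0.6, 0.1, 0.3) and
shared-environment-leaning (0.1, 0.6, 0.3) — each scaled by the empirical
total variance; the best of the three is kept. The E model has the closed
form `ve = mean of squares`. Likelihood evaluations use per-zygosity
sufficient statistics (n, sum of squares, sum of cross-products), so a fit
costs the same at 50 pairs as at 200,000. Non-positive-definite proposals
return `-Inf`, which L-BFGS-B handles as a rejected step.

**Model selection.** Components are dropped sequentially from the full ACE
model: drop C (AE), drop A (CE), drop both (E). A drop survives when its
likelihood-ratio test against ACE is not rejected at `alpha = 0.05`
(chi-square, df = number of dropped components). Among the surviving models
the lowest AIC (`-2 logLik + 2k`) wins; ties break toward fewer parameters
and then toward the model retaining A, so that an ACE fit whose C estimate
is exactly zero resolves to AE (identical likelihood, AIC lower by 2).

The plain chi-square reference is mildly conservative for drops that pin a
component to its boundary; the traditional twin literature uses it anyway,
and it is the default here. A 50:50 chi-square(0)/chi-square(1) mixture
reference is available via `mixture = TRUE` for single-component drops.

**Confidence intervals.** Profile likelihood on the standardized share: a
component's interval collects the values whose profiled log-likelihood
(maximizing over the total variance and the split of the remaining share)
lies within `qchisq(0.95, 1)/2 = 1.9207` of the maximum, truncated to
[0, 1]. Bounds are located by `uniroot` between the estimate and the
boundary; a profile too flat to bracket returns [0, 1] with a warning.
The interval method for twin variance shares is a convention choice —
profile intervals respect the boundary and the sum-to-one constraint,
which Wald intervals do not.

**ICC.** Intra-class correlations use the double-entry Pearson convention
(each pair entered in both orders), with Fisher-z intervals on the number
of pairs as effective n. A one-way random-effects ANOVA ICC serves as an
independent oracle in the test suite only; the two agree within 0.02 at
200 pairs.

**Heritability classification.** A trait is "low heritability" when its
best model carries no additive component (CE, E) or its additive share is
at or below 0.35. The threshold is inclusive — a fitted h² of exactly 0.35
counts as low — which matches how borderline traits are flagged in
published twin tables of these traits.

## Power

`twin_power()` estimates, by simulation, the probability that the additive
component is detected: each replicate simulates the cohort and applies the
likelihood-ratio test that drops A from the full model (ACE vs CE, df = 1)
at the requested level. This is the same drop the selection procedure uses,
it is size-correct for every true shared-environment level (conservative
at the boundary; the mixture flag restores the nominal level), and its
power is monotone in the cohort size. A tempting alternative — first
picking the better A-containing model by AIC and testing it against its
A-free counterpart — was evaluated and rejected as a design: when the true
shared environment is positive, the AE-vs-E branch tests familial
correlation rather than the additive component (empirical size 0.13–0.16
at `a2 = 0, c2 = 0.3`), and its apparent power is not monotone in n.

At the emulated cohort size (220 MZ + 310 DZ pairs) and `a2 = 0.4`, the
drop-A test at α = 0.05 attains simulated power of roughly 0.83–0.86 at
`c2 = 0.1` and essentially 1.0 at `c2 = 0.5` (1,000 replicates;
`scripts/acceptance.R` recomputes this). Detecting a modest additive
component next to a small shared environment is genuinely the hard case:
power rises with c2 because a larger shared correlation sharpens the
contrast that identifies A.

## The synthetic cohort generator

The generator's defaults emulate a female adult twin cohort with glycomics
and methylation data: 220 MZ and 310 DZ pairs; pair-shared age with mean
58.71 and SD 9.37 years drawn from the same law for both zygosity blocks
(the emulated cohort shows no age difference between them); individual BMI
around 26.6 (SD 4.8); batch, chip (12 samples per chip, matching common
array plating) and chip position assigned after a random shuffle.

**Traits.** Each trait is generated additively:
`y = scaled(A + C + E) + sum(beta_probe * probe) + beta_age * age_c +
beta_batch * batch_dev`. The additive part is drawn shared within MZ pairs
and split into a pair-shared half and a segregating half within DZ pairs,
so the ACE covariance algebra holds exactly rather than asymptotically.
The default trait panel spans the range seen for IgG glycan traits —
additive shares from 0 to 0.8 and shared-environment shares up to about
0.7 — plus a pure-noise trait. Marginal trait variance is 1 before planted
probe and covariate effects are added.

**Glycan peaks.** Peak compositions are Dirichlet draws scaled to 100, so
the sum-to-100 constraint holds exactly and expected values equal the
configured means. Published tables report only per-peak means and SDs, and
the observed SDs are not consistent with any single Dirichlet concentration
(real peaks have heterogeneous noise), so the generator exposes one
`dispersion` parameter — the inverse concentration; larger is noisier —
with default 0.01, a middle ground that reproduces realistic coefficients
of variation for mid-size peaks. The default mean vector uses published
per-peak means for the 22 peaks such tables report, fills the two omitted
peaks with small conventional values (0.2 and 0.3), and renormalizes.

**Methylation.** Probes are simulated directly on the standardized scale
(mean 0, variance 1), not as array beta-values: the association model
standardizes probes anyway, and raw-intensity simulation is out of scope.
Each probe is a family-shared intercept plus individual noise. The
within-family probe correlation is not published for the emulated cohort;
the family-intercept variance default of 0.2 is a free parameter chosen as
a plausible middling value, not an estimate. A planted (probe, trait, beta)
adds `beta * probe` to that trait's generating equation, giving the
association stage a known truth to recover; planted effect sizes of
0.2–0.4 on the standardized scale match the magnitudes published for these
traits.

**Seeding.** One master seed; each stage (covariates, traits, methylation,
peaks) draws from a substream derived deterministically from the seed and
the stage name, so the cohort reproduces bit-for-bit and enlarging one
stage does not disturb the draws of another.

**What the generator does not emulate.** Non-normal trait distributions
(several real glycan traits are skewed); heteroscedastic, peak-specific
compositional noise; correlation between the glycan peak table and the
ACE trait panel (they are independent channels — derived-trait arithmetic
is tested on the peak channel, variance decomposition on the trait
channel); spatial chip artifacts and cell-composition effects; genotypes.
Passing tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to those real-data features.

## Glycan trait grammar and annotation

Derived traits are defined as ratios of feature-group sums over the 24
peaks rather than 76 hand-written formulas, because the standard
nomenclature is systematic: `F` core fucose without bisecting GlcNAc,
`Ftotal` with or without, `FB` with, leading `B` bisecting without core
fucose; `G0/G1/G2` exact galactose count (`G` alone: at least one);
`S1/S2` exact sialic acid count (`S`/`Stotal`: at least one; no S element:
neutral); suffix `n`: evaluated on the neutral-normalized basis, where
`GPkn = 100 * peak_k / sum(neutral peaks)`; a bare `F`/`FB`/`B` token in a
raw-basis expression denotes the agalactosylated neutral group; `‰` scales
per mille. The shipped definition table produces the standard 76 columns:
22 directly measured peaks, 17 sialylation ratios, 14 neutral peak
percentages and 23 derived neutral traits.

The per-peak structural annotation ships as an editable TSV. Four
assignments are published anchors (GP4 = FA2, GP8/GP9 = FA2G1,
GP14 = FA2G2, GP21 = A2G2S2); the remaining peaks follow a conventional
IgG-panel-style assignment and are flagged `convention` in the file. On
the default mean composition this conventional annotation reproduces the
published magnitudes of the derived traits (e.g. neutral galactosylation
splits near 32/46/22 percent and a fucosylation share near 96–97 percent
of neutral glycans), which is the consistency check that motivated it.
Analyses that depend on the exact identity of a conventional peak should
replace the annotation file rather than trust it.

A zero denominator in a trait yields a missing value with a logged
warning, not an error, so cohort stages can drop the sample; a token that
selects no peaks is a definition error caught at load time.

## Methylation association

The association model is a linear mixed model
`trait ~ probe + age + BMI + batch + chip + chip position + (1 | family)`,
fitted by REML through `lme4`, with a Wald p-value for the probe
coefficient against the standard normal reference (a t reference with
residual df is available). The glycan outcomes are continuous, and
published effect tables for these traits report betas and SEs on the
continuous standardized scale, so a linear — not logistic — random-intercept
model is the appropriate reading; a dichotomized-outcome variant is not
implemented. Sex is constant in the all-female design and is dropped
automatically, as are any aliased covariate columns (QR rank check with a
warning). Zygosity is excluded from the default covariate set — it does
not change results in cohorts of this design — and can be added by passing
it in the covariate table. When the fitted family variance is zero the
mixed model collapses to OLS exactly, which the test suite uses as an
oracle. Array-wide significance uses the Bonferroni cutoff
`alpha / n_probes` (0.05 over 24,641 probes gives 2.03e-6, reported to one
significant figure as 2e-6).

## Enrichment

Hits are counted as significant association rows (probe x trait pairs)
per heritability class; denominators are the trait counts per class. This
is the counting convention of published array-wide enrichment summaries;
it allows a multi-hit trait to push a numerator above its denominator, in
which case the complementary cell floors at zero — a documented quirk of
the convention, not a bug. The primary test is the one-sided exact
hypergeometric tail (via `phyper`; the test suite checks it against a
log-factorial enumeration oracle at 1e-12), with a Pearson chi-square as
the secondary check and an odds ratio with Haldane correction for zero
cells. Reported class percentages truncate at one decimal (5/12 prints as
41.6), matching the published convention for these summaries.
`welch_t_summary()` covers demographic mean(SD) comparisons from summary
statistics alone.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes simulate, traits, heritability, ewas, enrich
and report in dependency order, writes every table as TSV with a key
column, and records a YAML manifest (config snapshot, package version,
seed, per-file MD5 checksums, stage durations). Disabling a stage that a
later stage needs aborts with a dependency error before any computation.

The shipped demo configuration (50 + 50 pairs, 200 probes, three planted
effects of 0.30–0.36, seed 1) runs in well under a minute. At that size
the per-effect probability of clearing the array-wide Bonferroni cutoff
is about 0.8 — planted magnitudes were deliberately kept in the realistic
range rather than inflated — so recovery of all three effects is a
property of the shipped seed, at which they also rank as the top three
associations; across arbitrary seeds the guaranteed statement is the
ranking, not the flag.

Test-suite problem sizes were chosen so the full suite runs in a few
minutes on one CPU: closed-form limit checks at 200,000 pairs per
zygosity (sufficient statistics make these cheap), selection-consistency
and coverage studies at 100–200 replicates, association scans at 60–250
probes. The heritability screen's profile intervals dominate per-trait
cost; `ci = FALSE` skips them where only point estimates are needed.

## Known limitations

- No dominance (ADE), sex-limitation or multivariate (cross-trait) twin
  models; no assortative-mating or gene-environment interaction terms.
- Profile intervals assume a unimodal profile; pathological multimodal
  likelihoods would need a grid scan.
- The EWAS refits the mixed model per probe; at array scale (tens of
  thousands of probes) a dedicated screening approximation would be
  preferable. The design target here is subsets of a few hundred probes.
- The exact enrichment test conditions on both margins; with trait counts
  as denominators and row counts as hits the margins are mildly
  inconsistent when a trait has several hits (see the counting quirk
  above).
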