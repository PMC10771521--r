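---
title: "Twin models for aesthetic phenotypes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin models for aesthetic phenotypes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models in `aesthetwin`, the
assumptions they rest on, the choices made where the design was genuinely
open, and what the synthetic-data generator does and does not emulate.

## The phenotypes

A rating study presents each individual with a set of images from one or
more visual domains; some images are shown twice. After quality control,
repeated presentations are averaged into an individuals × images matrix per
domain. Three phenotypes are derived from it:

* **Pairwise agreement** `r_inter` — the Pearson correlation of two
  individuals' rating vectors over shared images. Analyses operate on the
  Fisher scale `z = atanh(r)` because z is approximately
  variance-stabilised and additive; means are taken on the z scale and
  back-transformed with `tanh` for reporting.
* **Taste-typicality** (`mm2`) — the correlation between an individual's
  ratings and the image-wise mean of everyone *except* the individual and
  their co-twin. Excluding the co-twin keeps familial resemblance out of
  the reference profile, which matters because the reference otherwise
  contains a vector correlated with the individual by construction.
  Taste-typicality is modelled on the z scale throughout.
* **Evaluation-bias** — the individual's mean rating. It is exactly
  shift-equivariant (adding a constant to one individual's ratings moves
  their bias by that constant and nothing else), while `mm2` and `r_inter`
  are shift-invariant; the test suite asserts both properties.

Unrelated (UR) pseudo-pairs provide the no-relatedness baseline for
agreement: each twin-order-2 member is matched to a twin-order-1 member of
a *different* family of the same sex, greedily by nearest age after a
seed-determined shuffle. Greedy matching is O(n log n) and is checked
against an exhaustive assignment oracle at small n in the tests; ties are
broken deterministically by the seed, so the construction is reproducible.
UR pairs are re-matched independently per domain, mirroring the fact that
the retained individuals differ per domain after QC.

## Quality control

Within each domain, an individual is excluded if (a) their ratings have
zero standard deviation, or (b) their intra-individual reliability — the
Pearson correlation between first- and second-presentation ratings of the
repeated images — is below 0.5. The threshold is a strict `<`: a
reliability of exactly 0.50 is retained. An individual whose presentation
vector is constant has an undefined reliability and is excluded,
conservatively. A pair whose other member survives is kept as an
incomplete pair (the likelihood machinery below handles it).

Metric-level outliers are fenced at `Q1 − 3·IQR` and `Q3 + 3·IQR` with
type-7 (linear-interpolation) quartiles — the most common default, and
documented as such. The fence is two-sided because correlation-type
metrics can be extreme in either direction; a one-sided variant is
available via `one_sided = TRUE`. With an all-equal sample the IQR is
zero and nothing is excluded.

## Variance partitioning

Rating variance is decomposed with the crossed random-intercept model

```
rating ~ 1 + (1|individual) + (1|image) + (1|individual:image)
           + (1|exposure) + (1|exposure:individual) + (1|exposure:image)
```

fitted by REML through `lme4` on one twin per family (using both twins
would let familial resemblance inflate the individual component).
"Exposure" is the presentation index — first versus second showing — coded
as a crossed factor. Identifiability rules: the individual × image
interaction is separable from the residual only through repeated
presentations, so without repeats it is merged into the residual with a
warning, and the exposure terms are dropped. Variance partitioning
coefficients are each component's share of the summed components and
normalise to 1 exactly. A hand-written method-of-moments ANOVA estimator
for complete balanced one-presentation designs serves as an independent
oracle: REML and MoM agree to ~1e-3 there, which the tests assert.

## Univariate twin models

The Classical Twin Design compares monozygotic (MZ) pairs, who share all
segregating variants, with same-sex dizygotic (DZ) pairs, who share half
on average. Phenotypic variance decomposes into additive genetic (A),
shared environment (C), dominance (D) and unique environment (E, which
absorbs measurement error). The model implies co-twin covariance
`A + C + D` for MZ and `0.5A + C + 0.25D` for DZ; C and D cannot be
estimated together from twins alone, and the fitter refuses the request.

Estimation is full-information maximum likelihood over per-family Gaussian
observations: complete pairs contribute a bivariate normal term,
incomplete pairs their univariate marginal. Means carry an intercept plus
optional sex and centred-age covariates, with coefficients shared across
co-twins. Components are parameterized **directly and unconstrained in
sign** (the direct symmetric approach) rather than through Cholesky
factors. This has two consequences worth naming: small negative estimates
are representable (an honest reflection of sampling noise near a zero
component, and less upward bias in the retained components), and
likelihood-ratio statistics keep their standard chi-square reference
because no parameter sits on a boundary by construction.

The saturated model frees per-zygosity, per-twin-order means and variances
and a per-zygosity covariance (12 parameters with 2 covariates); equating
means or variances across order and zygosity gives the homogeneity LRTs.
Comparing the saturated model with a full ACE/ADE model costs 6 degrees of
freedom; each dropped component costs 1.

**Numerical choices.** Optimization is BFGS from moment-based starting
values (components solved from the observed MZ/DZ covariances), followed
by deterministic jittered restarts, keeping the best −2LL; the restart
factors are fixed so fits are bit-reproducible without touching the RNG.
Parameter regions where the implied covariance is not positive definite
return a large penalty rather than an error. Profile-likelihood CIs locate
the parameter values where the profiled −2LL rises by `qchisq(0.95, 1) =
3.841`, by bracket expansion plus `uniroot` bisection; for standardized
shares the inner problem reparameterizes to (log total variance, shares)
so the constraint is exact. A bound that cannot be bracketed is reported
as `NA`, i.e. open-ended.

The automated model ladder in `run_pipeline()` picks the full model from
the saturated twin correlations — ACE when `r_DZ >= r_MZ / 2` (tie goes to
ACE), ADE otherwise — and then takes the most parsimonious submodel whose
LRT against the full model does not reject at 0.05, matching standard
twin-analysis practice. Ladder p-values are not multiplicity-adjusted; the
agreement ANOVA's pairwise contrasts are Bonferroni-corrected with
multipliers 3 (pair classes), 3 (domains) and 9 (classes within domains).

## Multivariate twin models

For several traits (e.g. taste-typicality across domains) the model
carries symmetric component matrices `Σ_A`, `Σ_C`, `Σ_E`. The
within-individual covariance is their sum; the cross-twin block is
`Σ_A + Σ_C` (MZ) and `0.5Σ_A + Σ_C` (DZ), which implies the cross-twin
cross-trait covariances the design exploits. Traits can carry different
components: excluding a component for a trait zeroes that trait's row and
column of the matrix, so a specification like "A for scenes and faces, C
for abstract images" is expressed structurally; cross-component
covariances (A of one trait with C of another) are structurally zero, the
standard CTD identification. Each trait is z-standardized before fitting
by default, so component matrices are on a correlation-like scale. The
full bivariate ACE model has 11 free parameters against a 28-parameter
saturated model (17 df); the trivariate, 21 against 54 (33 df).

Derived quantities: bivariate heritability
`h²_b = σ_Aij / (σ_Aij + σ_Cij + σ_Eij)` (clipped to [0, 1] with a flag if
outside), genetic correlation `ρA = σ_A1A2 / √(σ²_A1 σ²_A2)` and its E
analogue. Their confidence intervals use the delta method on the
numerically estimated parameter covariance (2 × inverse Hessian of the
−2LL), flagged `ci_method = "delta"` in the output. Profile intervals for
derived multivariate quantities were considered and deliberately not
implemented: each would require a constrained refit inside a root search
on an 8–21 parameter surface, and the delta approximation is accurate in
the regimes the package targets (hundreds of pairs, interior estimates).

## The synthetic-data generator

The generator is the package's testbed and defines its study conditions.
Latent per-individual traits (taste-typicality and evaluation-bias)
decompose into A/C/D/E with configurable covariance matrices: MZ co-twins
share the A (and D) draw; DZ co-twins' A draws correlate 0.5 and D draws
0.25 (the additive and dominance expectations under random mating); C is
shared within family; E is independent. Ratings are then built additively:

```
rating = grand mean + image value + bias + typicality-weight × image value
         + individual-by-image idiosyncrasy + exposure effect + residual
```

with `bias = bias_scale × latent bias` and
`weight = typicality_scale × latent typicality`. No published generative
model links twin genetics to image ratings, so this layered construction
is the package's own design; it was chosen because it provably hands the
configured A/C/E structure down to the derived metrics — the rating row
mean is the latent bias plus averaging noise, and `mm2` is monotone in the
typicality weight.

Defaults (rating units unless noted): 65 images, 15 repeated, image sd
0.8, idiosyncrasy sd 0.7, residual sd 0.6, exposure sd 0.05 (the small
systematic repetition effect of real rating data), grand mean 4 on a 1–7
scale, 76% female same-sex pairs, ages uniform on 21–68 years — values a
twin rating study of this kind would consider realistic. Latent trait
variances default to A = 0.36 / E = 0.64 (typicality) and
A = 0.30 / E = 0.70 (bias), i.e. published-scale heritabilities for these
phenotypes. The raw-scale variance of evaluation-bias is not reported
anywhere we could anchor to, so `bias_scale` (default 0.8) is a free
calibration parameter documented here and in the config.

Deliberate simplifications: ratings are generated on a continuous scale —
clipping to the rating bounds and rounding to Likert integers exist as
flags but default **off**, because clipping distorts the variance
decomposition that the recovery tests rely on; there is no assortative
mating, no gene–environment correlation or interaction, no ordinal
measurement model, and image content is abstract (an exchangeable Gaussian
image value, not pixels). Passing tests therefore demonstrate correctness
of the estimators under the stated model, not robustness to ordinal
measurement or model misspecification in real data.

Ages are drawn per family (twins share age); sex is assigned per family
(same-sex design). The C-and-D-together configuration is allowed in the
generator (it is only the *fitter* that cannot identify both) but draws a
validation warning.

## Problem sizes in the test suite

Simulation-backed checks run at sizes chosen to make Monte-Carlo noise
small relative to the asserted tolerances while keeping the suite quick:
moment-matching of the generator at 10,000–12,000 pairs per zygosity;
univariate recovery at 1,000 MZ + 400 DZ pairs averaged over 10 seeds
(tolerance ±5 percentage points); bivariate genetic-correlation recovery
at ~1,500 pairs × 10 seeds (±0.07); LRT null calibration at 500 replicates
of 200 pairs (rejection rate close to the nominal 5%); profile-CI coverage
at 150 replicates of 500 pairs (covering ~95% with a binomial tolerance
band); crossed variance-component recovery at 120–150 individuals × 30–40
doubly-presented images (within 15%).

## Known limitations

* Same-sex pairs only; no sex-limitation models or opposite-sex DZ pairs.
* The univariate sex/age covariates enter the mean model linearly; the
  saturated model assumes the same.
* Exposure is modelled as a crossed two-level factor; with only two levels
  its variance is weakly identified and best read as descriptive.
* Delta-method CIs for multivariate derived quantities can misbehave when
  an A variance sits near zero (the `ρA` denominator), where the quantity
  itself is ill-defined; the functions refuse non-positive variances
  rather than report a meaningless interval.
* FIML assumes data are missing at random; QC exclusions are per-domain
  and can correlate with the phenotype, which a real analysis should keep
  in mind when interpreting incomplete-pair contributions.
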