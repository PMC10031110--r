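---
title: "Multi-method latent factors of puberty and cortical thickness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-method latent factors of puberty and cortical thickness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubsem)
```

## The measurement problem

Pubertal maturation in girls is driven by two overlapping endocrine
processes. Adrenarche begins with maturation of the adrenal zona
reticularis and releases DHEA and testosterone, eventually producing body
hair, skin changes and body odour. Gonadarche follows from maturation of
the hypothalamic–pituitary–gonadal axis, raises estradiol, and produces
breast development and menarche. Studies measure these processes with
self-report questionnaires (the Pubertal Development Scale's 4-point items
plus a binary menarche item; 5-point Tanner-stage line drawings), with
repeated salivary hormone assays, and with hair hormone concentrations.
None of these instruments measures a process directly; each adds method
variance of its own. The natural statistical frame is a hierarchical
confirmatory factor model in which observed indicators load on first-order
method-specific factors, and those factors load on second-order constructs:
either separate adrenarche (ADR) and gonadarche (GON) factors, or a single
overall puberty (PUB) factor. Regional cortical thickness can then be
brought into the structural model as an observed variable covarying with
the latent constructs, one model per cortical region, yielding a brain-wide
map of latent-factor effect sizes.

## Model topology

`build_model()` constructs every analysed variant from a
`model_variant()` description:

* First-order factors: one per saliva hormone over its four weekly samples
  (`sal_dhea`, `sal_t`, `sal_e2`), and self-report factors over the ordinal
  items (`sr_adr` over body hair, skin changes and the pubic-hair drawing;
  `sr_gon` over height growth, breast development, menarche and the breast
  drawing; or a single `sr_pub` over all seven).
* Second order (full multi-method models): `ADR =~ sal_dhea + sal_t +
  sr_adr`, `GON =~ sal_e2 + sr_gon`, with `ADR ~~ GON` free; the one-factor
  scheme collapses to `PUB =~ sal_dhea + sal_t + sal_e2 + sr_pub`. Hair
  concentrations, when included (hormone-only models), load directly on the
  top-level factors; the hair-DHEA loading can be pinned to zero.
* Residual options: covariances among the three hormones' saliva samples
  collected on the same day (12 in all), and a correlated-uniqueness option
  adding questionnaire (method) covariances among items of *different*
  processes — within-process same-questionnaire covariances are confounded
  with the trait factor and would destroy identification, so they are not
  offered.
* Age enters either as a correlate of the top-level factors
  (`age_mode = "correlate"`) or as their predictor
  (`age_mode = "regress"`), in which case the factor covariance is a
  disturbance covariance, i.e. age-partialled.

Identification uses unit-variance latents: every latent (residual) variance
is fixed to 1, so loadings are reported on the scale of standardized
factors; `standardize()` maps any solution onto the fully standardized
metric via the model-implied covariance of all variables. Local
identification is verified by the rank of the Jacobian of the implied
covariance's unique elements, evaluated at deterministically jittered start
values (exactly symmetric starts can produce coincidental rank drops). The
two-factor saliva-only variant is structurally unidentified — the gonadal
factor has a single indicator — and `build_model()` refuses it with a
diagnostic; this is the formal reason one- and two-factor hormone-only
models are equivalent without hair.

## The synthetic cohort generator

No public cohort with this battery exists, so the generator *is* the
reference population for every test. Its defaults encode the study
conditions the package is designed around:

* 174 participants aged 10.0–13.0 years (mean 11.55, SD 0.81).
* Saliva loadings inside the reported ranges (DHEA 0.90–0.93, T 0.72–0.87,
  E2 0.72–0.90, varying by sample); self-report item loadings 0.80 except
  height growth (0.50), which is known to sit apart from both processes;
  hair loadings at or below 0.4 (hair DHEA 0.20), matching their observed
  weakness.
* Second-order loadings 0.80/0.70/0.80 (ADR over saliva-DHEA, saliva-T,
  self-report) and 0.60/0.85 (GON over saliva-E2, self-report): hormones
  and self-report each retain unique variance.
* ADR–GON correlation 0.95; age correlations 0.58 (ADR), 0.70 (GON), 0.73
  (PUB in the one-factor scheme).
* Same-day residual correlation 0.30 among the three hormones' sample *k*
  (all assigned to collection day *k*): large enough that omitting the 12
  covariances visibly damages fit, small enough not to dominate the factor
  structure.
* Raw hormone marginals matching the descriptive table of the target
  cohort (e.g. salivary DHEA 104 ± 127 pg/mL): each hormone's latent column
  is a normal log-concentration, exponentiated on output, so raw values are
  log-normal — positively skewed with heavy upper tails, as assay data are.
  An outlier layer additionally plants values beyond 3 SD on the log scale
  (rate 0.01, location 4 SD) to exercise winsorization.
* Ordinal items are standard-normal latent responses cut at configurable
  thresholds; defaults (±1, 0 for 4-point items; ±1.5, ±0.5 for 5-point
  drawings; 0.25 for menarche, i.e. about 40% post-menarcheal) spread mass
  across categories and put the composite means near the middle of the 1–5
  scale, as in a mid-pubertal cohort.
* Thickness: 68 Desikan–Killiany regions at 2.55 ± 0.12 mm, with a planted
  correlation of −0.30 between the overall pubertal composite and the
  occipital/parietal regions (both hemispheres), 0 elsewhere. In the
  two-factor scheme the effect is carried equally by ADR and GON through
  the standardized composite `(ADR + GON) / sqrt(2 + 2*rho)`. A
  `thickness_age_mediated` switch reroutes the effect through age alone,
  which is what makes the stage-versus-timing contract testable.
* Missingness is missing-completely-at-random per block (2% items, 5%
  saliva, 10% hair by default). One master seed expands into fixed,
  independently seeded substreams for the latent draw, the outlier layer
  and the missingness masks, so toggling one layer does not perturb the
  others.

`implied_population_covariance()` assembles the population covariance of
all observed continuous/latent-response variables by path tracing and
rejects any configuration whose implied matrix is not positive
semi-definite (reporting the offending eigenvalue) or whose communalities
exceed 1.

What the generator does **not** emulate: circadian or menstrual hormone
dynamics beyond the day-level residual covariance; non-normal latent
response distributions; informative (non-MCAR) missingness; measurement
non-invariance across pubertal stage; and any spatial covariance among
cortical regions beyond what the shared factor induces. Passing tests
therefore show that the pipeline recovers the structure it assumes — not
that real pubertal data satisfy those assumptions.

## Estimators and numerical choices

**ML.** The discrepancy `F_ML` is minimized by `nlminb` with analytic
gradients assembled from the RAM derivative identity
`dSigma = B dA V + (B dA V)' + B dS B'`; non-positive-definite candidates
are penalized smoothly. Convergence is declared when the gradient max-norm
falls below 1e-4 after a BFGS polish pass that targets 1e-6; failures are
reported, never silently accepted. Start values: loadings 0.7, observed
residual variances half the sample variance, latent covariances 0.3,
regressions 0. The chi-square convention is `n * F_ML` with `n` the number
of analyzed cases (not `n - 1`); this enters MFI and ECVI only through `n`.
Improper solutions (negative residual variances, standardized loadings
beyond 1) are flagged as Heywood cases with a warning and left untruncated.

**FIML.** Casewise likelihood with saturated (free) means, grouped by
missingness pattern, with analytic gradients accumulated per pattern. The
chi-square compares against the saturated multivariate normal, estimated by
EM when data are incomplete; the CFI baseline is the independence model
with free variances and means (closed form). Rows with no observed cells
carry no information and are dropped with a warning.

**PML.** For ordinal indicators: free thresholds per item (started at the
inverse-normal cumulative marginal frequencies), unit latent-response
variances with residual variances derived as 1 − communality, and an
objective summing log bivariate-normal rectangle probabilities over all
ordinal pairs (aggregated into contingency tables, so cost is independent
of n) plus exact bivariate normal log-likelihood terms for continuous
pairs. Rectangle probabilities use a vectorized 64-node Gauss–Legendre
quadrature of the tetrachoric integral, accurate to well below 1e-8 (the
unit tests verify it against an independent reference implementation to
1e-9). Mixed ordinal–continuous pairs are refused with a pointer to FIML,
matching the estimator ladder actually used: PML for ordinal-only
self-report models, ML for continuous-only hormone models, FIML for the
combined models with items treated as numeric. An ordinal variable with an
empty interior category has an unidentifiable threshold and is rejected
with an instruction to merge categories. Because the pairwise objective is
not a likelihood-ratio chi-square, PML fits report `NA` fit indices.

**Robust tier.** `sandwich_se()` computes Huber–White standard errors
`A^-1 B A^-1` with `A` the observed information and `B` the outer-product
sum of per-case scores (central differences of the casewise
log-likelihood, vectorized per pattern). `scaled_chisq()` implements a
mean-scaled chi-square: the scaling factor is `tr(U Gamma)/df` with `U` the
residual weight matrix under the normal-theory metric and `Gamma` the
empirical fourth-moment covariance of the half-vectorized sample
covariance. Under multivariate normal data the factor converges to 1
(property-tested); under heavy tails it exceeds 1 and deflates the
statistic. The unscaled chi-square is always reported alongside.

## Preprocessing conventions

Hormones are log-transformed before any outlier handling (their raw
distributions are positively skewed and kurtotic), and winsorization is
applied **on the log scale**: values beyond mean ± 3 SD are moved to the
cut plus (or minus) rank-preserving increments of 0.01 — the increment is
in the units of the scale being winsorized, and both the cut multiplier and
increment are configurable. With moments re-estimated from the data the
operation is not a strict fixed point (replaced values sit just beyond the
cut, and a second pass with shrunken moments re-flags them); against fixed
cut statistics it is exactly idempotent, and either way the rank vector is
unchanged — that is the property the procedure exists to preserve.

Composite scores rescale each item to 1–5 (4-point items linearly; menarche
to {1, 5}) and average them: body hair, skin changes and the pubic-hair
drawing into the adrenarche composite; height growth, breast development,
menarche and the breast drawing into the gonadarche composite; the puberty
composite is their mean. The assignment of the height-growth item to the
gonadal composite is conventional rather than settled — it may track a
separate growth-axis process — and is configurable. The PDS-only stage
score approximating Tanner stages is a documented *reconstruction* of the
conventional scheme (body hair + breasts, split by menarche); the original
mapping is not printed in the source literature, so the table here should
be treated as one defensible choice, and it is overrideable. Stratified
refits split at stage ≥ 3 versus < 3.

The MRI quality-control cascade excludes opt-outs, scans rated 3 (worst) on
the three-point quality scale, and rating-2 scans flagged for major motion
on re-examination; `qc_cascade_ledger()` builds a synthetic ledger with any
cascade counts (defaulting to the 174 → 112 arithmetic of the target
study's design).

## Brain maps and the age question

`fit_region()` adds one region's thickness to the measurement model as an
observed variable covarying with the top-level factors and extracts the
standardized latent–thickness correlation; `brain_sweep()` crosses regions
× variants × age options and labels effect bands (|r| < 0.1 weak, < 0.3
small, < 0.5 medium, else large; boundary values go to the upper band). A
fit failure flags the row rather than aborting the sweep. Each region model
refits the full measurement model jointly — measurement parameters are not
frozen from a no-brain fit — because the region block is small relative to
the measurement block and joint refitting keeps standard errors honest.

"Controlling for age" has two implementations, and they answer different
questions. With `age_mode = "correlate"`, age joins the covariance
structure and the reported association keeps its marginal interpretation
(pubertal *stage*). With `age_mode = "regress"`, factors and thickness are
regressed on age and the reported r is the age-partialled (disturbance)
correlation — pubertal *timing*. The generator's `thickness_age_mediated`
switch plants a thickness effect carried entirely by age; the testable
contract is that the regress-mode r collapses toward 0 on such data while
the unadjusted r (≈ planted r × factor–age correlation) does not. No
multiple-comparison correction is applied anywhere in the sweep by design:
the output is a map of effect sizes with standard errors, not a
significance map.

## Problem sizes and test design

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make Monte-Carlo error small relative to the tolerances checked:
the generator's covariance is validated at n = 100{,}000 against the
path-traced population matrix (tolerance 0.02 on correlations); estimator
cross-checks run at n = 1{,}000–5{,}000; and parameter-recovery checks fit
the full multi-method models on three replicate cohorts of n = 2{,}000 and
compare the *averaged* estimates with the generating values (loadings
within ±0.05, ADR–GON within ±0.03, age correlations within ±0.05). The
replication is a power decision made up front: at a single n = 2{,}000
draw, the Monte-Carlo standard error of the ADR–GON correlation (~0.018)
is of the same order as its tolerance, which would make a single-draw
check a coin flip rather than a test; averaging three replicates brings
every tolerance past three standard errors.

Recovery is assessed on the continuous latent-response scale (the
generator's `raw_scale = FALSE` output): that is the scale on which the
generating model is the true model. Fitting the thresholded ordinal items
as numeric attenuates their loadings — a well-understood coarsening
effect, visible in the package's own fits — and the pairwise-likelihood
estimator, which models the thresholds explicitly, is the route that
recovers the generating loadings from ordinal data (property-tested
against the generator).

## Known limitations

* The engine covers covariance structures with optional saturated means;
  structured means/intercept models, multi-group SEM, weighted least
  squares for ordinal data, Bayesian estimation and modification indices
  are out of scope.
* PML standard errors are inverse-Hessian approximations; a full Godambe
  (sandwich) information for the pairwise objective is not implemented.
* FIML assumes multivariate normality of the observed subvectors; with
  thresholded items treated as numeric this is an approximation, as it is
  in the analysis tradition the package follows.
* The generator's MCAR missingness cannot probe estimator behaviour under
  informative dropout.
* Winsorization interacts with the log transform in the documented order
  (log first); analyses that winsorize raw concentrations will differ.
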