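---
title: "Case-mix adjusted profiling: models, generator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-mix adjusted profiling: models, generator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(casemixr)
```

## The statistical model

`casemixr` profiles primary care units (centres, PHCs; and the basic care
teams nested in them, BCTs) on three axes — efficiency, case-mix
complexity, and clinical effectiveness — and measures how the axes relate
across units.

### Indirect standardization

Every attended patient carries one mutually exclusive morbidity-burden
category (an ACG code). Let $n_{u,a}$ be unit $u$'s patient count in
category $a$, $n_u = \sum_a n_{u,a}$, and $m_{a,q}$ the *reference
population's* mean of quantity $q \in \{\text{visits}, \text{episodes},
\text{cost}\}$ per patient in category $a$. The unit's expected mean is its
own case mix priced at reference rates,

$$E_q(u) = \frac{1}{n_u}\sum_a n_{u,a}\, m_{a,q},$$

and the three efficiency indices are ratios of observed to expected means,
$\mathrm{EI}_q(u) = O_q(u) / E_q(u)$. The risk index uses the visits
expectation only, $\mathrm{RI}(u) = E_{\text{visits}}(u) / \bar m_{\text{visits}}$,
with $\bar m_{\text{visits}}$ the reference pooled mean. The discriminating
property of this construction — and the package's central invariant — is the
decomposition: utilization intensity moves the EIs and not the RI, while
case-mix composition moves the RI and (in expectation) none of the EIs.

Two consequences are asserted as exact identities in the tests. When the
reference profile is built from the analyzed cohort itself, expected totals
conserve observed totals, so the pooled EI of every quantity and the
attended-weighted mean RI equal 1 (tolerance 1e-9, pure floating-point
noise). And the grouped computation must equal a per-patient brute-force
loop ($\sum_i m_{\mathrm{acg}(i),q}$) to 1e-12 relative on random cohorts
— the grouped path is an optimization, never a different estimator.

**Denominator choice.** Observed means divide by *attended patients*, not by
the assigned catchment population. The published per-centre tables only
reproduce under the attended denominator (e.g. an observed/expected cost
pair of 600.87/752.71 yielding an EI of 0.80), so that definition is
adopted throughout; assigned population enters only through the coverage
ratio. An externally supplied reference (`read_reference()`,
`reference_from_catalog()`) is supported; under an external reference the
conservation identities do not apply.

### The synthetic effectiveness index

Twenty care-quality indicators are scored 0–100 per unit:
higher-is-better proportions as $100\,c/e$ (compliant over eligible),
the one lower-is-better proportion as $100\,(1 - c/e)$, and the four
pharmacy-cost indicators as $100\,\min(1, b/x)$ with benchmark cost $b$
(EUR per defined daily dose) and observed cost $x$. The composite SI is a
weighted mean over the indicators available for the unit, weights
renormalized, equal by default. The operational construction used by the
original Catalan contract indicators is not public; these formulas are this
package's re-specification, chosen to preserve each indicator's documented
direction while being exactly testable. Three properties are enforced:
bounds (the SI lies within the component score range, hence in [0, 100]),
permutation invariance (including duplicating an indicator with its weight
split), and monotonicity in every component. Indicators with no eligible
patients are *missing*, not zero — a unit is never penalized for having no
eligible cases. The score floor is 0 rather than the nominal printed lower
bound of 1; the proportion formulas naturally reach 0 and the 1 is treated
as descriptive. Benchmark costs are configuration inputs with synthetic
defaults; they anchor the cost-score scale and make no claim about
historical prices.

### Association analysis

All ten pairwise correlations among the five indices (three EIs, RI, SI)
across units are computed as Pearson product-moment coefficients with
two-sided p-values from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of
freedom. The published analyses report raw pairwise coefficients, so no
multiple-testing correction is applied by default (Holm is available), and
significance is the strict `p < alpha` with `alpha = 0.05`. Spearman (rank
transform, then the same machinery) is a config option. Tests cross-check
the p-values against `stats::cor.test` and against a 10,000-replicate
permutation null, and verify that under the null scenario the fraction of
significant pairs matches the nominal 5% within a binomial band.

## The synthetic cohort generator

No patient-level data from the source setting are deposited, so the
generator is a first-class, tested module, not a fixture. It emulates the
published reference population through a per-category catalog
(`default_acg_catalog()`): 18 entries — the 17 most frequent categories
plus one pooled `"OTHER"` entry for the remaining rare codes, which are not
simulated individually because no per-code moments are published — each
carrying its attended share and the mean/SD of annual episodes, cost and
visits.

### Generative model

For unit $u$ with complexity shift $s_u$, the case-mix weights are an
exponential tilt of the catalog shares toward high-burden categories,
$w_a \propto \text{share}_a \exp\{s_u (m_{a,\text{visits}} - \bar m)/\sigma_m\}$,
which makes the implied visit burden strictly increasing in $s_u$. Residual
between-unit mix dispersion is Dirichlet with concentration
$\kappa \cdot w$ (default $\kappa = 3000$, chosen so residual RI dispersion
is of the order of 1%; $\kappa = \infty$ uses the tilted shares exactly).
Patients draw a category from the unit mix; then, given the category:

* **Visits, episodes** — zero-truncated counts. The dispersion parameter
  comes from an untruncated negative-binomial moment match
  ($\text{size} = \mu^2/(\sigma^2-\mu)$); when the catalog SD satisfies
  $\sigma^2 \le \mu$ (true for most episode cells) no negative binomial
  exists and the cell falls back to a zero-truncated Poisson, reported
  once per generation call as a warning. The untruncated mean is then
  solved by `uniroot` (tolerance 1e-12) so that the *zero-truncated* mean
  equals the target `efficiency_factor * catalog mean` exactly. Matching
  the truncated mean — rather than matching the untruncated family and
  accepting truncation bias — was a deliberate choice: the truncation bias
  on low-mean cells reaches several percent of the mean and varies
  nonlinearly with the planted efficiency factor, which would bias
  planted-factor recovery by more than the calibration criteria tolerate;
  with exact truncated means, recovery is unbiased by construction. The
  implied (slightly shrunken) truncated SD is computable in closed form
  and is what the moment-recovery tests check empirical SDs against.
  Targets below 1 are infeasible for zero-truncated counts and raise a
  configuration error.
* **Cost** — gamma with shape $(\mu/\sigma)^2$ matched to
  `eff_costs * catalog mean` and the catalog SD. Costs are continuous and
  positive, so no truncation is involved.
* **Demographics** — age from a normal (mean 49.9, SD 19.9) truncated to
  (14, 105], 56.7% female, mirroring the published attended population;
  demographics feed the descriptive table only.

Visits, episodes and cost are drawn independently within a patient given
the category: the published tables provide no within-category correlation
structure, and none is invented. This is the main acknowledged gap between
the generator and real cohorts (see Limitations).

### Sampling modes

The generator has two documented sampling designs:

* `"random"` — everything iid: multinomial category assignment, rejection
  sampling of the zero-truncated counts. This mode has honest
  $O(1/\sqrt{n})$ sampling noise and is used wherever the statistical
  behaviour of the pipeline is itself under test (null false-positive
  calibration, coupled-scenario correlation signs).
* `"balanced"` — a variance-reduction design for calibration instruments:
  category counts by largest-remainder quota allocation of the unit mix,
  and count/cost draws as stratified quantiles $F^{-1}((i-U_i)/n)$ in
  shuffled order. Marginal distributions are unchanged, but within-cell
  empirical moments converge at $O(1/n)$, so a planted gradient is
  recovered to ~0.002 rather than ~0.015 at 5,000 patients/unit. The
  planted-gradient scenarios use this mode so that what is measured is the
  estimator's structure, not Monte-Carlo luck.

Seeding: one master seed; per-unit substreams and the indicator stream are
drawn from it up front (`sample.int` inside `withr::with_seed`), so output
is byte-identical for a given configuration and seed, and the population
and indicator stages do not perturb each other.

### Planted scenarios

`plant_unit_effects()` encodes four study conditions:

* `null` — all factors 1, no tilt, quality 0.5 everywhere; iid sampling.
* `efficiency_gradient` — visit factors evenly spaced in [0.85, 1.20], the
  span of per-centre visit indices observed in the published tables;
  balanced sampling, exact mix.
* `complexity_gradient` — per-unit tilts solved (by `uniroot` on the tilt
  equation) so planted RIs are evenly spaced in [0.75, 1.25]. This span is
  deliberately somewhat wider than the published per-centre RI range
  (0.89–1.09): adjacent planted values must be separated by much more than
  the residual sampling noise at the calibration sizes for strict
  monotonicity of recovered RIs to be a meaningful check. Balanced
  sampling, exact mix.
* `coupled_quality_efficiency` — quality levels evenly spaced in
  [0.25, 0.90], cost factors $1.25 - 0.4q$ (negative coupling), episode
  factors $0.92 + 0.24q$ (positive coupling; the intercept keeps every
  zero-truncated episode target mean at or above 1, the feasibility bound
  of the smallest catalog episode mean, 1.1). Mirrors qualitatively the
  negative effectiveness–cost and positive effectiveness–episodes
  associations reported across real care teams; iid sampling, since the
  correlation analysis needs genuine noise.

Indicator observations: eligible counts are fixed fractions of the unit
panel (per-indicator `eligible_frac`, plausible prevalences of the
respective conditions); compliant counts are binomial with success
probability $\mathrm{logit}^{-1}(-1.8 + 3.6q)$ (direction reversed for the
lower-is-better indicator), so quality 0 and 1 map to compliance 14% and
86%; observed pharmacy costs are $b(2-q)$ times mean-one lognormal noise
(log-SD 0.1), so a unit at quality 1 sits exactly at benchmark. The
`exact = TRUE` mode removes all noise and is what monotonicity tests use.

## Numerical and reporting conventions

* All values are stored and compared at full precision; rounding is
  presentation-only, half-away-from-zero (`round_half_up()`), 2 decimals
  for indices and 1 for percentages. The rounding convention of the source
  tables is unstated; half-away-from-zero is the convention under which
  all printed worked examples reproduce.
* p-values below 1e-4 render as `<0.0001`; stored values keep full
  precision.
* Degenerate inputs fail loudly with classed conditions: categories absent
  from the reference (no silent smoothing — a unit with zero patients in a
  category simply contributes zero to expected totals), zero expected
  means, constant vectors in correlations, |r| = 1 (p = 0 returned with a
  warning), empty cohorts, infeasible moment targets.
* Scale equivariance: multiplying all costs by $k>0$ (cohort and reference
  alike) leaves the cost EI unchanged; asserted at 1e-12.

## Problem sizes used by the test suite

Chosen as the package's own calibration design: planted-gradient recovery
runs 13 units x 5,000 patients (recovery tolerance 0.03, against a design
error of ~0.002 under balanced sampling); conservation and oracle
equivalence run on cohorts up to 10,000 patients across 100 random draws;
null calibration uses 30 seeds x 20 teams x 250 patients (300 p-values,
binomial band 0.05 +/- 0.035); the coupled scenario uses 187 teams x 800
patients, matching the published team count; SI properties run over 1,000
random indicator tables. The full suite completes in under two minutes on
one CPU.

## Limitations

* Within a patient, visits, episodes and cost are conditionally
  independent given the category; real utilization is cross-correlated
  (an episode spans visits, costs follow visits). Passing tests therefore
  validate the index machinery and its calibration, not the joint
  fine structure of real cohorts.
* The pooled `"OTHER"` entry flattens 38 rare categories into one; unit
  differences concentrated in rare codes are not representable.
* The SI construction is a re-specification; absolute SI levels are not
  comparable to operational contract scores, only orderings and
  associations under the package's own scoring rules are meaningful.
* Upstream exclusions (out-of-region patients, transfers,
  orthodontics-only contacts) are assumed applied before data reach the
  package; the generator never produces them and `validate_cohort()` only
  checks structural consistency.
* Episode-count cells are underdispersed relative to the Poisson, so their
  zero-truncated Poisson fallback slightly overstates within-cell episode
  variance; the episode EI noise in synthetic studies is accordingly a
  touch conservative.
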