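---
title: "Analogy costing of hospital-onset infections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analogy costing of hospital-onset infections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoicost)
```

## The estimation problem

A hospital-onset infection (HOI) arises during an inpatient stay, on top of
whatever condition caused the admission. Discharge records report one total
cost per hospitalization, so the infection's incremental ("attributable")
cost is not directly observable, and the usual cohort contrasts are
confounded by disease severity, treatment intensity and length-of-stay
dynamics.

The analogy-costing framework implemented here replaces the unobservable
object with a measured analog. Hospitalizations in which the same infection
type is the *principal* diagnosis — the first-listed code, the reason for
admission — give a clean view of what treating that infection costs, and of
how that cost co-moves with patient and facility characteristics. Those
cost relationships are then transferred to hospitalizations in which the
infection appears as a *secondary* diagnosis, the administrative proxy for
hospital onset. Two assumptions carry the transfer: (i) treating a given
infection consumes similar resources whether its onset was in the community
or the hospital, and (ii) the extra cost of treating comorbidities
alongside a principal infection approximates the extra cost an HOI imposes
on treatment of the underlying disease. The credibility condition checked
descriptively (see `univariate_summary()`) is that secondary-group mean
cost and mean LOS strictly exceed those of both the principal group and a
matched no-infection group; if treating infection and underlying disease
together were *cheaper* (economies of scope), the analogy would not hold.

## Pipeline stages

**Cohorts** (`classify_infection()`, `build_cohorts()`). A record is
principal for a type when its first diagnosis code is in the type's
catalog; secondary when a later field holds a catalog code, the first does
not, and the stay lasted at least `min_secondary_los = 3` days (a crude
hospital-onset screen: day-1 or day-2 coded infections are more likely
present on admission). A record that is principal for one type and
secondary for another contributes to both types' cohorts: the models are
fitted per type, and no cross-type exclusion is applied. Within a type,
first-position membership wins: such a record is principal only.
Device-association (`device_flags()`) is a pure conjunction — a urinary
tract infection code plus a catheter-insertion procedure code flags CAUTI,
a pneumonia code plus a mechanical-ventilation code flags VAP — while
bloodstream infections are kept as a single combined type because coding
for central-line insertion is too unreliable to split them.

The matched no-infection group is drawn 5:1 by exact stratification on the
secondary group's principal diagnosis codes, sampling without replacement
among pool records that carry no catalog code of *any* infection type.
Stratum shortfalls are reported (achieved ratio per stratum), never
back-filled from other strata, since the only matching criterion is the
principal-code distribution. The matched group is descriptive only; it
enters no cost model.

**Costing** (`charges_to_cost()`, `inflate()`). Costs are charges times the
facility cost-to-charge ratio. Money is kept at full precision internally
and rounded to whole dollars only in reports. Currency years move through
multiplicative price-index factors; the bundled defaults (2011→2017 =
1.0921, 2016→2017 = 1.0226) are the hospital producer-price factors implied
by the bundled reference tables, recoverable to within ±0.001 from every
row (`implied_inflation_factors()`). Inflation is linear, so adjusting
before or after averaging differs only in sub-dollar rounding.

**Stage 1** (`fit_median_regression()`). Cost is regressed on an intercept
plus nine covariates — LOS (days), diagnosis count, procedure count,
urban-teaching flag, small-bedsize (< 250 beds) flag, age (years), APR-DRG
severity-of-illness and risk-of-mortality indices (1–4, treated as
continuous), and the CMS area wage index — by minimizing the sum of
absolute residuals. The median is the right target for charge data: the
upper tail is long and partly artifactual (outliers, upcoding), and the L1
fit is insensitive to it. The covariate list is configurable; the nine
variables above are the default because the framework's published
coefficient sets use them.

**Stage 2** (`attributable_costs()`, `mean_attributable_cost()`). For each
secondary record the full stage-1 linear predictor is evaluated — intercept
included, all non-LOS covariates at the record's own values — with LOS
replaced by the principal cohort's mean LOS, interpreted as the
attributable stay. The estimate is the average over the secondary cohort,
decomposed exactly into `b_los × attributable_los` and a non-LOS remainder.
This functional form is a reconstruction (the source figure is not printed
as an equation); it is the one that reproduces the published decomposition
anchors at the published secondary-group covariate means, whereas
difference-based alternatives (secondary-minus-principal covariates, or
dropping the intercept) miss them by a wide margin. Negative per-record
predictions are retained: averaging is the estimator, and flooring would
bias the mean upward. Because the model is linear, the mean of per-record
predictions equals the prediction at mean covariates (tested to 1e-6
relative tolerance), which is also what makes the wage-index
counterfactual (`wage_counterfactual()`) a closed-form shift:
`b_wage × (new_wage − mean_wage)`.

**National totals** (`national_totals()`, `cost_shares()`,
`split_burden()`). Mean attributable costs in a single currency year are
multiplied by central/low/high incident-case counts and summed to
device/nondevice subtotals and a grand total; mixing currency-year tags is
refused. Burden counts are kept as multiples of 100 (half rounds away from
zero; the sources state no tie rule). Where a source reports only a
combined burden, `split_burden()` applies a device-associated proportion
and re-derives both parts from unrounded intermediates. Reproduction mode
(`reference_national_table()`, `as_national_cost_table()`) recomputes
aggregates from published *rounded* inputs and therefore asserts agreement
with published totals only to rounding slack: the bundled tables' own
per-type rows sum to their printed subtotals within $2, and recomputing
per-type totals from rounded costs × rounded burdens lands within 0.1% of
the printed grand totals. The pipeline proper never rounds intermediates.

Two published-arithmetic conventions are exposed rather than silently
reproduced: `attributable_decomposition(round_coefficient = TRUE)` rounds
the LOS coefficient to whole dollars before multiplying (the convention of
the published decomposition, e.g. $1476 × 4.24), and the professional-fee
uplift figures in the acceptance script apply the 15% rate to
billions-rounded totals, again matching the published arithmetic. The
default code paths stay exact.

## The L1 solver

No quantile-regression routine ships with the declared dependencies, and
the solver's correctness is load-bearing for the whole framework, so it is
implemented in-package (`l1_fit()`) in two phases:

1. *Smoothed start.* Iteratively reweighted least squares on weights
   `1 / max(|r|, eps)`, with `eps` shrunk from `0.1 × mean(|y|)` down to
   `1e-11 × mean(|y|)` as steps stall. This is the Huber-style
   majorize-minimize scheme for the L1 objective; it gets close to the
   optimum but never exactly onto a vertex.
2. *Basis-exchange polish.* An L1 optimum interpolates `p = ncol(X)`
   observations. Starting from the `p` smallest-residual, linearly
   independent rows, each sweep relaxes one interpolation condition at a
   time and minimizes the objective exactly along the resulting edge
   direction — a weighted-median problem solved in closed form — exchanging
   basis rows whenever the objective drops. At a vertex where no exchange
   improves, convexity of the piecewise-linear objective makes the vertex a
   global minimizer.

Numerical choices: exchange improvements must beat the current objective by
`1e-12 × (1 + f)`; a weighted-median crossing that lands exactly on half
the total weight (within 1e-9 relative) indicates a flat optimal segment —
the midpoint is taken and the fit is flagged `nonunique`. Rank-deficient
designs are refused with the collinear columns named; so are cohorts with
fewer records than parameters. Ties in the data are unproblematic because
tests compare objectives, not coefficient vectors, in degenerate cases.
The solver is validated three ways: objective equality (1e-8 relative) with
brute-force enumeration of all exact-fit bases on every random instance
with n ≤ 10 and up to two columns; agreement with an external
quantile-regression implementation on a larger instance; and
scale/shift-equivariance plus a coordinate-perturbation optimality
certificate. Standard errors are nonparametric case-resampling bootstrap
percentiles (`bootstrap_se()`), seeded and reproducible; the published
tables do not name their SE method, so no agreement with published SEs is
claimed.

## The synthetic discharge generator

Restricted inpatient samples cannot be redistributed, so
`generate_discharges()` produces datasets with the statistical structure
the analysis needs, and `lrti_generator_config()` pins that structure to
the bundled LRTI reference values: ground-truth cost coefficients equal to
the published stage-1 estimates for the matching year, and per-group
covariate distributions targeting the published group means (principal mean
LOS 3.83 days in 2011 and 4.24 in 2016; secondary groups shifted upward in
LOS, code counts, age, severity and mortality risk so the analogy ordering
holds by construction). Counts use negative-binomial draws (LOS offset by
+1, or +3 for secondary records so the cohort respects the 3-day screen;
diagnosis counts capped at the 25/30 fields of the ICD-9/ICD-10 layouts),
severity and risk use four-point categorical distributions solved to match
the published means, ages are gamma draws capped at the published maxima,
and facility variables use urban-teaching share 0.5, small-bedsize share
0.3 and a truncated-normal wage index at the published mean/SD. The
infection mix (30% principal / 25% secondary) is far denser than any real
sample; it exists so that moderate `n_records` yield workable cohorts of
every kind.

Cost is the configured linear index times a multiplicative disturbance with
median exactly 1, so the conditional median of cost equals the index and
the generating coefficients are recoverable by median regression. The
disturbance is a contaminated log-symmetric model: `exp(0.005·Z)` for 90%
of records and `exp(1.5·Z)` for the remaining 10%. The heavy component
produces the extreme right-tail outliers (costs off by orders of magnitude)
that motivate using the median in the first place; the tight component
keeps the coefficients identifiable at desk scale — an a-priori power
calculation shows that with a single wide lognormal the small coefficients
(age enters at ~$2.3/year against costs in the thousands) would need
sample sizes far beyond a 10^4-record cohort to pin down within ±5%. Under
these defaults the package's recovery test re-estimates every generating
coefficient within ±5% on a 10^4-record principal cohort. Negative index ×
noise draws are clamped at a $31 floor (the smallest plausible discharge
cost in the reference statistics); the affected fraction is far too small
to disturb the conditional medians. Charges are defined as `cost / CCR`
with CCR uniform on (0.2, 0.8), and cost is then re-derived as
`charges × CCR` so the conversion round-trips exactly in floating point.

What the generator does **not** emulate: survey weights, hospital
clustering and state composition, cost-accounting differences between
hospitals, correlation between covariates beyond group membership, per-type
covariate differences (all types share the group-level distributions), and
any dependence of CCR on facility type. Passing tests therefore demonstrate
that the *machinery* — classification, matching, the solver, the transfer
arithmetic — is correct under the stated data-generating process, not that
the analogy assumptions hold in real discharge data.

## Problem sizes and seeds

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the asymptotic behaviour being tested is visibly
stable: 10^4-record cohorts for recovery, partition and ordering
invariants; 8 replicate datasets × 120 bootstrap replicates (principal
cohorts of ≈ 1,800) for the interval-coverage check of the nominal-95%
bootstrap intervals (≥ 90% observed coverage required); 60–150 random small
instances for the brute-force solver comparison. Every stochastic step —
generation, matching, bootstrap — takes an explicit integer seed and
restores the caller's RNG state, so results are bit-reproducible.

## Known limitations

- The stage-2 functional form is a numerically supported reconstruction,
  not a transcribed equation; alternative forms fitting the same published
  anchors less well were rejected, but the ambiguity is inherent.
- The 3-day secondary screen is a blunt onset filter; records misclassified
  in either direction remain, exactly as in the source methodology.
- Bootstrap percentile intervals mildly undercover in small cohorts
  (vertex solutions move discretely under resampling); the coverage test
  sizes reflect where nominal coverage is reached.
- The generator's covariate independence makes the stage-1 design matrix
  better conditioned than real discharge data, where LOS, severity and
  code counts are strongly correlated; real-data fits should expect wider
  intervals than the synthetic benchmarks suggest.
- `stat_mode()` computes modes on dollar-rounded costs with smallest-value
  tie-breaking — a declared convention, since mode-on-continuous-data is
  otherwise ill-defined.
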