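---
title: "Models and methods behind glutenmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glutenmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutenmeta)
```

`glutenmeta` chains four analyses: a meta-analysis of nitrogen-fertilisation
effects on wheat gluten/gliadin outcomes, a dose–response model of grain
gliadin content, a per-capita gliadin-intake derivation over 1961–2010, and
a country-level association with coeliac-disease prevalence. This vignette
explains each model, its assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Effect sizes

A fertilisation contrast compares a higher-dose arm against a control arm
of the same study and outcome. The effect size is the log response ratio
`lnRR = ln(X_t) − ln(X_c)` with delta-method sampling variance

$$ v = \frac{S_t^2}{n_t X_t^2} + \frac{S_c^2}{n_c X_c^2}. $$

Two properties make the lnRR the right scale for this evidence base, where
absolute contents are reported in incompatible assays: it is invariant to a
common rescaling of both arms, and antisymmetric under swapping them (both
are enforced as property tests). Some published variance expressions wrap
this sum in an additional logarithm; that renders the quantity negative for
typical inputs and is inconsistent with the standard response-ratio
machinery, so we treat it as a typographical slip and use the plain sum.

Multi-dose experiments are expanded by `contrasts_from_dose_series()`. The
default pairs every higher dose against the *lowest* dose (usually 0) as a
common control — the standard convention for fertilisation meta-analyses
and the natural reading of designs such as 0/120/240/360 kg N ha⁻¹ y⁻¹. An
`"adjacent"` pairing is available for sensitivity checks. Each genotype ×
dose contrast enters as its own row; within-study dependence is handled
downstream rather than by pre-averaging genotypes, because averaging would
discard the genotype-level dispersion that the dose–response stage needs.

Outcome groups with 30 or fewer effects are dropped (`min_obs = 30`):
pooled estimates from sparser groups would not support a global claim, and
the filter threshold is exposed for reanalysis.

Zero or negative reported means are rejected rather than offset-corrected —
the log ratio is undefined there and an offset would silently bias small
contrasts. SE-to-SD conversion (`SD = SE·√n`) is a table-construction
concern, never applied inside the effect-size code.

## Random-effects pooling by REML

Per outcome, effects follow

$$ y_j \sim N(\mu,\; v_j + \tau^2), $$

optionally with a study-level random intercept (variance
$\sigma^2_{study}$) added whenever a study contributes more than one
contrast. The marginal covariance is block-diagonal by study, so the
restricted log-likelihood is evaluated with one rank-one
(Sherman–Morrison) update per study block — O(k) per evaluation.

Numerical choices:

* single-component fits maximise the profiled restricted likelihood with
  Brent search on `[0, 10·var(y)]` at tolerance 1e-8, snapping to the
  τ² = 0 boundary when the boundary likelihood is at least as good (Brent
  never evaluates the endpoint itself);
* two-component fits use `nlminb` from a DerSimonian–Laird starting point,
  bounds `[0, 10·var(y)]`, iteration cap 200; non-convergence is an error
  that reports the last iterate rather than returning it silently;
* the 95 % CI uses the normal quantile (`μ̂ ± 1.96·SE`), matching the
  common default of meta-analytic software, not a t/Knapp–Hartung
  adjustment; at the evidence sizes targeted here (≈ 50–120 effects per
  outcome) the difference is small, and the coverage property test
  (93–97 % at 1000 replicates) checks the consequence rather than the
  formula;
* significance is *defined* as the 95 % CI excluding zero; a Wald p-value
  is reported alongside but the flag never depends on it.

Dependence induced by shared control arms (one control serving several
dose contrasts) is **not** covariance-adjusted. This matches how such
tables are commonly analysed, keeps the weighting simple, and is listed as
a known limitation: it makes CIs slightly narrower than a full
multivariate treatment would.

The REML engine is validated two ways: against a dense grid-search oracle
of the profiled restricted likelihood (agreement within 1e-3 on random
small instances) and, in the test suite only, against `metafor`'s
`rma`/`rma.mv` as an independent implementation.

## Dose–response

Two entry points exist and are deliberately distinct:

* `fit_dose_response()` — content scale: regresses gliadin content
  (mg g⁻¹) on the fertilisation rate. The default form is linear in the
  raw rate; because doses span an order of magnitude a `log_dose` form
  (`log1p`, since control doses of 0 occur) is one flag away. The linear
  default reflects that the downstream intake chain is anchored on two
  (rate, content) endpoint pairs, which a line fits exactly.
* `meta_regression()` — effect scale: REML meta-regression of lnRR on the
  dose increment, weights `1/(v + τ²)`, for the moderator-sensitivity
  question "does a bigger dose step produce a bigger ratio?".

Predictions are guarded to `[0, 1.5 × max observed dose]`; extrapolating a
fitted agronomic line far beyond the evidence is almost never meaningful,
and the guard must be overridden explicitly.

`anchored_dose_response()` builds the exact line through 44 mg g⁻¹ at
10 kg N ha⁻¹ y⁻¹ and 59 mg g⁻¹ at 100 kg N ha⁻¹ y⁻¹ (slope 1/6). Its
coefficient covariance is zero, so uncertainty propagated from it
vanishes — a useful degenerate case for testing the bootstrap.

## The intake chain

Concentration (mg g⁻¹ = g per kg) times per-capita wheat-and-derivatives
consumption (kg y⁻¹) gives per-capita gliadin intake after a factor 10⁻³;
a dimensional test pins this (44 mg g⁻¹ of 1000 kg is 44 kg). Series are
inner-joined on years; interior gaps may be filled by linear interpolation
(`fill_year_gaps()`, flagged in the result), never extrapolated.

The endpoint change reports `delta = end − start` and
`pct = 100·delta/start`. Its uncertainty comes from a parametric bootstrap
over the dose–response coefficients: draws from `N(coef, vcov)` are pushed
through the whole chain with the input series held fixed. The source of
the published-style "± SE" on such derived trajectories is rarely stated;
we chose coefficient uncertainty as the dominant, reconstructible term and
document the replicate count (default 1000) and seed in the result. The
wheat-consumption series is an *input*: flour-extraction rates and
additive-flour corrections are out of scope.

## Country association and co-trajectory

Both prevalence and consumption are measured with error, so the
country-level slope uses model-II regression. The major axis (MA) is the
primary estimator, with SMA and OLS always reported alongside, because MA
is the conventional first output of model-II software and the choice is
not otherwise determinable; the ranged major axis is omitted since it
requires a range-ratio choice we have no basis for. Slopes come from the
closed forms (leading eigenvector; `sign(r)·sd_y/sd_x`), intercepts pass
through the centroid, CIs use the classical constructions (Jolicoeur's
eigenvalue interval for MA, the `B = t²(1−r²)/(n−2)` interval for SMA),
and the p-value is the Pearson correlation test. Property tests enforce
the attenuation ordering (|MA|, |SMA| ≥ |OLS| for |r| < 1), centroid
passage, SMA swap-inversion, and agreement with brute-force loss
minimisation over a dense slope grid.

`trajectory_correlation()` correlates two annual series on their common
years. The default uses raw levels; `diff = TRUE` offers first differences
because "increase correlated with increase" is ambiguous between levels
and changes. Two strongly monotone series will correlate highly on levels
regardless of mechanism — the correlation is descriptive, not causal, and
the package makes no adjustment for confounding because none is possible
at this aggregation level.

## The synthetic generator

The generator exists so that every stage can be exercised end-to-end with
known ground truth. Defaults encode the study conditions of the analysis
it emulates: 47 studies, six outcomes, dose designs drawn from a pool of
realistic grids (0–450 kg N ha⁻¹ y⁻¹), a fertilisation series rising
9.84 → 93.8 kg N ha⁻¹ y⁻¹ over 1961–2010, a 38-country panel, and a
prevalence trajectory anchored at 0.2 % (1975) rising five-fold by 2000.

Contents follow `base_o · (1 + a_o·dose)` times lognormal offsets; the
per-outcome amplitude `a_o` is parameterised by the true lnRR of a
reference 10 → 100 kg contrast (total gliadin: `log(59/44)`, i.e. the
line through 44 and 59 mg g⁻¹). Because studies sample their dose design
from a grid pool, the *expected pooled* lnRR differs from the reference
value; `generator_config()` derives it exactly by enumerating all
lowest-vs-higher contrasts of the pool (`mu_true`), and parameter-recovery
tests compare against that, not the reference.

Dispersion is layered deliberately:

* `study_sd` (0.15) and `outcome_sd` (0.30): lognormal baseline offsets at
  the study and study-by-outcome level, shared by both arms of a contrast.
  They scatter absolute contents — driving the realistic weakness of the
  content-vs-dose fit — while cancelling exactly in the response ratio.
* `tau2` (0.01) and `sigma2_study` (0.005): heterogeneity injected into
  the ratio itself, at contrast and study level.
* `arm_sd` (0.05): a small independent per-arm dispersion that feeds both.

`outcome_sd` is the one calibrated constant: a one-time grid search
(`scripts/calibrate_noise.R`) selected it so the expected content-fit R²
is ≈ 0.30 under the default design; the script and its selection are in
the repository, and the value is frozen — it is part of the study
conditions, not a tuning knob.

The wheat-consumption default is a linear ramp 54.5 → 64.4 kg y⁻¹ per
capita. Those endpoints are implied by dividing the target intake
endpoints (≈ 2.4 and 3.8 kg y⁻¹) by the anchored concentrations (44 and
59 mg g⁻¹): the concentration rise alone (+34 %) cannot produce a +58 %
intake rise, so the consumption series must carry the remaining ≈ 18 %. A
`constant` profile is available, under which the intake %-change collapses
to the concentration %-change exactly (a property test).

What the generator does **not** emulate: genotype-specific dose–response
biology (one genotype label per study), realistic transcript-count noise
(lognormal suffices), missing or asymmetric reporting (SDs are always
present), correlated errors between arms, and publication bias. Passing
tests therefore demonstrate that the *machinery* recovers known truth
under a plausible data-generating process — not that the real literature
satisfies these assumptions.

## Problem sizes and runtime envelope

Simulation-based tests use sizes chosen to make their Monte-Carlo error
small relative to the bands they check: 1000 replicates for CI coverage
(binomial SE ≈ 0.7 %), 500 for the type-I rate of the significance flag
(SE ≈ 1 %), 200 for country-slope recovery, 20 random instances for each
oracle comparison, and 8 pipeline replicates for the end-to-end pattern.
The end-to-end checks compare *replicate averages* of R² and the intake
%-change against their envelopes: a single 47-study realisation carries
irreducible sampling spread (R̂² has SE ≈ 0.08 at ~160 points), so the
envelope is a statement about the calibrated expectation, which the
averages estimate with adequate precision.

## Known limitations

* Shared-control covariance is ignored (see above).
* The normal-quantile CI is slightly anticonservative for few studies.
* The content dose–response fit pools arms across studies without weights;
  between-study baseline spread therefore inflates the fitted intercept
  and slope by the lognormal mean factor, which cancels in %-change
  quantities but not in absolute predictions.
* The co-trajectory correlation and the country association are
  descriptive; no causal identification is attempted.
* Real FAO consumption and prevalence compilations are not bundled; file
  readers (`read_study_table()`, `read_time_series()`,
  `read_country_panel()`) accept externally assembled CSVs with the
  documented schemas.
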