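# glutenmeta

Nitrogen fertilisation of wheat has intensified roughly ten-fold since the
1960s, and fertilisation is known to raise the concentration of grain
storage proteins — including the gliadins, the gluten fraction that
triggers coeliac disease in genetically susceptible people. `glutenmeta`
implements the full quantitative chain needed to study that link: a
response-ratio meta-analysis of fertilisation experiments, a dose–response
model of grain gliadin content, the derivation of the per-capita gliadin
intake trajectory, and the population-level association with
coeliac-disease prevalence. It is aimed at biostatisticians and
agronomy/epidemiology researchers who want each stage as a tested,
reusable component.

## The models

**Effect sizes.** Each fertilisation contrast (control dose vs higher
dose) contributes a log response ratio with its sampling variance

```
lnRR = ln(X_t / X_c),    v = S_t²/(n_t X_t²) + S_c²/(n_c X_c²)
```

where `X`, `S`, `n` are the arm means, SDs and sample sizes.

**Pooling.** Per outcome (total gluten, total gliadins, α/β-, γ-,
ω-gliadins, gliadin transcripts), effects are pooled under the
random-effects model `lnRR_j ~ N(μ + u_study, v_j + τ²)`, with the
heterogeneity τ² (and the study-level intercept variance σ²_study, since
most studies contribute several dose contrasts) estimated by restricted
maximum likelihood. An effect is significant when the 95 % CI excludes
zero. Outcomes with 30 or fewer effects are dropped.

**Dose–response.** Grain gliadin content (mg g⁻¹) is regressed on the
fertilisation rate (kg N ha⁻¹ y⁻¹); a REML meta-regression of lnRR on the
dose increment is available as a sensitivity analysis.

**Intake chain.** An annual fertilisation series is pushed through the
dose–response fit to a concentration series, multiplied by per-capita
wheat consumption (`kg intake = mg g⁻¹ × kg wheat / 1000`), and summarised
as the endpoint change with parametric-bootstrap SEs over the fit
coefficients.

**Association.** Coeliac prevalence vs per-capita wheat intake across
countries is fitted by model-II regression (major axis, standardised major
axis, OLS side by side), and the intake and prevalence trajectories are
compared by Pearson correlation on their common years.

A calibrated synthetic generator (`generator_config()`,
`generate_study_table()`, `generate_time_series()`,
`generate_country_panel()`) produces every input with known ground truth.

## Worked example

```r
library(glutenmeta)
report <- run_pipeline(seed = 1)   # simulates all inputs, runs every stage
print(report)
```

```
== Fertilisation -> gliadin -> intake pipeline ==

Pooled response ratios by outcome (REML random effects)
            outcome   k n_studies             lnRR [95% CI]       tau2
       total_gluten 119        47 +0.267 [+0.196, +0.339] * 0.03884660
      total_gliadin 119        47 +0.320 [+0.249, +0.392] * 0.03474536
         ab_gliadin 119        47 +0.356 [+0.292, +0.420] * 0.04638966
          g_gliadin 119        47 +0.275 [+0.216, +0.335] * 0.04069372
          w_gliadin 119        47 +0.319 [+0.250, +0.389] * 0.05275547
 gliadin_transcript 119        47 +0.425 [+0.338, +0.511] * 0.06842336
* 95% CI excludes zero

Dose-response fit (linear form, n = 166)
  content = 42.5 + 0.1822 * dose
  R^2 = 0.4362, slope p = 3.64e-22

Intake change 1961 -> 2010 [kg y-1 per capita]
  2.41 -> 3.84  (delta +1.42 +/- 0.0734, +59% +/- 5.8%)
  SEs from 1000 parametric bootstrap draws of the dose-response coefficients

Intake/prevalence co-trajectory: r = 0.998 (p = 4.5e-62, 50 overlapping years)
Country panel MA slope: 0.01284 %CD per kg wheat (r = 0.894)
```

Reading the output: all six pooled response ratios are positive with CIs
excluding zero — fertilisation raises every gluten/gliadin outcome in the
simulated evidence base. The fitted content line (R² ≈ 0.3–0.45 across
realisations) converts the historical fertilisation rise
(9.84 → 93.8 kg N ha⁻¹ y⁻¹) into a concentration rise of roughly
44 → 59 mg g⁻¹, which combined with wheat consumption gives a per-capita
gliadin intake rise of about 1.4 kg y⁻¹ (≈ +58 %), co-moving with the
coeliac-prevalence trajectory.

Individual stages are plain functions returning classed objects
(`meta_reml()`, `fit_dose_response()`, `intake_change()`, `model2_fit()`,
…) with the usual `print`/`coef`/`confint`/`predict` methods;
`write_pipeline_report()` serialises a run to JSON, a text forest table
and series CSVs.

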