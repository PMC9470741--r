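# netstage

Stage-specific net survival from cancer-registry data when historical stage
at diagnosis is largely missing.

## The problem

Cancer registries report survival by stage at diagnosis (localised /
regional / distant), but stage recording is often incomplete — and worst
exactly where long-term estimates draw their information: diagnoses from a
decade ago. Up-to-date 10-year stage-specific estimates therefore need
three ingredients at once:

* **period analysis** — only person-time falling inside a recent calendar
  window (here 2015–2017) enters the estimation, via delayed entry at
  `t0 = max(0, window_start − diagnosis date)`, so short-term estimates come
  from recently diagnosed patients and long-term estimates from survivors of
  older diagnoses;
* **relative-survival (excess-hazard) modelling** — all-cause registry
  deaths are decomposed as expected (population lifetable) hazard plus a
  cancer-attributable excess hazard, avoiding unreliable cause-of-death
  coding. The package fits flexible parametric models on the log cumulative
  excess hazard scale,

  `log Λ(t | x) = s0(log t) + x'β + Σ_k s_k(log t) x_k`,

  with restricted cubic splines for the baseline (df 5), an age spline
  (df 4, effect constant in the outer 2 age percentiles), sex, and
  time-dependent effects (df 2 splines) for each covariate, one model per
  stage, maximised with an analytic gradient under delayed entry;
* **multiple imputation of stage** — a multinomial logistic model of
  observed stage on sex, age, subsite, grade, diagnosis year, the event
  indicator and the Nelson–Aalen cumulative hazard `H` together with its
  time-weighted companion `H1(t) = Σ_{t_j≤t} t_j d(t_j)/n(t_j)` (plus
  sex/age interactions with both), drawn properly (coefficients sampled
  from the asymptotic distribution), with estimates pooled by Rubin's
  rules on the complementary log-log scale.

A **pre-window** (2012–2015) confines strong assumptions to diagnoses made
before a span of calendar time with good stage completeness. Four stress
conditions probe the imputation: (1) impute everyone missing; (2)–(4)
impute only diagnoses on/after the boundary and exclude / assume localised
/ assume distant before it. Marginal (age-standardised to the 2017
diagnosis distribution) relative survival per stage is compared across
conditions, against the full-data fit, and against the non-parametric
Pohar–Perme net-survival estimator standardised over ICSS age groups
(<45, 45–54, 55–64, 65–74, 75+).

Because real registry extracts are access-restricted, the package ships a
synthetic registry generator with known truth: stage-specific Weibull
excess hazards calibrated to published US colon relative survival,
background mortality from a Gompertz lifetable, administrative censoring at
the end of 2017, and the exactly parameterised stage-missingness mechanism
(35% of regional diagnoses in 2011 set missing, +5 pp per earlier year to
65% in 2005, distant +7 pp and localised −7 pp, and a uniform 20% for
2012–2017). Every pipeline stage is testable against the retained truth.

## A worked example

```r
library(netstage)
library(dplyr)

cfg <- experiment_config(
  cohort   = cohort_spec(n = 20000),
  conditions = 1:4, prewindow = c(TRUE, FALSE),
  m = 10, tgrid = c(1, 5, 10), seed = 42)
res <- run_experiment(cfg)

res$summary %>%
  filter(time == 10, stage == "distant") %>%
  select(condition, prewindow, estimate, reference, pp)
#> # A tibble: 8 × 5
#>   condition prewindow estimate reference    pp
#>       <int> <lgl>        <dbl>     <dbl> <dbl>
#> 1         1 TRUE        0.0889     0.112 0.108
#> 2         1 FALSE       0.0889     0.112 0.108
#> 3         2 TRUE        0.0933     0.112 0.108
#> 4         2 FALSE       0.0967     0.112 0.108
#> 5         3 TRUE        0.0933     0.112 0.108
#> 6         3 FALSE       0.0967     0.112 0.108
#> 7         4 TRUE        0.211      0.112 0.108
#> 8         4 FALSE       0.307      0.112 0.108
```

`estimate` is the pooled 10-year marginal relative survival for
distant-stage disease under each imputation condition, `reference` the
full-data (true-stage) model estimate and `pp` the Pohar–Perme check.
Conditions 1–3 sit close to the reference; condition 4 — recoding every
historical missing stage as distant — inflates the distant-stage estimate
(0.21 vs 0.11), and removing the pre-window roughly doubles the distortion
(0.31): long-surviving patients whose true stage was localised or regional
are being counted as distant survivors. `autoplot(res)` draws the curves;
`compare_to_truth(res)` tabulates signed deviations.

Individual stages of the pipeline are ordinary functions over data frames —
`generate_cohort()`, `apply_missingness()`, `apply_period()`,
`nelson_aalen()` / `h1_statistic()` / `impute_stage()`, `fit_fpm()` /
`marginal_rs()` / `rubin_combine()`, `pohar_perme()` — and return tibbles,
so they compose with the usual dplyr verbs. See the methods vignette
(`vignettes/stage-imputation-methods.Rmd`) for the model details, numerical
choices and limitations.

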