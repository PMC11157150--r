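# accbehav

Behaviour classification and heat-response time budgets from collar
accelerometry.

Biologging collars on wild ungulates record short tri-axial acceleration
"bursts" (here 3.3 s at 33.3 Hz, one burst every 5 minutes) around the
clock, for months, on animals nobody can watch. `accbehav` turns those raw
bursts into an answer to an ecological question: **how do animals
reallocate their behaviour — feeding, walking, ruminating, resting — when
the day gets dangerously hot, and do they make up for it at night?** It is
aimed at movement ecologists and ecophysiologists working with
accelerometer collars and station weather data.

The chain has three stages:

1. **Classification.** Each burst is summarised by 19 features: for the
   surge axis x and the rotation-invariant yz-plane magnitude
   `ayz = sqrt(y² + z²)`, the time-domain mean, variance, SD, max, min,
   range and the spectral main frequency, main amplitude and normalised
   entropy; plus tri-axial ODBA (overall dynamic body acceleration,
   `mean(|x − x̄ₛ| + |y − ȳₛ| + |z − z̄ₛ|)` with the static components from a
   22-sample running mean), the standard proxy for energy expenditure.
   Correlation-filtered forward selection (|r| < 0.9) keeps the 5 most
   predictive features, and a gradient-boosted tree model (nrounds 10,
   max_depth 6, eta 0.3) classifies bursts into a 12-behaviour ethogram,
   evaluated with a pooled 5-fold cross-validated confusion report.
2. **Aggregation.** Predictions consolidate to 5 analysis categories
   (browsing, grazing, walking, ruminating, resting; ~2% rare behaviours
   excluded), join a blackglobe heat index computed from air temperature,
   solar radiation and humidity, and aggregate into afternoon
   (12:00–17:59) time-budget proportions and mean-ODBA cells per
   (blackglobe °C × hour × month × individual), the latter only where ≥ 30
   recordings support the mean.
3. **Modelling.** Penalized-spline mixed models (GAMMs with random
   intercepts per individual) estimate the partial effect of blackglobe
   temperature on each behaviour's budget and ODBA, and cyclic-spline
   models compare diel curves between the 10 hottest and 10 coolest days
   of the hot season, separating a change in diel *shape* (interaction
   smooth) from a change in the 24-h *mean* (intercept contrast, reported
   as a percentage difference).

A synthetic-data module generates labelled bursts, behaviour timelines and
weather series with known ground truth, so the whole pipeline is testable
— and demonstrable — without any field data.

## Worked example

Train and evaluate a classifier on a simulated labelled deployment:

```r
library(accbehav)

train <- simulate_training_set(n_per_class = 50, seed = 11)  # 600 bursts
feats <- feature_matrix(center_bursts(train))
sel <- select_features(feats, seed = 11)
sel
#> Forward feature selection (baseline accuracy 0.083, |r| < 0.9)
#> # A tibble: 5 × 4
#>   feature     step accuracy contribution
#>   <chr>      <int>    <dbl>        <dbl>
#> 1 x_variance     1    0.875      0.792
#> 2 x_mean         2    0.987      0.112
#> 3 yz_min         3    0.995      0.00833
#> 4 x_freqmain     4    0.997      0.00167
#> 5 x_entropy      5    0.997      0

cross_validate(feats, sel$feature, seed = 12)
#> Confusion report on 600 predictions
#>   accuracy 99.7%, 95% CI [98.8%, 99.9%]
```

Surge variance dominates (it separates gaits from postures), posture means
and spectral features mop up the rest — and 99.7% of simulated bursts are
recovered. Now the thermal analysis on a 3-individual, 30-day hot-season
scenario with the generator's default heat response (grazing suppressed by
−0.05 log-odds per °C blackglobe):

```r
cfg <- scenario_config(n_individuals = 3, n_days = 30, seed = 11)
tl <- simulate_timeline(cfg)
rec <- consolidate_records(tl$ticks)
#> excluded 539 of 25920 records (2.1%) in rare behaviours
rec <- add_time_fields(join_weather(rec, thermal_series(tl$weather)))

cells <- time_budget(afternoon_filter(rec))
fit_heat_model(cells, "grazing")
#> Penalized-spline mixed model: proportion of grazing (alpha = 0.05)
#>               term       type       edf ref_df  statistic   p_value
#> 1      (Intercept) parametric        NA     NA -2.160e+01 5.696e-57
#> 2    s(blackglobe)     smooth 1.5018393  1.833  1.230e+02 0.000e+00
#> 3          s(hour)     smooth 1.4867687  1.812  3.152e+01 0.000e+00
#> 4 s(individual_id)     smooth 0.0004897  2.000  1.669e-04 5.068e-01
```

The planted temperature effect is recovered as a strongly significant
blackglobe smooth (its partial effect, via `partial_effect()`, falls
monotonically across the 40–60 °C range). The diel comparison between the
10 hottest and 10 coolest days:

```r
ex <- select_extreme_days(daily_max(tl$weather), n = 10)
fit_diel_model(diel_budget(rec, ex), "grazing")
#> 24-h mean, hot vs cool: -49.6% (interaction p = 0.72, intercept p = 1.82e-55)
```

Under this scenario heat suppresses grazing at every hour, so the 24-h mean
drops sharply (intercept contrast significant) while the diel *shape* is
unchanged (interaction not significant). The
`scenario_diel_compensation()` generator plants the opposite pattern —
daytime suppression exactly repaid at night — and the model then reports a
significant interaction with a non-significant intercept contrast.

The full pipeline (simulate → train → analyze, file-based, YAML-configured)
is available as `run_simulate()`, `run_train()` and `run_analyze()`, or
from a shell via `inst/cli/accbehav.R`.

## Package layout

- `R/io.R` — burst/weather readers and writers, dialects, validation
- `R/preprocess.R` — centring, G conversion, collar-orientation harmonisation
- `R/features.R` — 19 burst features incl. ODBA
- `R/select.R`, `R/classify.R` — feature selection, boosted classifier,
  confusion reports
- `R/ethogram.R` — 12 → 5 consolidation
- `R/thermal.R` — blackglobe index, daily maxima, extreme-day selection
- `R/budget.R` — weather join, afternoon filter, budget and ODBA cells
- `R/smooth.R` — heat-response and diel GAMMs, concurvity, partial effects
- `R/synthetic.R` — signal models, timeline scenarios, fixture suites
- `R/pipeline.R` — configuration and the simulate/train/analyze stages

The methods vignette (`vignettes/accbehav-methods.Rmd`) documents the
models, parameter defaults, generator design and known limitations.
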