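---
title: "From collar accelerometry to heat-response time budgets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From collar accelerometry to heat-response time budgets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`accbehav` implements a complete analysis chain for studying how free-ranging
ungulates reallocate their behaviour under heat: raw tri-axial collar
accelerometer bursts are classified into behaviours with a gradient-boosted
model, classified records are aggregated into time budgets and
energy-expenditure proxies, and penalized-spline mixed models quantify how
those budgets respond to a blackglobe heat index during the hottest part of
the day and across the 24-hour cycle on hot versus cool days. This vignette
explains each stage's model and assumptions, the tunable parameters and their
defaults, the synthetic-data generator used throughout the tests, and the
numerical and design choices a maintainer should know about.

## Data model

A *burst* is one short continuous tri-axial recording. The deployment design
this package targets records 3.3 s every 5 minutes at 33.3 Hz, i.e. 110
samples per axis per burst; observation collars used for labelling record
6.6 s every 30 s, and `split_long_bursts()` halves those into the standard
geometry. Counts are 12-bit (0–4095) with 2048 representing zero
acceleration and the full range mapping linearly onto −4 G to +4 G
(`counts_to_g()`, 8/4096 G per count). Sample counts per burst are validated
from the data rather than hard-coded, so other geometries work unchanged.

Two delimited-text layouts are supported and must be declared in the
configuration (`burst_dialect()`), never sniffed: a Movebank-style
interleaved column `x1 y1 z1 x2 y2 z2 …` and three per-axis columns. All
timestamps are stored and compared in UTC; a single configurable offset
converts to local solar time, and it is applied exactly once (in
`add_time_fields()`) so hour bins cannot drift between modules.

## Preprocessing

Counts are centred by subtracting 2048. Because a neck collar rotates freely
about the neck axis, the y (sway) and z (heave) components are summarised by
their per-sample plane magnitude `ayz = sqrt(y² + z²)`, which is invariant
under any rotation of the (y, z) pair — the property the test suite asserts
to 1e−9 under random rotations.

Deployment-to-deployment differences in mounting can reverse the surge (x)
and sway (y) axes. `decide_orientation()` compares the per-axis mean of the
training individuals against the mean over an inference individual's whole
dataset and flags an axis for flipping when the signs disagree **and** both
magnitudes exceed a floor (default 100 centred counts, about 0.2 G). The
floor is our own addition: sign comparison alone would flip axes on
near-zero means that carry no orientation information. Orientation is
decided per individual, never per burst, and z is never flipped.

Features are computed on centred raw counts, not G: the unit change is
linear, so it rescales features without reordering them, and raw counts keep
integer arithmetic exact. `counts_to_g()` exists for reporting.

## Burst features

Nineteen features feed the classifier: for each of the two channels (x and
ayz) the time-domain mean, variance, standard deviation, maximum, minimum
and range, plus three frequency-domain descriptors; and one tri-axial ODBA.
Conventions, chosen once and documented because descriptive variants exist:

* **Variance** uses the population (divide-by-N) convention.
* **Spectral features** come from the DFT magnitude spectrum of the
  mean-removed series over bins `1..⌊N/2⌋`. The DC bin is excluded so
  posture (the mean) cannot leak into "main frequency". `freqmain` is the
  frequency of the largest magnitude with ties resolved towards the lowest
  frequency; `freqamp` is that magnitude scaled by 2/N so a pure on-bin sine
  of amplitude A reports A; `entropy` is the Shannon entropy of the
  normalised magnitude spectrum divided by `log(nbins)`, hence in [0, 1] and
  comparable across burst lengths. A spectrum with no dynamic content
  returns (0, 0, 0).
* **ODBA** estimates the static (postural) component of each axis with a
  centred running mean over 22 samples — one fifth of a 110-sample burst,
  0.67 s — and averages the summed absolute residuals of the three axes.
  Edge windows shrink (truncate) rather than pad; padding would
  manufacture spurious dynamic acceleration at the burst ends. Note a
  consequence the tests freeze explicitly: even with `window = n` the edge
  samples never see the whole series, so ODBA is *not* `mean(|x − mean(x)|)`
  under this convention.

Scaling laws tie the set together and are tested: multiplying all counts by
k scales the linear features and ODBA by k, variance by k², and leaves
`freqmain` and `entropy` unchanged.

## Feature selection and classification

`select_features()` performs greedy forward selection with a redundancy
filter: a candidate is admissible only while its absolute Pearson
correlation with every already-selected feature stays below 0.9, and each
step adds the admissible feature with the best cross-validated accuracy when
appended to the current set. The default target is 5 features. A feature's
*contribution* is its accuracy gain over the previous step; the first
feature is credited against the majority-class baseline, a definition we
fixed ourselves (marginal CV gains, not permutation importances), so
baseline + Σ contributions equals the final CV accuracy by construction.

The classifier is a multiclass gradient-boosted tree model (xgboost) with
the stock hyperparameters `nrounds = 10, max_depth = 6, eta = 0.3,
gamma = 0, colsample_bytree = 1, min_child_weight = 1, subsample = 1`,
restricted to the selected features, trained single-threaded for
determinism. We force `tree_method = "exact"`: the newer histogram method
places split points on quantile-sketch boundaries, which for small tabular
feature sets can sit exactly on a cluster edge and misclassify extreme
held-out points; exact greedy midpoint splits are the classical behaviour
for data of this size.

Evaluation offers a stratified 75/25 train/test split (largest-remainder
allocation across classes, so the overall split is exact) and a pooled
5-fold cross-validated confusion report: every burst is predicted exactly
once, counts are pooled into one matrix with observed behaviours in columns
and predictions in rows, and per-class precision and recall accompany the
overall accuracy. The accuracy's 95% interval is a Wilson score interval on
the pooled predictions; pooling (rather than averaging per-fold accuracies)
and stratified folds are our recorded choices. Class imbalance is left
unweighted, accepting weaker performance on minority behaviours.

## Ethogram and consolidation

Twelve behaviours are distinguishable by direct observation: browsing,
drinking, foraging, grazing, grooming, low-activity, ruminating, running,
salt-licking, sleeping, trotting and walking. For the thermal analysis they
consolidate to five categories: foraging (slow food-searching walking) pools
with walking; sleeping and low-activity become resting; drinking,
salt-licking, grooming, trotting and running — collectively a ~2% sliver of
records — are excluded, and `consolidate_records()` reports the excluded
fraction. The map is total and idempotent, and is exported as a two-column
audit table.

## Thermal index and extreme days

Blackglobe temperature integrates air temperature, solar radiation and
relative humidity into a single heat-stress measure. Published estimators
are site-calibrated linear regressions, so `blackglobe()` is pluggable: the
coefficients live in configuration, with defaults (intercept 0.5, 1.35 per
°C air, 0.006 per W/m², −0.002 per % RH) that are this package's own
calibration for a dryland summer regime — midday globe roughly 15 °C above
air under full sun at ~40 °C — and keep the globe at or above air
temperature whenever the sun is up. An identity fallback
(`coefficients = "identity"`) keeps the pipeline runnable without any
calibration and announces itself in the log. Absolute blackglobe values are
never asserted in tests; only structure (monotonicity, vectorisation,
bounds) is.

Hot and cool days are defined by daily maximum air temperature within the
hot-season window (October–December by default): the 10 hottest and 10
coolest dates, ties resolved towards the earlier date so selection is
deterministic. The two sets are disjoint by construction.

## Budgets and mean-ODBA cells

Each classified burst is one 5-minute tick, so "proportion of time" is the
proportion of records — the only reading consistent with the fixed burst
schedule. Records gain the blackglobe value of the nearest weather record
within a 30-minute tolerance (unmatched records are dropped and counted),
and local hour/month fields. The afternoon analysis keeps hours 12–17
(12:00–17:59). Budget cells are keyed by integer blackglobe °C (floor
binning, so boundaries are reproducible), hour, month and individual; all
five category proportions are reported per cell and sum to one. Mean-ODBA
cells additionally require at least 30 recordings (100 s of measurement) —
sparsely-visited temperature-hour combinations drop out, which at small
simulated scales can leave entire behaviours without fittable ODBA
batteries; `run_analyze()` then skips those models with a message rather
than fitting nonsense.

## Penalized-spline mixed models

Two model families, both penalized regression splines with REML smoothing
selection (mgcv) and random intercepts per individual:

* **Afternoon heat response** (`fit_heat_model()`): response ~ species +
  s(blackglobe, by species) + s(hour, by species) + month + (1 |
  individual). With one species the by-terms collapse. Proportions are
  modelled on the logit scale with a quasibinomial variance and cell sizes
  as weights; mean ODBA with identity link and constant variance — the
  response families are our own choices and are recorded in the report
  header. Month enters as a factor: with three levels a smooth would be
  degenerate. Basis dimensions default to k = 10 for blackglobe (reference
  df 9) and k = 8 for hour, capped automatically at the number of distinct
  covariate values.
* **Diel hot/cool comparison** (`fit_diel_model()`): response ~ dayclass +
  s(hour) + s(hour, by ordered(dayclass)) + (1 | individual) with a cyclic
  cubic basis for hour (knots spanning 0–24 so the day wraps at midnight).
  The ordered-factor difference smooth isolates a change in diel *shape*
  (its approximate p-value is the interaction test) while the parametric
  day-class coefficient tests a shift in the 24-h *mean* (the intercept
  contrast). The reported percentage difference of 24-h means is the ratio
  of model-predicted means over an hourly grid with random effects excluded
  — ratio of means, not mean of ratios.

Worst-case concurvity (the nonlinear analogue of collinearity, in [0, 1])
is attached to every fit; covariate smooths at or above 0.8 trigger a
warning. Random-intercept smooths are excluded from the warning because
they overlap the parametric intercept by construction and sit at 1
trivially. Significance is read at α = 0.05 with no multiple-testing
correction across the behaviour × response battery — a deliberate mirror of
common practice in this literature, and a caveat to keep in mind.

Degenerate inputs are refused loudly: fewer than 20 cells, a single day
class, fewer than 12 distinct hours, or missing blackglobe coefficients all
raise errors naming the problem.

## The synthetic-data generator

Because the field data (collar archives and station weather) are external,
every stage is exercised against a generator whose defaults encode the
study conditions: 110-sample bursts at 33.3 Hz; one burst every 5 minutes
(288 ticks per day); hot-season days whose daily maximum air temperatures
fall in 26–32.4 °C (cool) or 39.1–40.6 °C (hot) with a 14 °C sinusoidal
diel cycle peaking at 14:00; and behaviour allocation per tick from a
multinomial over the 12-behaviour ethogram.

Burst waveforms are phenomenological: a static posture vector, one periodic
component and Gaussian noise per behaviour — the minimum structure that
drives every feature (posture → means, gait → main frequency and amplitude,
irregularity → entropy, intensity → ODBA). No biomechanical realism is
claimed. A physical constraint shaped the defaults: a motionless collar
always reports |ayz| ≈ 1 g, so quiet behaviours can only be told apart by
collar tilt and noise level; the default postures (sleeping = neck-curled
tilt, drinking = deep head-down) were set so all twelve classes are
pairwise distinguishable (between-class silhouette above 0.5 on the
z-scored 19-feature space, asserted in the tests).

Behaviour weights vary by hour (crepuscular grazing, diurnal browsing,
nocturnal resting, a ~2% pool of rare behaviours) and respond to blackglobe
temperature through per-behaviour log-odds slopes relative to a 45 °C
reference; the defaults suppress grazing (−0.05 per °C) and mildly favour
rumination and low activity, the qualitative heat response expected of
dryland antelope. A first-order persistence term (probability 0.3 of
repeating the previous tick's behaviour) adds the serial dependence real
records have; the quasibinomial variance in the budget models absorbs the
resulting extra-binomial dispersion, which is why the type-I simulations
stay near nominal. Scenario constructors plant specific truths:
`scenario_null()` (no temperature effect), `scenario_diel_compensation()`
(hot-day daytime grazing suppression exactly repaid at night — interaction
without intercept shift) and `scenario_diel_reduction()` (hot-day grazing
scaled by a factor at every hour — e.g. a planted −20% 24-h mean).

Tick-level records carry an ODBA value drawn from a behaviour-specific
gamma distribution whose means are part of the emitted ground truth; full
waveform synthesis per tick is available (`signals = TRUE`) and is used
where the classifier is in the loop, but the model-recovery simulations run
on ticks directly since the classifier's fidelity is established separately
(cross-validated accuracy ≥ 0.95 at default signal-to-noise). Ground-truth
parameters are always returned next to the data; recovery tests never reach
into the generator's internals.

What the generator does **not** emulate — and hence what passing tests do
not show about field data: real gait harmonics and transitional bursts that
straddle behaviours, individual-specific signal idiosyncrasies, classifier
error correlated with behaviour context, weather fronts and within-day
weather noise, and missing data. Recovery results here demonstrate that the
pipeline's statistics work when their assumptions hold, not that any
particular field effect size is reproducible.

## Problem sizes and numerics

The test and acceptance workloads were sized for a single CPU: a 2 040-burst
training fixture (170 per behaviour); heat-model recovery on 3 individuals
× 30 days (50 planted + 100 null simulations); diel recovery on 4
individuals × 20 days (50 seeds per scenario); 200 direct-cell null fits
for the p-value calibration check; and 100 random bursts for the ODBA
oracle. Tolerances: exact integer centring; 1e−9 for ODBA-oracle agreement
and rotation invariance; spectral assertions to within one DFT bin width
(fs/n ≈ 0.30 Hz). Frequency ties break to the lowest bin; extreme-day ties
break to the earlier date; basis dimensions cap at the number of distinct
covariate values.

## Known limitations

* The blackglobe defaults are a plausible calibration, not a site fit;
  absolute thermal values should come from local regression coefficients.
* Proportions are pooled across days within an hour bin before modelling;
  a per-day budget with day-level random effects would be the natural
  sensitivity analysis.
* The orientation rule (sign-with-floor on axis means) is the simplest
  operationalisation of training/inference mean comparison; deployments
  with genuinely ambiguous mounting need manual review of the audit file.
* Minority behaviours are classified with lower fidelity (unweighted
  training) and are excluded or pooled downstream; inference about rare
  behaviours is out of scope.
* No multiple-testing correction is applied across model batteries.
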