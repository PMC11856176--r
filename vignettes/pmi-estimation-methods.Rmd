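---
title: "Estimating minimum post-mortem intervals from insect development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating minimum post-mortem intervals from insect development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmintr)
```

## The problem

Classical pathology estimates of the time of death (livor, algor, rigor
mortis) lose reliability after roughly 48–72 hours. For longer
decomposition periods, forensic entomology offers a different bound: the
blowflies that colonize remains develop at temperature-predictable rates,
so the developmental stage of the oldest insects found on a body dates the
earliest colonization. That date is the **minimum post-mortem interval
(PMI-min)** — death occurred no later than first oviposition, and usually
somewhat earlier, by the **pre-colonization interval (PCI)**.

`pmintr` implements the full estimation chain:

1. **Scene-temperature retrodiction.** A data logger placed at the scene
   after discovery records hours-to-days of concurrent scene and
   weather-station temperatures; a correction model fitted to this pairing
   retrodicts the unobserved scene temperatures over the pre-discovery
   window.
2. **Thermal-summation development.** Accumulated degree hours (ADH),
   $\sum_h \max(T_h - T_{base}, 0)\,\Delta t$, drive stage transitions at
   fixed thresholds; development time to a stage at constant $T$ is
   $\mathrm{ADH}_{stage} / (T - T_{base})$.
3. **Back-calculation.** Walking backward from the collection time,
   consuming the observed oldest stage's entry threshold, yields the latest
   oviposition time compatible with the evidence, plus every intermediate
   stage entry.
4. **PCI adjustment and discrepancy.** A published minimum PCI, matched by
   species and temperature band, extends the death-time bound earlier; the
   signed gap against an external last-known-activity reference is reported
   at the reference's own granularity.

## Temperature correction models

Two model families map hourly station temperature to scene temperature:

* **Quadratic regression** `scene = a + b·station + c·station²`, fitted by
  least squares (`fit_quadratic()`). Simple, interpretable, and exact when
  the true relation is polynomial.
* **Epsilon-SVR with an RBF kernel** (`fit_svr()`), able to absorb
  covariates — humidity, wind speed, rainfall — whose effects a univariate
  quadratic cannot represent. Features are z-standardized with
  training-window statistics. Hyperparameters default to `cost = 10`,
  `epsilon = 0.1` (°C, the half-width of the insensitivity tube, of the
  same order as the logger's ±0.5 °C accuracy) and
  `gamma = 1/n_features` on standardized features; published uses of these
  models for scene retrodiction do not report values, so the defaults are
  conventional ones that behave well on hourly series of this size. They
  are configuration, not constants.

Both fitters require **at least 48 paired hourly rows** — two days of
records at one-hour intervals, the minimum recommended for reliable
retrodiction — and refuse gappy or irregular series rather than
interpolating silently.

Models are compared by mean absolute difference (MAD) and root mean square
error (RMSE). Because the validation scheme behind published comparisons is
unstated, the package defaults to **5-fold blocked cross-validation** over
contiguous hour blocks (time-series aware: folds are never interleaved
hours), with plain in-sample residuals available via `cv = FALSE`.
`select_model()` picks the lowest RMSE, breaking ties by lower MAD and then
by preferring the simpler quadratic. RMSE ≥ MAD holds mathematically for
any error vector and is asserted throughout the test suite rather than
assumed.

When only a scalar corrected mean is available for a case — the usual
situation, since the pre-discovery scene record cannot be republished —
the pipeline runs in constant-temperature mode; when an hourly corrected
series is supplied it always wins over the scalar.

## The development engine

`development_dataset()` stores per-species ADH thresholds **cumulative from
oviposition to stage entry** (not per-stage increments); this makes the
backward walk a single threshold consumption and keeps increments
derivable. Conventions that matter numerically:

* Temperatures are treated as constant over each hour block (the logger's
  recording interval); fractional first/last hours prorate linearly.
  `adh_accumulate()` is therefore exact for its piecewise-constant input,
  and the tests check it against a 1-second Riemann oracle.
* **Closed-left boundaries**: an individual exactly at a threshold has
  entered the stage (`stage_at()`), with a 1e-9 degree-hour tolerance
  absorbing float drift.
* The backward inversion returns the **latest** oviposition time when
  zero-accumulation stretches (temperatures at or below base) make the
  solution non-unique — the conservative choice for a *minimum* interval.
* Under constant temperature the general path reduces exactly to
  `at − threshold/(T − T_base)`, and the tests assert this closed form
  against the block-walking implementation.
* Maggot-mass heating is deliberately not modelled; it is listed among the
  report caveats instead.

Thresholds may be derived from constant-temperature rearing tables
(`thresholds_from_constant_table()`): `ADH = hours × (T − T_base)`, with
per-stage spread across rearing temperatures reported as a consistency
diagnostic — a large spread means the data reject a single linear ADH law.

### Base temperature and case calibration

The three packaged Busan cases print stage-boundary timestamps but no base
temperatures, and their implied durations at the two case temperatures are
mutually inconsistent with any single ADH law (e.g. third-instar entry for
*L. sericata* implies 83 h × 18.9 °C = 1568.7 ADH at one scene and
145 h × 11.6 °C = 1682 ADH at another above a 10 °C base). The package
therefore ships **one calibrated dataset per case per species**, each
derived from the case's printed durations at its corrected mean
temperature. With this construction the case arithmetic is insensitive to
the chosen base (duration × (T − base) appears identically on both sides);
10 °C is used as a conventional value for both species. The dataset files
are labelled synthetic stand-ins in their provenance strings — they are
calibrations to published case timelines, not re-derivations of the
underlying rearing studies.

Two of the published timelines are internally inconsistent, and the
fixtures document rather than repair this: the first case's stage intervals
sum to 10 d 3 h against a narrative total of "about 10 d 1 h" (and its
first-instar interval starts before the egg interval ends); the third
case's intervals sum to 14 d 0 h against "about 14 d 8 h". The calibrated
laws follow the printed stage-boundary timestamps, which are
self-consistent, so the pipeline reproduces the printed PMI-min timestamps
exactly; the narrative totals are treated as rounded prose.

## Reference species and PCI

With several species on a body, `select_reference_species()` picks the one
whose development to its observed oldest stage takes **longest** at the
scene mean temperature: the slowest developer must have arrived earliest,
giving the most conservative colonization bound (ties break
alphabetically). In the packaged cases this selects *L. sericata* over the
faster *C. megacephala* at both 28.9 °C (83 h vs 46 h to third instar) and
21.6 °C.

`apply_pci()` matches rules by species **and** temperature band. The
shipped rule — minimum PCI of 0.2 day for adult *L. sericata* between 14.0
and 25.1 °C — fires for the third case (21.6 °C) but not the second
(28.9 °C). The adjusted quantity is interpreted as the **residual gap**
against the external reference: a 1-day gap becomes
24 h − 0.2 × 24 h = 19.2 h, which the package reports exactly (the
published rounded figure is "approximately 20 h"); the death-time bound
itself moves 4.8 h earlier. This is the only arithmetic consistent with a
0.2-day PCI and a 1-day discrepancy. Overlapping rules that disagree are a
configuration error; a 0.2-day rule outside its band, or a 0-day rule
anywhere, leaves the estimate unchanged.

Discrepancies honour the reference's declared granularity, which is an
explicit field and never inferred from formatting: minute-precision
references (a timestamped receipt) give differences in hours; date-only
references (a phone record's day) give whole calendar-day differences, so a
bound at 03:50 on the 9th against a reference on the 7th is 2 days
regardless of clock time.

## The synthetic-data module

`scenario_config()` + `gen_station_series()` / `gen_paired_series()` /
`gen_case()` generate every input with known ground truth:

* Station temperature is a **single 24 h sinusoid** (afternoon peak) plus
  optional Gaussian noise. The emulated cases span under a month indoors,
  so no seasonal trend is included; the default 21.5 ± 3.6 °C outdoor
  cycle feeding a damped 24.5 ± 0.8 °C indoor scene mirrors the reported
  early-autumn conditions, and scene noise defaults to the logger's 0.5 °C
  accuracy.
* Rainfall is zero-inflated exponential, default dry (the emulated cases
  record none); humidity and wind come from clipped/folded normals.
* The scene is the configured quadratic-plus-covariate transform of the
  station series; the noise-free truth rides along as an attribute so
  recovery tests need no second bookkeeping path.
* `gen_case()` places colonization at `death + PCI`, develops insects
  forward along the noise-free scene series, and assembles a `pmi_case`.
  By default the collection time **snaps to the entry time of the oldest
  stage reached**: the PMI-min convention dates that stage's entry at
  collection, so snapping isolates back-calculation error from the
  censoring introduced by sampling mid-stage. With `snap = FALSE` the raw
  sampling time is kept and the estimate is late by exactly the time since
  stage entry — useful for studying that censoring, which in real cases is
  an unavoidable conservatism of the method.

All generators are bit-reproducible under the config seed, and generated
scenarios satisfy the preconditions they feed (≥ 48 paired rows, series
coverage).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: aggregation-driven maggot-mass heat, weather
front passages and other non-sinusoidal temperature structure, mixed
ovipositing cohorts, species succession, and measurement gaps. Recovery
results on synthetic scenes are a check of the estimation machinery, not a
field validation.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use sizes chosen to exercise
every code path while staying desk-fast: 72–144-hour paired windows for
model fitting, 100 seeds for the coefficient-coverage check, 50 seeded
zero-noise scenarios (10-day series, 15–30 °C means) for end-to-end
colonization recovery, and a 6-day rainy scenario (96 training / 48
held-out hours) for the SVR-vs-quadratic comparison. The whole suite runs
in well under a minute.

## Known limitations

* Thermal summation is linear; no curvilinear degree-day models.
* Datetimes are timezone-naive local times at minute precision, without
  DST handling — adequate for casework spanning days to weeks, not for
  transitions across clock changes.
* The case-calibrated development files are fixtures for reproducing the
  packaged investigations; real casework should load thresholds derived
  from the primary rearing literature for the local population.
* PCI adjustment uses published minima as point values; no uncertainty is
  propagated.
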