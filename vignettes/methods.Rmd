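---
title: "Methods: cold-hardiness dynamics, freeze damage, and budbreak prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cold-hardiness dynamics, freeze damage, and budbreak prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The modelling framework

`budfreeze` predicts grapevine budbreak from bud *cold hardiness* dynamics
rather than from a classical chilling/forcing sum. Cold hardiness (CH) is the
lethal temperature of the bud population, tracked per population percentile
(CH10, CH50, CH90 — the lethal temperatures of the least hardy 10%, the
median, and the hardiest tail). The daily update is

    CH(d) = CH(d-1) - gain(d) + loss(d)

where `gain` (acclimation) deepens hardiness in response to cold nights and
`loss` (deacclimation) erodes it in response to warmth, gated by the state of
dormancy. Budbreak is predicted on the first day the *projected* CH50 —
allowed to run past the hardiness of living green tissue into positive lethal
temperatures — crosses a cultivar- and observation-convention-specific
threshold (+10 °C for Cabernet-Sauvignon and Riesling, +5 °C for Concord
under 50%-of-buds BBCH 07 observations; +5 °C / 0 °C adjustments for
BBCH 05 conventions). Because the framework carries the whole hardiness
trajectory, it simultaneously yields freeze-damage detection, survivor
corrections, and frost-risk indicators — quantities a pure thermal-time
phenology model cannot express.

### Chill submodel

Dormancy state is driven by chill portions from the Dynamic Model: a
two-intermediate chemical analogy in which a thermolabile precursor forms at
low temperatures, is destroyed at warm temperatures, and — once its pool
reaches a threshold — is banked irreversibly as a portion, scaled by a
temperature-dependent transfer probability. We implement the canonical
published rate constants verbatim (`dynamic_model_constants`), convert
°C to K inside the step, and bank-and-reset in the same branch as the
standard horticultural implementations (verified against an independently
coded reference; golden values are frozen in the test suite). At constant
temperature the portion rate is unimodal with its optimum near 7.5 °C; the
phase-shift experiments displace the submodel's input (`T - s`), which by
exact equivariance moves the optimum to `7.5 + s`.

Hourly temperatures are derived from daily minima/maxima by the
sine-day/log-night scheme: daytime follows
`tmin + (tmax - tmin) * sin(pi (h - sunrise) / (daylength + 4))`, night
declines logarithmically from the sunset temperature to the next morning's
minimum, with day length from standard solar declination geometry.
Latitudes beyond 66.6° (polar day/night) are rejected.

### Hardiness engine and its parameters

The original model's supplement equations and fitted parameter values were
not available to this implementation; the packaged table
(`inst/extdata/nyus1_parameters_synthetic.csv`, `source = "synthetic"`) is a
**synthetic stand-in** constructed once to satisfy every documented
behavioural contract, and the functional forms below are this package's own:

* **Deacclimation potential** `plogis(dp_slope (chill - dp_mid))`: ≈0 at
  zero chill (a warm spell in deep dormancy costs nothing), ≥0.95 by
  ~150 portions. `dp_mid` (portions) is the chill requirement midpoint;
  lower for the Northern hybrid Concord (45) than for Cabernet-Sauvignon
  (55).
* **Acclimation gain** `acc_rate * max(0, thr(chill) - tmin) * capacity`,
  with threshold `thr = acc_t0 - acc_t1 * chill/(chill + acc_tk)` declining
  as chill accumulates (colder nights needed late in winter), and
  `capacity = (CH - ch_max)/(0 - ch_max)` clipped to [0, 1] so gain
  vanishes at the maximum-hardiness bound `ch_max` (< 0 °C; deepest for
  Concord, shallowest for Cabernet-Sauvignon).
* **Deacclimation loss** `potential * (r(tmin) + r(tmax))/2` with
  `r(T) = deacc_rate * plogis(deacc_b (T - deacc_mid))` — two half-day
  contributions at the daily extremes. `deacc_rate` (°C/day) ranks
  Concord (3.0) > Riesling (2.0) > Cabernet-Sauvignon (1.6), the documented
  deacclimation-rate ordering.

Within a day the order is: chill first (hourly), then gain and loss from the
previous day's CH, then clamping (`max` at the bound, `min` at the spring
floor in bounded mode — no reflection). Percentile sets within a cultivar
share rate parameters and differ in `ch_max`/`ch_init`; this guarantees the
daily ordering CH10 ≥ CH50 ≥ CH90, which `simulate_all_percentiles`
enforces as a hard error.

The *spring floor* caps bounded-mode trajectories at the minimum hardiness
of growing green tissue. Published controlled freeze tests on newly emerged
shoots span 0 to −4 °C; defaults are (−1, −2, −3) °C for percentiles
(10, 50, 90) and are configuration (`spring_floor()`), not fitted truth.

### Freeze damage and survivor correction

A freeze event is a day with `tmin` **strictly** below the bounded CH10
(equality is no event: at `tmin == CH10` the interpolation returns exactly
the 10% nominally at the threshold, which the percentile representation
already carries). Percent damage of the existing population interpolates
linearly between quantile anchors:

* `10 + 40/(CH50-CH10) * (tmin - CH10)` for `CH50 <= tmin < CH10`,
* `min(50 + 40/(CH90-CH50) * (tmin - CH50), 90)` below CH50,

continuous at the seam and capped at 90 (the hardiest decile is treated as
a censored survivor tail — the population reading under which the cap is
exact, mirrored by the Monte-Carlo oracle in the tests). Survivor
percentiles re-read the old quantile curve at position
`d + p (100 - d)/100`; the CH50 and CH90 updates use the 50–90 segment
slope, CH10 uses the 10–50 segment for `d <= 50` and the 10–90 chord above
(tie at `d = 50` to the first branch). For `d` in [10, 80] the CH50 update
is *exactly* the survivor-median of the piecewise-linear population model;
the CH10 chord deviates from the segmentwise reading for `d` above ~44
(where the survivor 10th percentile crosses the old median) — we keep the
published chord form rather than "fixing" it. Ordering and hardening of the
adjusted percentiles are guaranteed when the two percentile gaps are within
about a 5:1 asymmetry, the regime the engine actually produces; extreme
asymmetric spreads can invert the adjusted values, a property of the chord
equations noted here and excluded from the randomized sweeps.

Events adjust both the bounded states (used for risk) and the projected
states (used for budbreak); detection always uses the bounded trajectory,
since projected values rise through spring air temperatures by
construction. Adjustment only deepens hardiness, so events after the
corrected crossing cannot move it — which implements the rule that only
pre-budbreak damage delays budbreak, while later spring events remain
recorded. Multiple events, including consecutive days, are all processed
against the population existing immediately prior; the cumulative surviving
fraction multiplies by `1 - d/100` per event. A degenerate percentile
spread (equal values) is a hard error.

### Risk indicators and evaluation

The daily safety margin is `tmin - CH50` on the damage-adjusted bounded
trajectory; days with margin ≤ 0 are freeze-risk days (boundary included,
per the indicator sum), margins in (0, 2] are near misses. Mean
dormant-season temperature (MDST) averages 1 Nov–30 Apr; the daily value is
`(tmin + tmax)/2` by default (`method = "hourly"` averages the interpolated
hours instead — the source text says only "average temperature", and
midpoint is the daily-resolution convention). MDST risk bands break at 1, 3
and 8 °C with boundaries owned by the lower band (ownership is not stated
anywhere; a choice had to be fixed). Evaluation reports bias (mean of
predicted − observed), RMSE, and r² as the squared Pearson correlation
(an explicit `r2_method = "ss"` flag gives 1 − SSE/SST); segmented MDST
sensitivity uses per-segment ordinary least squares on [−1, 3], (3, 10],
(10, 12] — the segment boundaries "3.01"/"10.01" in the source analysis
imply half-open intervals — in place of restricted-cubic-spline machinery.

### The synthetic world

`generate_weather()` emits daily means as a seasonal sinusoid (coldest at
`coldest_day_doy`, default mid-January) plus stationary AR(1) noise
(ρ = 0.7, sd = 3 °C): autocorrelated multi-day spells are what create
realistic chill totals, deacclimation runs and freeze events; independent
daily noise would not. `tmin`/`tmax` sit a constant half diurnal range
(default 8 °C) below/above the mean. The generator deliberately omits
weather fronts, skewed minima, seasonal diurnal modulation and spatial
structure — so a green end-to-end test establishes internal consistency of
the pipeline on a plausible climate, not skill on real station records.
`calibrate_spec_for_mdst()` solves the deterministic part in closed form so
target MDSTs from −1 to 12 °C (the study's site range) can be swept.
Synthetic observations are model predictions plus rounded Gaussian noise
(observations are daily), skipping failed predictions. All randomness is
seeded; generation restores the caller's RNG state.

### Numerical conventions and degenerate inputs

* Budbreak crossing is first day at-or-above threshold (≥), daily
  resolution; `FAILED` (no crossing by 30 June) is a recorded outcome, not
  an exception.
* Seasons are fixed 1 Jul–30 Jun Northern-Hemisphere windows; Southern
  latitudes and gaps inside a season are hard errors (the integration is
  stateful; no imputation).
* Leap days are retained; DOY is the calendar day of year of the spring
  year.
* Concord has no published BBCH 05 threshold adjustment; requesting one is
  an error rather than a silent fallback.
* The chill constant-temperature response is unimodal only up to the
  discrete portion-banking quantization (~one bank); tests assert
  unimodality with exactly that tolerance.

### Known limitations

The parameter table is synthetic: absolute hardiness levels, budbreak dates
and event frequencies are realistic in pattern but not validated against
any field record, and none of the published headline statistics are
reproduced here — the pipeline computes all of them (`fit_stats`,
`damage_confusion`, `phase_shift_experiment`, `sensitivity_slopes`) and
will deliver comparable numbers only when driven by the original multi-site
weather and phenology records. Carry-over of damage between seasons,
tissue-specific damage, and alternative chill metrics are out of scope.
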