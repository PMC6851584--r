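---
title: "Methods: winter climate-change indicators and their trend statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: winter climate-change indicators and their trend statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wintertrends)
```

## The scientific problem

Winter in the seasonally snow-covered forests of northeastern North America
is changing faster than the annual mean climate, and many of its ecological
and economic consequences hinge on threshold behaviour rather than on mean
temperature: whether a night kills an overwintering insect, whether the
ground is bare when a hard freeze arrives, whether rain falls on an existing
snowpack, whether a ski area can make snow before the holidays. This package
computes a suite of threshold-based winter indicators from daily station
weather and tests their long-term trends with rank-based statistics that
make no distributional assumptions about the counts.

The pipeline is: daily station records → completeness screening and snow
gap-filling → degree-day snow-water-equivalent (SWE) simulation → per-winter
indicator counts → site and regional nonparametric trend tests → subregional
summaries. A seeded synthetic weather generator stands in for archive data
so that every stage can be validated against known ground truth.

## The winter window and the indicator suite

A winter runs from 1 November to 31 May — the dormant season between autumn
senescence and spring leaf-out — and is labeled by its ending calendar year
(November 2000–May 2001 is winter 2001). The ending-year label was chosen
because it is unambiguous and monotone in time; nothing downstream depends
on the label beyond its role as the trend time axis. The window is 212 days,
213 when the ending year is a leap year; 29 February is an ordinary winter
day.

The day classifications, all strict inequalities:

| Indicator | Definition | Inputs |
|---|---|---|
| Thaw day | Tmax > 0 °C | Tmax |
| Ice day | Tmax < 0 °C | Tmax |
| Frost day | Tmin < 0 °C | Tmin |
| Extreme cold / pine beetle kill day | Tmin < −18 °C | Tmin |
| Hemlock woolly adelgid kill day | Tmin < −30 °C | Tmin |
| Snowmaking / mosquito kill day | Tmin < −5 °C | Tmin |
| Snow covered day | SWE > 0 mm | SWE |
| Bare ground day | SWE = 0 mm | SWE |
| Rain-on-snow day | rain > 0 mm and SWE > 0 mm | Tmin, Tmax, prcp, SWE |
| Bare ground ice / frozen ground day | Tmax < 0 °C and SWE = 0 mm | Tmax, SWE |
| Bare ground thaw / mud day | Tmax > 0 °C and SWE = 0 mm | Tmax, SWE |

Snowmaking days are additionally counted within two cumulative ski-season
windows: before 25 December and through 28 February. The sources that
motivate these windows say "before" and "prior to" without fixing the
boundary day, so the package adopts and documents one convention — 25
December excluded, 28 February included (29 February never counts) — and
exposes both boundaries in `threshold_config()`. Because a day at exactly
0 °C is neither a thaw day nor an ice day, thaw + ice + (days with Tmax
exactly 0) partitions the Tmax-defined days of a winter; this partition is
one of the invariants the test suite checks on random winters.

Counts are raw day counts, never rescaled to a standard winter length:
rescaling would silently change Sen slopes. A count whose required inputs
were missing all winter is reported as missing, never as zero, and every
count carries the valid-day denominator of its input set.

## The degree-day snow model

Snow-depth archives in this region are short and riddled with the
"unreported zero" pathology (observers leaving the field blank when no snow
is on the ground), so all snow-dependent indicators use modeled SWE instead
of observed depth, simulated over the entire record from temperature and
precipitation. The model is a daily temperature-index water balance driven
by `tavg = (tmin + tmax)/2` — the only temperatures daily archives provide:

* phase: precipitation is all snow at or below `t_snow`, all rain at or
  above `t_rain`, linearly mixed between (rain + snow = precipitation
  exactly);
* melt: `ddf · max(0, tavg − t_melt)`, capped at the available SWE;
* liquid store: melt and rain are retained in the pack up to
  `retain_frac · swe`, the excess leaves as runoff;
* refreeze: stored liquid refreezes at `refreeze_factor · max(0, t_melt −
  tavg)`.

Defaults — `t_snow = 0`, `t_rain = 2`, `t_melt = 0` °C, `ddf = 2.5`
mm °C⁻¹ d⁻¹, `retain_frac = 0.05`, `refreeze_factor = 1` mm °C⁻¹ d⁻¹ —
are central literature values for daily temperature-index models in
seasonal-snow climates. All are configurable, and `calibrate_snow_params()`
offers an exhaustive grid search that scores candidates by day-wise
agreement of snow presence (observed depth > 0 versus modeled SWE > 0),
breaking ties toward the defaults so that an uninformative record (for
example, a snow-free summer where every candidate scores 1) never pulls
parameters away from sensible values.

Three numerical properties are enforced by construction and verified by
test: exact mass balance (the change in `swe + liquid_store` equals
snow + rain − runoff each day, to floating-point round-off), non-negativity
of both stores, and monotonicity of SWE in `ddf` up to accumulated float
noise (the tests allow 10⁻⁹ mm). The pack is reset to empty at each
1 August so winters never inherit a phantom pack across snow-free summers
and results are independent of where a record begins. A day with missing
temperature or precipitation carries the state forward unchanged and is
flagged undefined; its SWE is treated as missing by the classifiers.
"Snow covered" means modeled SWE strictly greater than 0 mm; a trace cutoff
is exposed as `snow_cover_mm` for sensitivity analyses.

## Quality control and snow gap-filling

A winter is usable for a variable if its missing fraction over the full
window (days absent from the record count as missing) is at most 10%, a
common climatological completeness rule; a station is retained if at least
`min_valid_winters` (default 90) winters are usable for temperature and/or
precipitation, an inclusive bound that encodes the preference for
century-scale records in trend detection. Both thresholds are configuration,
not constants.

Snow gap-filling applies three conservative repairs: missing snowfall
becomes zero on dry days (or warm days with missing precipitation); a run of
consecutive missing depth days of length ≤ k (default 7) flanked by observed
zeros is filled with zeros; a run ≤ k flanked by positive observations is
linearly interpolated. The rules act on maximal gap runs against observed
flanking values — a per-day "zero within k on both sides" rule was
considered and rejected because fills would enable further fills on
reapplication, breaking idempotence; the run-based rule is idempotent, which
the tests verify on randomly punctured series. Mixed-flank runs, runs longer
than k, and runs touching the record ends stay missing; observed values are
never altered, and every fill is flagged. Gap-filled depth is used only for
snow-model validation/calibration; indicator snow status always comes from
modeled SWE. Duplicate dates are reported by `validate_series()` and refused
by every downstream stage: the upstream archives give no rule for resolving
conflicting reports, so the package does not guess. Rows with
`tmin > tmax` are quarantined (both temperatures set missing) rather than
swapped, because swapping would fabricate data.

## Trend statistics

Site-level trends use the Mann-Kendall test with the tie-corrected variance
and continuity-corrected normal deviate,

$$S = \sum_{i<j} \mathrm{sign}(x_j - x_i), \qquad
\mathrm{var}(S) = \frac{n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)}{18}, \qquad
z = \frac{S - \mathrm{sign}(S)}{\sqrt{\mathrm{var}(S)}},$$

with a two-sided normal p value, and the Sen slope — the median of all
pairwise slopes — reported in days per decade. The normal approximation is
used throughout (no exact small-sample tables): the series of interest have
on the order of 100 points, where the approximation error is negligible; a
floor of n ≥ 4 returns an insufficient-data result instead of a test.
Missing winters are omitted pairwise on the true year axis, so slopes use
real year gaps. Constant series are reported as S = 0, z = 0, p = 1.

Serial correlation is screened with sample autocorrelations up to lag 30
years (the length of a climate normal), flagging a series when any
coefficient leaves the ±1.96/√n band. The flag is advisory — reported
alongside the test, never blocking it, and no prewhitening is applied —
mirroring the workflow this pipeline reproduces, where the screen found no
violations and the tests proceeded unadjusted.

Regional verdicts use the blocked (regional) Kendall test with station as
the block: block S and tie-corrected variances are summed, assuming no
correlation between blocks, and the regional Sen slope is the median of the
pooled within-block pairwise slopes (×10 for per-decade units). Pooling the
slopes, rather than taking a median of block medians, follows the standard
regional-Kendall convention; with a single block the regional test reduces
exactly to the site test, which the suite asserts. Blocks with fewer than 4
usable winters are skipped.

Subregions partition the longitude line at 87° W and 78° W. The sources do
not say which side the boundary meridians fall on; here each boundary
belongs to the more eastern class (−87° is central, −78° is east), a
declared convention exposed as `west_bound`/`east_bound`. Summaries report,
per indicator and subregion, the number of significantly positive and
negative sites (α = 0.05 by default), the median and range of Sen slopes
over significant sites only, the regional slope with its significance, and
the long-term median and range of station-median annual counts.

No multiple-testing correction is applied across the twelve indicators, and
no seasonal Kendall blocking is used (counts are annual): both choices
deliberately reproduce the workflow the pipeline implements.

## The synthetic weather generator

`generate_daily_series()` emulates exactly the statistical structure the
downstream tests need and no more:

* a sinusoidal seasonal cycle in daily mean temperature with a 365.25-day
  period evaluated on real calendar day-of-year, so the coldest day stays
  aligned across leap years;
* AR(1) day-to-day noise (stationary sd `noise_sd`, lag-1 correlation
  `ar1`, initialised from the stationary distribution) shared by Tmin and
  Tmax — perfectly correlated deviations keep Tmin ≤ Tmax by construction
  without rejection sampling, which is adequate for testing threshold
  counters;
* independent linear trends on Tmin and Tmax in °C per decade;
* wet days as Bernoulli(`p_wet`) with Gamma amounts, independent of
  temperature except through phase partitioning;
* snowfall recorded as the snow component of the phase partition at a 10:1
  fresh-snow ratio (mm solid);
* values rounded to the 0.1 °C / 0.1 mm resolution of daily archives, so a
  generated series survives a write/read round trip bit-identically and
  file-based runs reproduce in-memory runs exactly.

Defaults (mean 5 °C, amplitude 15 °C, coldest day 15 January, diurnal range
8 °C, noise sd 4 °C, ar1 0.6, wet-day probability 0.35, Gamma(0.7, scale 8)
amounts) describe a generic cold-temperate mid-latitude station whose winter
Tmin distribution straddles the 0, −5 and −18 °C thresholds, so all
indicator counters are exercised. The generator spans whole hydrological
years (1 August to 31 July), giving exactly `n_years` complete winters.
`inject_missingness()` adds geometric-length missing blocks per variable to
a target fraction and can blank every true-zero snow-depth day (the
unreported-zero pathology).

What the generator does *not* emulate — spatial correlation between
stations, temperature-dependent precipitation occurrence, weather regimes
beyond AR(1), inhomogeneities, instrument changes — bounds what passing
tests can show: they validate the statistical machinery (counting,
screening, trend detection, regional blocking) on data whose ground truth
is known, not the climatology of any real station network. Archive data
carry inhomogeneities that this package deliberately does not adjust
(it consumes already-homogenised products).

Every stochastic choice is seeded. In pipeline runs a single global seed
fans out to per-station substreams keyed by the station id, so adding a
station never perturbs the weather of the others — a property the test
suite asserts and that keeps regression tests stable.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` recompute, at run time:

* exact agreement of S and the Sen slope with brute-force double-loop
  oracles on 500 random short tied series, plus closed-form cases
  (x = 1…10 gives S = 45, var 125, z = 44/√125; two identical 5-point
  blocks give S = 20, var 100/3);
* the empirical type-I error of the test at α = 0.05 on 2000 white-noise
  series of 100 winters, checked against the [0.035, 0.065] band implied by
  the normal approximation plus Monte-Carlo error;
* recovery of an injected frost-day trend: the Tmin warming equivalent to
  −1.5 frost days per decade is derived in closed form by
  `frost_slope_to_tmin_trend()` (each day's frost probability is
  Φ((0 − μ_d)/σ), the expected winter counts are summed, and the trend is
  the root at which their noiseless Sen slope equals the target), then 200
  replicates of 5 stations × 100 winters check that the mean estimated Sen
  slope lands within ±0.3 d/decade of the target and that the regional test
  detects it at α = 0.05 in ≥ 90% of replicates;
* snow-model mass balance to 10⁻⁹ mm over 10,000 randomized steps, ddf
  monotonicity, and calibration self-recovery (the grid search returns the
  generating parameters with agreement 1.0 on model-generated
  observations);
* exhaustive truth-table agreement of `classify_day()` over a grid spanning
  every threshold boundary (including missing inputs), and the per-winter
  partition/nesting invariants on 1000 random synthetic winters;
* a three-subregion experiment — nine stations, warming of 1 °C/decade on
  Tmin injected only in the west and east — checking that the regional
  frost-day verdict is significantly negative in west and east and
  non-significant in central in the majority of 200 seeds.

These sizes (200 seeds, 100 winters, 2000 null replicates) were chosen as
the smallest designs whose Monte-Carlo error is well inside the asserted
margins.

## Known limitations

* Snow indicators inherit the biases of a calibratable but simple
  temperature-index model: no energy balance, no sublimation, no
  depth–density conversion (SWE is used directly).
* The QC thresholds and gap-fill window are sensible defaults, not
  reconstructions of any particular archive's rules; analyses of real data
  should state the values used (they are all in the run config, which the
  pipeline logs in its manifest).
* The regional test assumes independent stations; in dense networks with
  spatially correlated weather its variance is optimistic.
* Rain-on-snow uses the modeled rain component of daily precipitation, so
  mixed-phase days contribute partial rain; with sub-daily data one could do
  better.
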