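# wintertrends

Winter climate-change indicators and nonparametric trend analysis for daily
station weather.

## What it does and for whom

For ecologists, hydrologists and climatologists studying how winters are
changing in seasonally snow-covered regions, `wintertrends` turns daily
station records (Tmin, Tmax, precipitation, snowfall, snow depth) into
per-winter counts of twelve threshold-based indicators — frost, ice and thaw
days; extreme-cold (pine beetle kill) and hemlock-woolly-adelgid kill days;
snowmaking/mosquito-kill days with early- and late-season windows;
snow-covered, bare-ground, rain-on-snow, frozen-ground and mud days — and
tests their long-term trends. Winter is the dormant season, 1 November–31
May, labeled by its ending year.

The statistical core is rank-based and assumption-light:

- **Mann-Kendall test** per site and indicator:
  `S = Σ_{i<j} sign(x_j − x_i)`, tie-corrected variance
  `var(S) = [n(n−1)(2n+5) − Σ_t t(t−1)(2t+5)]/18`, continuity-corrected
  `z = (S − sign(S))/√var(S)`, two-sided normal p.
- **Sen slope**: median of all pairwise slopes, reported in days/decade,
  missing winters omitted pairwise on the true year axis.
- **Regional (site-blocked) Kendall test**: block S and variances summed
  across stations (independent blocks), regional slope = median of pooled
  within-block pairwise slopes.
- **Autocorrelation screen** to lag 30 with a ±1.96/√n band, advisory only.

Because snow-depth archives are short and observers often leave zero depth
unreported, snow-dependent indicators use SWE simulated over the whole
record by a degree-day model (linear rain/snow partition between 0 and 2 °C,
melt factor 2.5 mm °C⁻¹ d⁻¹, small refreezable liquid store; all
parameters configurable, with grid calibration against observed snow
presence). A seeded synthetic daily-weather generator (seasonal cycle, AR(1)
noise, configurable °C/decade trends, wet-day Gamma precipitation, block
missingness including the unreported-zero pathology) provides ground truth
for validating every stage without downloading any archive.

## Worked example

Six synthetic century-long stations, two per subregion, with 1 °C/decade
Tmin warming injected in the west and east only:

```r
library(wintertrends)

cfg <- pipeline_config(
  mode = "synthesize",
  stations = tibble::tibble(
    station_id = c("W1", "W2", "C1", "C2", "E1", "E2"),
    latitude   = 45,
    longitude  = c(-90, -89, -82, -81, -72, -71),
    trend_tmin = c(1, 1, 0, 0, 1, 1)   # deg C / decade
  ),
  gen  = gen_params(n_years = 100),
  qc   = qc_params(min_valid_winters = 90),
  seed = 42
)
res <- run_pipeline(cfg)

dplyr::filter(res$regional_trends, indicator == "frost")
#>   subregion n_blocks      S  var_S       z        p sen_slope significant
#> 1      west        2  -8137 225336 -17.139 7.54e-66     -8.33        TRUE
#> 2   central        2    -80 224240  -0.167 8.68e-01      0.00       FALSE
#> 3      east        2  -8075 225366 -17.008 7.21e-65     -8.09        TRUE
#> 4       all        6 -16292 674942 -19.830 1.65e-87     -6.17        TRUE
```

The warmed subregions show strong, significant declines in frost days
(about −8 days/decade at this warming rate); the unwarmed central subregion
is correctly non-significant with a zero regional slope. Site-level results,
the indicator matrix and Table-style summaries are in `res$site_trends`,
`res$indicator_matrix`, `res$trend_summary` (counts of significant sites,
median/range of significant Sen slopes, regional slope) and
`res$level_summary` (long-term median and range of annual counts by
subregion):

```r
dplyr::filter(res$trend_summary, indicator == "frost")
#>   subregion indicator n_sites n_pos n_neg med_slope min_slope max_slope regional_slope regional_significant
#> 1   central     frost       2     0     0        NA        NA        NA           0.00                FALSE
#> 2      east     frost       2     0     2     -8.08     -8.43     -7.73          -8.09                 TRUE
#> 3      west     frost       2     0     2     -8.32     -8.36     -8.28          -8.33                 TRUE

head(res$indicator_matrix[, 1:9], 3)
#>   station_id winter_year n_days thaw ice frost extreme_cold hwa_kill snowmaking
#> 1         W1        1917    212  118  93   168            9        0        127
#> 2         W1        1918    212  113  98   160            9        0        121
#> 3         W1        1919    212  120  92   157           10        0        117
```

Passing `out_dir =` to `run_pipeline()` writes every table as CSV plus a
JSON manifest (config hash, seed, per-stage counts). Real station files are
analysed the same way with `mode = "read"`, a `path` column in `stations`,
and a `station_dialect()` describing the CSV layout, units and missing-value
sentinel. A thin command-line wrapper with `generate`, `qc`, `trends` and
`run-all` subcommands over a YAML config is installed at
`inst/scripts/wintertrends.R`.

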