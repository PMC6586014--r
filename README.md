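# stemclim

Tools linking mountain microclimate to tree water relations and radial
growth. The package is aimed at ecophysiologists and dendroecologists who
work with the three classic data streams of a forest transect study —
point dendrometers, sap-flow sensors and increment cores — and want the
full quantitative chain in one tested place:

* **Zero-growth decomposition** of dendrometer records. With `r` the stem
  radius, the growth line is the running maximum
  `GRO(t) = max_{s≤t} r(s)` and the tree water deficit is
  `TWD(t) = GRO(t) − r(t)`: irreversible growth versus reversible,
  drought-related shrinkage, under the assumption that growth happens only
  at stem water saturation.
* **Gompertz phenology**: `y(t) = A·exp(−exp(μe/A·(λ−t)+1))`, with total
  growth `A`, maximum rate `μ`, onset `λ` and analytic inflection point
  `I_p = λ + A/(eμ)`.
* **Sap-flow scaling** from tissue-heat-balance rates per unit
  circumference (kg h⁻¹ cm⁻¹) to tree-level daily sums (l d⁻¹) via the
  effective circumference `C − 2π·t_bark`.
* **Tree-ring chronologies**: Tucson RWL I/O, basal area increment
  `BAI_t = π(R_t² − R_{t−1}²)`, negative-exponential + frequency-cutoff
  spline detrending, AR prewhitening, Tukey-biweight site chronologies,
  the standard statistics (MS, AC1, r̄, SNR, EPS) and segment-correlation
  crossdating QC.
* **Bootstrap response functions**: principal-component regression of a
  residual chronology on monthly temperature and precipitation
  (previous-June … current-September window), with seeded bootstrap
  confidence intervals, static and in moving 25-yr windows.
* **Climatic-water-deficit upscaling**: annual `CWD = P − PET_Thornthwaite`
  plus a −2.5 °C thermal floor classify growth conditions over elevation
  grids, now and under a warming scenario (e.g. +3.2 °C, −14.5 %
  precipitation).
* **Seeded synthetic-data generators** for all of the above with known
  ground truth, so every stage is validated end to end.

## Worked example

Simulate a dry mid-elevation site-year (scripted drought DOY 175–200),
decompose the dendrometer trace, and fit the season's phenology:

```r
library(stemclim)

met   <- gen_microclimate(1160, year = 2013, seed = 42,
                          drought = data.frame(start_doy = 175,
                                               end_doy = 200,
                                               swc_floor = 0.09))
daily <- aggregate_daily(fill_gaps(met))
circ  <- gen_dendrometer(daily, seed = 42)
part  <- partition_zero_growth(circumference_to_radius(circ))
stats <- daily_stem_stats(part)

max(stats$twd_max[as.integer(format(stats$date, "%j")) %in% 170:205])
#> [1] 257.6
fit_gompertz(as.integer(format(stats$date, "%j")),
             stats$gro_max - min(stats$gro_max))[, c("A", "mu", "lam", "ip")]
#>        A   mu   lam    ip
#> 1 1173.6 26.2 130.1 146.6
detect_growth_period(stats)
#>   start_doy end_doy n_days qualified
#> 1       123     177     55      TRUE
```

The drought drives the tree water deficit to ~258 µm and ends the main
growth period at DOY 177; the fitted asymptote (1174 µm) falls short of
the generator's drought-free potential (A = 1500 µm) because growth ceased
early — exactly the drought signature the decomposition is meant to expose.

Build a chronology from a synthetic 80-yr, 12-tree ensemble carrying a
June-precipitation signal, and test the climate–growth response:

```r
st    <- gen_station_monthly(1929:2009, seed = 42)
rwl   <- gen_ringwidths(st, 1930:2009, n_trees = 12,
                        beta = c(P.Jun = 0.6), seed = 42)
trees <- average_cores_to_tree(rwl)
pw    <- prewhiten_rwl(detrend_rwl(trees))
chron <- build_chronology(pw)
chronology_stats(trees, prewhitened = pw)[c("rbar", "snr", "eps")]
#> $rbar 0.43   $snr 9.19   $eps 0.9

x    <- monthly_climate_matrix(st, chron$year)
resp <- static_response(chron, x, n_boot = 1000, seed = 42)
resp[resp$variable == "P.Jun", ]
#>   variable coef ci_lower ci_upper significant
#>      P.Jun 0.36     0.24     0.49        TRUE
```

The injected June-precipitation signal is recovered as the strongest
positive response (standardized coefficient 0.36, 95 % CI excluding zero);
the expressed population signal (0.90) clears the conventional 0.85
reliability threshold.

Classify transect growth conditions from the water balance:

```r
cal <- calibrate_cwd_thresholds()
round(cal$site_cwd, 1)
#>  S1070  S1160  S1715  S1990  S2250
#> -151.7 -125.8   25.4  102.3  160.9
classify_cell(transect_cell(1715), cal$thresholds)$class
#> [1] "drought-restricted"
```

The whole chain runs from one configuration with
`run_pipeline("run.yaml")` (or a config list), writing tidy per-stage CSVs
and a JSON manifest with seeds, effective parameters and output hashes.

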