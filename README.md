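# qdetect

Geographical detectors for spatial stratified heterogeneity in
accident-severity point data.

## What problem this solves

Casualty severity in road traffic accidents is *stratified*: it varies
more between the strata of explanatory factors (violation type, road
class, lighting, zone, time of day, ...) than within them.  For analysts of
crash records — traffic-safety researchers, injury epidemiologists, road
authorities — the questions are: which factors' strata explain that
heterogeneity, which strata are high-risk, which of two factors explains
more, and how do factors interact?

The workhorse is the **q statistic**,

    q = 1 − SSW/SST = 1 − (Σ_h N_h σ_h²) / (N σ²),

the share of the outcome's total variance explained by a stratification
(h = 1…H strata of sizes N_h; population variances).  `q = 0`: the factor
is unrelated; `q = 1`: it determines the outcome completely; `100·q` is
the percentage of heterogeneity explained.  Around it, four detectors:

| Detector | Function | Question |
|---|---|---|
| Factor | `qdetect()`, `compute_q()` | Does factor X explain the outcome's heterogeneity? (q + permutation p) |
| Influence / risk | `risk_detector()` | Which strata have significantly higher mean severity? (pairwise Welch t) |
| Ecological | `ecological_detector()` | Does X1 explain more than X2? (F ratio of within-strata variance sums) |
| Interaction | `interaction_detector()` | Does the overlay X1 ∩ X2 weaken, enhance, or nonlinearly enhance? |

plus a global Moran's I spatial-dependence check (`moran_test()`, kNN
row-standardized weights on haversine distances) and a synthetic
accident-record generator (`make_preset()`, `generate()`) with planted
heterogeneity, planted interactions and spatial clustering, including a
preset calibrated to the published Shenzhen 2014–2016 summary statistics.

## Worked example

```r
library(qdetect)

tab    <- generate(make_preset("shenzhen_like"))   # 3250 synthetic records
groups <- split_groups(tab)                        # fatality / injuries-only

fit <- qdetect(injuries ~ primary_cause + responsible_party + zones + day_of_week,
               groups$group2, n_perm = 999, seed = 1)
fit
#> Factor detection of 'injuries' (permutation test, alpha = 0.05)
#>             factor      q p_value
#>      primary_cause 0.0688   0.001
#>  responsible_party 0.0260   0.001
#>        day_of_week 0.0077   0.035
#>              zones 0.0062   0.020
```

Primary cause explains 6.9% of the injury heterogeneity in this synthetic
table (q = 0.0688, permutation p = 0.001) and responsible party 2.6%; a
factor whose p exceeded alpha would be masked with `-`.  Interactions
combine factors through the overlay of their stratifications:

```r
ir <- interaction_detector(groups$group2$records$injuries,
                           stratify(groups$group2, "primary_cause"),
                           stratify(groups$group2, "seasons"))
ir
#> Interaction primary_cause ∩ seasons: Enhance, nonlinear
#>   q(X1) = 0.06883, q(X2) = 0.001702, q(X1∩X2) = 0.09062, q(X1)+q(X2) = 0.07053
```

The overlay explains more than the two factors' q values summed
(0.091 > 0.071): nonlinear enhancement — a weak factor can matter a lot in
combination.  Spatial dependence is checked the same way:

```r
moran_test(generate(make_preset("spatial_demo")), "injuries")
#> Global Moran's I: I = 0.6739 (E[I] = -0.001252), z = 40.95, p = < 2.22e-16
#>   n = 800, weights: knn(k=8), row-standardized, haversine
```

`run_analysis()` chains everything (group split, Moran, masked factor
tables, risk tables, all-pairs interaction matrix with type shares, top-k
combined-factor ranking) into one report object; `write_report()` emits
CSVs and a JSON bundle.  A thin command-line driver with the same verbs
(`simulate`, `detect`, `risk`, `interact`, `combine`, `moran`, `report`)
ships in `inst/scripts/qdetect-cli.R`.

Real records are read with `read_accident_csv(path, shenzhen_codings())`:
one row per accident with `record_id, lon, lat, year, fatalities,
injuries` and one integer-coded column per factor.

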