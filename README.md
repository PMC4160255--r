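# ewdclim

Dendroclimatic reconstruction from tree-ring density chronologies.

`ewdclim` is an R package for the complete chain of a classical
dendroclimatology study built on mean earlywood density (EWD) — or any
annual tree-ring measurement — from a moisture-limited conifer site. At
sites with warm, dry springs, the earlywood density of pines rises in hot
dry years (narrow tracheid lumina, proportionally more cell wall), which
makes EWD a proxy for late-spring maximum temperature. The package is for
paleoclimatologists who want every step of that argument — chronology
quality, climate signal, calibration skill, reconstruction — as tested,
scriptable code rather than a chain of legacy GUI programs (ARSTAN,
DENDROCLIM2002, spreadsheet verification).

## What it computes

Given per-core measurement series and monthly station climate:

1. **Detrending** — each series is divided by a fitted growth curve
   `g(t) = a·e^(−bt) + d` (cambial age `t`), with a conservative fallback
   cascade (negative exponential → non-positive-slope line → horizontal
   mean), yielding dimensionless index series `i_t = y_t / g(t)`.
2. **Chronology** — per-year Tukey biweight robust mean of the indices,
   with running Rbar (mean pairwise inter-series correlation over gliding
   windows) and the expressed population signal
   `EPS = N·r̄ / (N·r̄ + (1 − r̄))`; the chronology is truncated to the
   period where `EPS > 0.80` (with a depth-aware override) and at least 4
   trees / 6 cores are present.
3. **Climate response** — bootstrapped correlation functions and
   principal-component response functions of the chronology against a
   monthly window from July of the prior year to September of the growth
   year; first-order partial correlations.
4. **Calibration / verification** — a linear transfer function
   `T = β₀ + β₁·index` with the classic leave-one-out battery: Pearson
   `R`, explained variance `r²`, regression `F`, the sign test on
   departures from the calibration mean, the reduction of error
   `RE = 1 − Σ(o − p)² / Σ(o − ō_cal)²`, and the product-means `t`.
5. **Reconstruction** — the transfer function applied over the full
   reliable period; warm/cold years labelled by the ±1σ rule; a
   zero-phase 10-year low-pass (second-order Butterworth, forward and
   backward) exposes decadal warm/cold periods of at least 5 years.
6. **Field diagnostics** — detrended spatial correlation maps against a
   gridded field and composite anomaly maps for the extreme deciles of
   the reconstruction.
7. **Synthetic benchmark** — a seeded generator producing 63 density
   cores from 25 trees (1666–2008) plus monthly climate with known truth
   (transfer coefficients, common-variance fraction, noise tiers), so the
   whole pipeline is testable end to end without any data download.

## Worked example

```r
library(ewdclim)

bm    <- make_benchmark_dataset(seed = 1)                # synthetic study, known truth
chron <- truncate_reliable(build_chronology(detrend(bm$measurements)))
chron
#> <chronology> 343 years 1666-2008; depth 12-63 cores; reliable from 1666

cal <- 1953:2008
idx <- chron$index[match(cal, chron$year)]
tmj <- unname(seasonal_mean(bm$climate$tmax, 5:6, cal))  # May-June Tmax target
v   <- verify(idx, tmj, years = cal)
v
#> Calibration / leave-one-out verification
#>   R         0.526
#>   r2        0.277
#>   F        20.686
#>   Sign   34+/22-
#>   RE        0.222
#>   PMT       2.953

rec <- reconstruct(v$model, chron)
rec
#> <reconstruction> 343 years 1666-2008; mean 25.55, sigma 0.41
#>   warm 16%, cold 15%, normal 69%
```

The chronology spans all 343 years at full reliability (the staggered
recruitment keeps at least 4 trees and 6 cores back to 1666). The
verification block is the standard six-role battery: here the calibration
explains 27.7% of the May–June maximum temperature variance for this
seed's draw, the sign test gives 34 agreements to 22 disagreements over
the 56 calibration years, and RE > 0 indicates skill over climatology.
The reconstruction's mean (25.55 °C) and spread (0.41 °C) are in the
range typical of warm temperate spring maxima, and warm/cold/normal
percentages partition the 343 years by the one-sigma rule. One `run_full_analysis(run_config(...))`
call performs the same steps from CSV inputs and writes every table, the
resolved configuration and a run log to an output directory.

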