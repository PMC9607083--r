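# lagtox

Time-lagged correlation screening for shellfish toxicity surveillance
panels.

Coastal monitoring programmes measure diarrhetic shellfish poisoning (DSP)
toxin concentrations (µg OA eq. kg⁻¹) in shellfish, toxic-phytoplankton
cell counts, and oceanographic/meteorological conditions, roughly weekly
per production area. `lagtox` asks the forecasting question hidden in
those panels: **which series lead which, and by how many weeks?** It
provides:

* a **synthetic monitoring generator** with planted bimodal seasonality
  (May and September peaks), a north→south toxicity gradient,
  adjacency-decaying spatial correlation, and species-specific toxin
  uptake/elimination kinetics — so the whole pipeline is testable without
  any data download;
* **panel preparation**: weekly mean resampling onto a fixed 7-day grid,
  optional MAD outlier masking, a minimum-coverage filter (default 240 of
  312 weeks), and automated **imputation-method selection** that hides
  part of the observed data and picks the candidate minimising
  reconstruction RMSE;
* **seasonality/trend profiles**: monthly and yearly means with 95%
  confidence bands, per series and pooled by coastal region;
* **lagged correlation**: time-lagged Pearson curves (21 values over lags
  −10…+10) and the multi-scale detrended partial cross-correlation
  (DPCCA) coefficient at window sizes 4, 12, 26 and 52 weeks;
* a **threshold screen** over all pairs of a comparison class
  (area–area, species–species, phytoplankton–toxicity,
  environment–toxicity) with peak-lag location and curve-asymmetry
  diagnostics.

## The statistics

With lag applied to the second series (positive lag `k` pairs `x_t` with
`y_{t−k}`, so a peak at `k > 0` means `y` leads), the Pearson curve is

    r(k) = Σ(x_i − x̄)(y_i − ȳ) / √(Σ(x_i − x̄)² Σ(y_i − ȳ)²)

over the lag-`k` overlap, with two-sided p-values from the t transform.
The DCCA coefficient at scale `s` integrates each series into its
cumulative-deviation profile `X_t = Σ_{i≤t}(x_i − x̄)`, fits an OLS line in
every overlapping `s`-week window, and forms

    ρ(s) = F²_DCCA(s) / (F_DFA,x(s) · F_DFA,y(s)),

the ratio of detrended covariance to the detrended standard fluctuations.
The partial (DPCCA) version inverts the DCCA coefficient matrix `ρ(s)` of
the pair plus conditioning series and reads the coefficient off the
precision matrix `C(s) = ρ(s)⁻¹`:

    ρ_DPCCA(x, y; s) = −C_xy(s) / √(C_xx(s) · C_yy(s)).

## Worked example

```r
library(lagtox)

sim  <- simulate_monitoring(synth_config(seed = 1), out_dir = "data")
prep <- prepare_panel("data", list(seed = 1))

monthly_profile(panel_series(prep$panel, "RIAV1.toxin.mussel"))
#>    series_id          month  mean ci_halfwidth     n
#>  1 RIAV1.toxin.mussel     1  60.7         27.4    26
#>  ...
#>  5 RIAV1.toxin.mussel     5 576.         119.     26
#>  ...
#>  9 RIAV1.toxin.mussel     9 402.          65.6    25
```

The planted May and September toxicity peaks dominate the monthly
profile (576 and 402 µg OA eq. kg⁻¹ versus a winter floor near 60).

```r
screen_pairs(prep$panel, prep$areas, "area-area", "pearson")
#>   x                  y                 best_value peak_lag asymmetry adjacent
#> 1 LAG.toxin.mussel   OLH2.toxin.mussel      0.948        0   0.0101  TRUE
#> 2 RIAV1.toxin.mussel RIAV2.toxin.mussel     0.944        0  -0.0426  TRUE
#> 3 L2.toxin.mussel    RIAV1.toxin.mussel     0.933        0   0.00699 TRUE
```

Area pairs rank exactly as the generator plants them: adjacent areas at
the top, peaking at lag 0 with near-symmetric curves. Species screens
(`"species-species"`) instead show asymmetric curves whose sign identifies
the faster-accumulating species as the predictor, and
`lagged_dpcca()` adds the scale-resolved view:

```r
x <- panel_series(prep$panel, "RIAV1.toxin.mussel")
y <- panel_series(prep$panel, "RIAV2.toxin.mussel")
lagged_dpcca(x, y, max_lag = 10)   # 21 lags x 4 scales (4, 12, 26, 52 wk)
```

`run_pipeline(list(seed = 1, out_dir = "results"))` executes the whole
chain — synthesis (or ingestion of CSVs in the same layout), preparation,
profiles, all screens — and writes tidy CSV outputs plus a manifest with
seed, config hash and file digests. A thin CLI wrapper is installed under
`inst/scripts/lagtox`.

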