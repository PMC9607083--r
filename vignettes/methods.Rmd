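---
title: "Methods: time-lagged correlation screening of shellfish toxicity panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-lagged correlation screening of shellfish toxicity panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagtox)
```

## The problem

Shellfish harvested in coastal production areas accumulate diarrhetic
shellfish poisoning (DSP) toxins — okadaic-acid-group compounds produced by
*Dinophysis* and *Prorocentrum* dinoflagellates — whenever these
phytoplankton bloom. Regulatory surveillance samples each area roughly
weekly, closing harvests above the EU limit of 160 µg OA eq. kg⁻¹. Such
programmes are reactive: they detect contamination, they do not anticipate
it. A first step toward forecasting is quantifying *which signals lead
which*: does toxicity in one area anticipate a neighbouring area, does a
fast-accumulating species anticipate a slow one, do cell counts or
temperature anticipate toxicity, and by how many weeks?

`lagtox` implements that screening workflow for weekly monitoring panels:
panel preparation (resampling, coverage filtering, automated imputation
selection), seasonality/trend profiling, and two families of lagged
association measures — time-lagged Pearson correlation and the multi-scale
detrended (partial) cross-correlation coefficient — plus a threshold-based
screen over all pairs of a comparison class. Because real surveillance
extracts are not bundled, the package ships a synthetic generator whose
planted structure makes every stage testable end to end.

## Weekly panels

All series live on a common grid of 7-day bins anchored at the panel start
date (`weekly_index()`). Only bins fully contained in the configured span
are kept; with the default span 2015-01-05 to 2020-12-29 this yields
exactly 312 weekly bins. Observations are averaged within bins (duplicate
within-week measurements collapse to their mean) and empty bins are
explicit `NA`s. A week is attributed to the calendar month and year of its
bin-start date; weeks straddling a boundary are not split — simple,
deterministic, and at most one week of attribution error.

Series are identified as `<area>.<variable>[.<species>]`, e.g.
`RIAV1.toxin.mussel` or `L2.sst`, and collected in a `series_panel`.

## Preparation

* **Coverage filter** — series with fewer than `min_weeks` (default 240
  of 312) observed weeks are dropped before any imputation, so no series
  in the analysis is mostly manufactured.
* **Outlier rule** — optional `median ± k·MAD` masking (`k` default 5).
  The default is `none`: the downstream screens live off toxicity *peaks*,
  and a dispersion-based rule on a bursty series removes exactly the
  signal of interest. A zero-dispersion series is left untouched.
* **Imputation selection** (`tune_imputer()`) — for each gappy series,
  `n_copies` (default 5) artificial-missingness copies are made by hiding
  disjoint random subsets (`hide_frac`, default 0.1) of *observed*
  positions. Each candidate imputer fills each copy and is scored by the
  root-mean-squared error on the hidden positions; the winner is the
  candidate with minimal mean RMSE. Ties break toward the method with
  fewer hyperparameters, then registry order, so the choice is
  deterministic. The candidate registry spans constant fills (mean,
  median), interpolation (linear, cubic spline), local smoothing (moving
  average, window 3–11) and a seasonal-naive rule (period 26 or 52
  weeks). Hyperparameter search supports exhaustive `grid` (the default
  in `prepare_panel`, exact for these small grids), `random`
  subsampling, and a `bayesian` strategy — a small in-package sequential
  model-based search (RBF-kernel Gaussian process with
  expected-improvement acquisition over the discretised grid) for users
  who extend the grids beyond exhaustive reach. All strategies are
  deterministic given the seed.
* Imputed values are treated as data downstream. This is a pragmatic
  choice, not a statistical endorsement: downstream p-values do not
  account for imputation uncertainty. Reports retain the imputed
  fraction per series so users can audit or exclude heavily-imputed
  series.

## Lagged correlation

The lag convention is fixed once and used everywhere: **at positive lag
`k`, the first series' present is paired with the second series' value `k`
weeks earlier**. A peak at `k > 0` therefore reads "the second series
leads". `shift_pair()` truncates to the overlap (no wrap-around), and every
per-lag computation — means, profiles, fluctuations — is redone on that
overlap, so each lag is a self-contained estimate rather than a slice of a
precomputed global object.

* **Pearson** (`lagged_pearson()`): the product-moment correlation per
  lag with a two-sided p-value from the t transform on `n − 2` degrees of
  freedom. `max_lag = 10` gives the standard 21-value curve; 20 is used
  when slow-response relations (e.g. phytoplankton to toxicity) might
  peak beyond ten weeks. Constant vectors yield `NA`, never a number.
* **DCCA** (`dcca_coefficient()`): each series is integrated into its
  cumulative-deviation profile; an ordinary-least-squares line is fitted
  in every overlapping window of `s` weeks (step 1); the coefficient is
  the ratio of the aggregated detrended covariance to the two detrended
  standard fluctuations, bounded in [−1, 1] by Cauchy–Schwarz. Windowed
  moments use the `1/(s − 1)` normaliser; the per-window DFA moment uses
  *squared* residuals — some printed statements of this quantity omit the
  square, but only the squared form makes it a variance, and the package
  follows the standard DFA definition. The `s = N` edge case leaves the
  `N − s` aggregate denominator empty; the coefficient is computed from
  window sums, which cancels the denominator and stays defined.
* **DPCCA** (`dpcca()`, `lagged_dpcca()`): the DCCA coefficient matrix
  over the pair plus any conditioning series is inverted, and the partial
  coefficient is read off the precision matrix. With the pair alone this
  reduces algebraically to DCCA (verified to 1e-10 in tests); the
  pairwise screens use the pair alone by default and accept a
  conditioning set via argument. Inversion is guarded by a
  condition-number threshold of 1e10 — a near-singular matrix means a
  collinear conditioning set and is reported as such rather than
  silently inverted. The default scale set `s ∈ {4, 12, 26, 52}` reads
  as month, trimester, semester, year; a lag/scale combination whose
  overlap is shorter than the scale is `NA`, not an error.

p-values are computed for the Pearson screen only, and no multiplicity
correction is applied — the screen mirrors a raw `p < 0.05` filter and
reports the number of tests performed so users can correct afterwards.
DPCCA significance would require a resampling scheme and is out of scope.

## Profiles

Seasonality and trend are summarised as monthly and yearly means — a
deliberate alternative to formal decomposition, since the goal is to read
calendar patterns, not to separate latent components. Confidence bands are
normal-approximation 95% intervals (`mean ± 1.96·sd/√n`); a single
observation leaves the band undefined. Regional profiles pool the weekly
values of all member series before averaging (pooled weeks, not
mean-of-means) so that sample counts drive the bands; the mean-of-means
alternative is available via `pool = FALSE`.

## The synthetic generator

`simulate_monitoring()` emulates the joint structure the analysis is meant
to detect; its defaults are the package's study conditions and are not
tuned per experiment.

* **Areas**: a north→south chain of 10 areas (7 west coast, 3 south
  coast) named after Portuguese production areas, with adjacency between
  consecutive ranks and a three-region grouping (northwest/southwest
  split at rank 4 on the west coast; the south coast is its own region).
* **Environment**: SST as an annual day-of-year sinusoid within the
  285–297 K coastal band peaking in late August; air temperature in
  phase; chlorophyll-a positive and bloom-linked; wind and rainfall
  non-negative with a winter-weighted rainfall cycle. `env_noise_sd = 0`
  gives deterministic cycles.
* **Blooms**: weekly Bernoulli pulses with log-normal magnitudes
  (meanlog 7.7, sdlog 2.2 — median ≈ 2,200 cells/L with a heavy right
  tail reaching the 10⁵–10⁶ range, matching the extreme spread of
  published cell-count summaries). Pulse probability and magnitude are
  modulated by Gaussian season bumps (s.d. 0.5 months) centred on the
  configured peak months, May and September by default with amplitudes
  1 and 0.9. Pulses mix along the chain with geometric attenuation
  (`spatial_decay`, default 0.6 per adjacency step, column-normalised so
  chain position does not change marginal levels), and southern areas are
  scaled by `ns_gradient^rank` (default 0.92). A `deterministic_blooms`
  mode replaces pulse trains by their expectation — the noiseless limit
  in which the planted structure holds exactly.
* **Toxin kinetics**: each species integrates the bloom forcing through
  `T[t+1] = (1 − e)·T[t] + u·P[t] + e·baseline`, a first-order
  uptake/elimination recursion. The forcing a species sees is
  `toxin_yield · P / (1 + P / half_sat)` — uptake saturates for extreme
  blooms (half-saturation 2·10⁴ cells/L), which is why simulated toxin
  burdens span roughly two orders of magnitude while cell counts span
  five, as real monitoring summaries show. Default kinetics give mussel
  and Donax clam slow elimination (0.30, 0.20 wk⁻¹; high burdens, long
  memory) and cockle and surf clam fast elimination (0.60, 0.70 wk⁻¹).
  Under shared forcing this produces cross-species curves that peak at or
  near lag 0 but decay asymmetrically — the faster species' past predicts
  the slower one's present better than the reverse — which is exactly the
  statistic `asymmetry_index()` measures. A *displaced* peak requires a
  genuinely delayed forcing; the recovery tests plant one explicitly by
  delaying one series' forcing by a known number of weeks.
* **Missingness**: i.i.d. thinning (default 10%) plus a Poisson number
  (default rate 2) of contiguous gap blocks with geometric length (mean
  3 weeks) — missing completely at random, since real surveillance gaps
  are unmodelled. Observed values are never altered and the realised
  mask is retained.

What the generator does **not** emulate: hydrodynamics, nutrient dynamics,
multi-toxin chemistry, informative missingness (closures cause sampling
gaps that correlate with toxicity in the field), and calibration to any
real coastline. Passing recovery tests therefore demonstrates that the
pipeline detects the planted statistical structure at realistic magnitudes
and noise levels — not that it would achieve the same rates on field data.

## Numerical and design choices

* Week-count convention: an inclusive 7-day sequence over the default
  span has 313 points; the package counts *full* bins inside the span,
  giving 312, and exposes the span as configuration rather than
  asserting a calendar convention.
* Peak-lag ties break toward the smallest |lag|, then the negative lag;
  ties are measure-zero for real data but must be deterministic for
  reproducibility.
* The bloom-season phase is validated against the ensemble-mean monthly
  toxicity profile: with the default kinetics the sub-month accumulation
  delay leaves the planted peak months intact, so no phase offset is
  applied by default (`bloom_lead_weeks = 0` is exposed for slower
  kinetics).
* All generator, masking and search randomness derives from explicit
  seeds; identical configurations produce byte-identical CSV exports,
  and the pipeline writes a manifest (seed, config hash, file digests)
  to make reruns checkable.
* Problem sizes used by the test-suite and acceptance checks: series of
  length ≤ 312 weeks, oracle cross-checks on 100 random instances of
  length ≤ 60 at scales 4–12, and 50-replicate recovery loops — sized so
  the full suite runs in well under an hour on one core while keeping
  the Monte-Carlo rates stable.

## Worked example

```{r example, eval = FALSE}
library(lagtox)

sim <- simulate_monitoring(synth_config(seed = 1), out_dir = "data")
prep <- prepare_panel("data", list(seed = 1))

# seasonality of mussel toxicity in one area
monthly_profile(panel_series(prep$panel, "RIAV1.toxin.mussel"))

# which area pairs could predict each other?
screen_pairs(prep$panel, prep$areas, "area-area", "pearson")

# full pipeline with outputs and manifest
run_pipeline(list(seed = 1, out_dir = "results"))
```

## Limitations

* Pearson p-values ignore autocorrelation and imputation, and the screen
  applies no multiplicity correction; treat the screen as ranking, not
  inference.
* DPCCA curves carry no significance measure.
* The imputation benchmark scores point reconstruction only; it does not
  propagate imputation uncertainty into downstream estimates.
* The generator's missingness is MCAR; informative gaps (closure-driven)
  would bias real-data profiles in ways the synthetic tests cannot
  reveal.
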