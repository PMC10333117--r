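# nicetrends

Neutral baselines and colonization–extinction imbalance for biodiversity
time series.

## The problem

Community surveys run for a finite window of years, and trends in species
richness estimated from them are routinely read against a null expectation
of *zero* change.  That expectation fails for finite, temporally
autocorrelated series: within any finite window a colonization is registered
the first year the species appears (early), while an extinction is only
complete once a declining population has lingered away (late, often past the
window end).  Even fully neutral dynamics — independent species, equal
colonization and extinction rates — then produce a systematic upward bias in
estimated richness trends.  `nicetrends` is for ecologists analysing
community time series who want to quantify this bias and test observed
trends against a neutral baseline instead of against zero.

## What is inside

* **Neutral simulator** — per-species two-state Markov chains from the
  island-biogeography model `dS/dt = c(S_P − S) − eS`, with equilibrium
  richness `c/(c+e)·S_P`, closed-form expected richness and lag-1
  autocorrelation `exp(−(c+e)Δt)` (`simulate_series()`, `transition_probs()`,
  `expected_richness()`, `rates_from_autocorrelation()`).
* **Event inference** — optimal linear estimation (OLE) of per-species
  colonization and extinction years from sighting records, with window
  censoring and a persistence rule (`ole_extinction()`, `ole_colonization()`,
  `infer_events()`).
* **NICE** — the net imbalance between cumulative colonizations and
  extinctions, `NICE = (C_cum − E_cum)/(C_cum + E_cum) ∈ [−1, 1]`, per
  sampled year (`nice_value()`, `nice_trajectory()`).
* **Null model** — chronosequence randomization: per-species permutation of
  yearly occurrences that conserves occupancy totals while destroying
  temporal autocorrelation (`randomize_chronosequences()`, `null_ensemble()`).
* **Trend statistics** — per-series OLS on log richness, lme4 mixed models
  with marginal/conditional R², a heteroscedastic-normal maximum-likelihood
  fit of trend mean and spread against series length, and t-tests on final
  NICE (`richness_trend()`, `mixed_trend()`, `length_effect()`,
  `nice_final_test()`, `nice_trend()`).
* **Synthetic data** — survey-style collections (fish-like and bird-like
  presets), winners/losers turnover scenarios and extinction-debt /
  immigration-credit step scenarios (`dataset_spec()`,
  `generate_neutral_dataset()`, `generate_turnover_scenario()`,
  `generate_directional_scenario()`).
* **Pipeline** — the three-arm comparison (observed / randomized null /
  matched neutral baseline) as one call (`run_pipeline()`), plus long-format
  CSV/TSV readers and writers (`read_long_table()`, `write_long_table()`).

## Worked example

Generate 120 fish-survey-like neutral series started below equilibrium with
strong temporal autocorrelation, then run the three arms:

```r
library(nicetrends)

spec <- dataset_spec(n_series = 120, preset = "fish", rho = 0.8,
                     init = "fraction", init_occupancy = 0.3, seed = 2024)
coll <- generate_neutral_dataset(spec)
summary(coll)
#> Series collection: 120 series from synthetic neutral (fish preset)
#>   sampled years per series: mean 15.9 (sd 4.2)
#>   observed species per series: mean 13.0 (sd 5.4)

report <- run_pipeline(coll, seed = 1)
report
#> <pipeline_report> 120 series (synthetic neutral (fish preset)), seed 1
#>   observed LME slope +0.02465 (p 3.3e-19), mean final NICE +0.193
#>   null     LME slope +0.000939 (p 0.5), mean final NICE +0.022
#>   neutral  LME slope +0.02535 (p 2.82e-27), mean final NICE +0.265
```

Reading the output: the "observed" arm (here itself neutral, but
autocorrelated and below equilibrium) shows a strongly significant richness
increase of about +2.5% per year — with no environmental forcing anywhere in
the generator.  The chronosequence-randomized null, which destroys temporal
autocorrelation, is flat (p = 0.5), and the matched neutral baseline
reproduces the observed slope.  Final NICE is positive: colonizations are
counted earlier than extinctions within the finite windows.  A real analysis
would read an observed slope against the neutral arm, not against zero.

The length effect on trend estimates (GAMLSS-style location-scale fit):

```r
report$arms$observed$length_effect
#> <hetnorm_fit> heteroscedastic normal, n=120 series
#>   mean:    0.0661 -0.002478 * length  (p_slope = 2.57e-06)
#>   log sd:  -2.731 -0.04955 * length  (p_slope = 0.000522)
#>   logLik 251.93, pseudo-R2 0.180
```

Longer series give smaller and tighter trend estimates — the funnel that
makes short-series compilations overstate richness gains.

## Documentation

The methods vignette (`vignettes/neutral-baselines.Rmd`) describes the
model, the OLE weight construction and its oracles, the censoring and NICE
conventions, the null model, the trend statistics, and the design decisions
and limitations in detail.
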