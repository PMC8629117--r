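# phenocue

Identification of temperature cues for annual phenological events, and
honest evaluation of how well the identified cues predict.

Long-term studies of events such as clutch initiation in woodland birds
need to know *which* days of temperature drive the event's timing before
they can predict how timing will shift in a warming climate. `phenocue`
implements, over one shared pair of data structures — an annual series of
mean event dates (days since 1 April) and a daily mean-temperature series —
the five statistical tools most often used for this cue-identification
problem, plus the cross-validation machinery needed to compare their
predictions:

| method | idea | cue |
|---|---|---|
| SWA (`search_absolute`) | exhaustive scan of every window of lag days before a calendar reference day (20 May), four aggregates (mean, min, max, within-window slope), ranked by AICc against an intercept-only baseline | aggregate temperature over the best window |
| SWR (`search_relative`) | the same scan with windows anchored to each year's own event date | event-anchored aggregate (identifiable, but unusable for prediction) |
| CSP (`csp_profile`) | day-by-day regressions smoothed into coefficient and R² profiles; days in the extreme 2.5%/97.5% quantile tails of both form the critical window | mean temperature over the critical window |
| PSR (`fit_psr`) | penalized B-spline signal regression of the event day on all 365 lags at once: y = α + Σ_d β(d) x_d with a cubic B-spline β and first-order difference penalty, λ by GCV | the whole coefficient function |
| GDD (`fit_gdd`) | three-parameter thermal-time model: degree-days above a base temperature T_b accumulate from start day t₀ until a requirement F\* is met; fitted by seeded simulated annealing in the box t₀∈[1,200], T_b∈[1,10] °C, F\*∈[50,1000] °C·days, with 1,000-replicate percentile bootstrap CIs | the date the requirement is reached |

`run_experiment()` cross-validates any subset of the predictive methods
(SWA, CSP, PSR, GDD) over near-future, fixed-test or K-fold split plans,
re-identifying the cue from scratch on every training set, and reports
MAE, mean signed error, 95% prediction-interval width, coverage and the
least-squares trend of prediction error through time. A synthetic
climate–phenology generator (`simulate_climate()`, `simulate_phenology()`)
plants any of the three cue mechanisms with known truth, so every stage is
testable by parameter recovery.

## A worked example

```r
library(phenocue)

sim   <- simulate_scenario(default_scenario(), seed = 1)  # 55 years, planted cue
train <- pheno_series(sim$phenology$year[sim$phenology$year <= 2010],
                      sim$phenology$event_day[sim$phenology$year <= 2010])
M     <- build_climate_matrix(sim$climate, 1961:2010)     # years x lags 0..364

search_absolute(train, M)
#> <pc_window_scan> absolute frame, 266815 candidates, 50 years
#>   best: mean over lags 83..14  slope=-6.661  adj R2=0.877  dAICc=-103.63

csp_profile(train, M, relax = TRUE)
#> <pc_csp_profile> 364 lags; critical window lags 36..36 (lower coef tail; ...)

fit_psr(train, M)
#> <pc_psr_model> n=50  20 basis fns (degree 3, penalty order 1)  lambda=3.16e+03
#>   edf=12.2  adj R2=0.818  important lags: 94..10

fit_gdd(train, sim$climate, seed = 42)
#> <pc_gdd_fit> t0=57  Tb=1.14 degC  F*=393.1 degC-days  SSQ(direct)=344.0
```

The scenario plants a mean-temperature cue over lag days 81..14 before
20 May with slope −6 days/°C. The exhaustive window scan recovers it
almost exactly (window 83..14, slope −6.66, adjusted R² 0.88, and an AICc
advantage of 104 over the intercept-only baseline). PSR flags essentially
the same period (important lags 94..10). The CSP quantile rule marks a
short segment *inside* the sensitive period — that is how the 2.5% tail
rule behaves when all days of the true window are about equally
informative. The thermal-time model, whose mechanism differs from the
planted one, still finds an accumulation proxy (start in late February,
low base temperature) that tracks the same spring warmth.

Cross-validated prediction:

```r
plan <- make_training_sets(c(1961, 2015), mode = "kfold")   # eleven 5-year folds
run_experiment(sim$phenology, sim$climate,
               methods = c("swa", "csp", "psr", "gdd"), plan = plan, seed = 21)
```

yields per-method MAE (days), interval width and coverage pooled over all
55 held-out years, plus the error-vs-year trend table.

A thin command-line front-end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","phenocue.R",package="phenocue"))')" \
    simulate --seed 2 --out sim
# then: prepare / window / csp / psr / gdd / evaluate / reproduce / run
```

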