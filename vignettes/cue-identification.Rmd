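---
title: "Identifying temperature cues for phenological events and evaluating their predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying temperature cues for phenological events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many annual life-history events — egg laying in birds, flowering, emergence —
track spring temperature. To predict how such events will shift under
climate change one must first identify the *cue*: which days of the year
matter, and which summary of temperature over those days (its mean, an
extreme, its rate of change, or an accumulated sum) drives the timing.
With observational data the cue can only be identified statistically, and
several families of statistical tools are in common use. `phenocue`
implements five of them against a single pair of data structures — an
annual series of mean event dates (days since 1 April, whole days) and a
daily mean-temperature series — together with a cross-validation framework
that measures how well each identified cue actually predicts.

All "absolute" methods index temperature by *lag*: the number of calendar
days before a fixed reference day (20 May by default), walking back through
real dates so leap days are handled naturally. Lag 0 is the reference day
itself; profiles that conceptually start "the day before the reference"
drop lag 0 (the `include_reference_day` switch).

## The five identification methods

**Absolute sliding window (SWA).** Every window of consecutive lags
(open ≥ close, duration 1–365) is a candidate; within a window the daily
means are collapsed to one of four aggregates — mean, minimum, maximum, or
the within-window warming slope (OLS gradient of temperature on
day-in-window, °C/day) — and the annual event day is regressed on the
aggregate. Candidates are ranked by AICc,
$\mathrm{AICc} = -2\log L + 2k + 2k(k+1)/(n-k-1)$,
with the Gaussian maximum likelihood and $k$ counting coefficients plus the
residual variance ($k=3$ for a slope model, $k=2$ for the intercept-only
baseline the winner is compared against). The search is exhaustive and
vectorized (window sums by cumulative sums, the slope aggregate by a second
weighted cumulative sum, running min/max for the extremes); the column-wise
closed-form OLS is the same arithmetic as `fit_linear()`, and the test
suite pins the whole ranked table against a naive double-loop oracle at
1e-8. Exact AICc ties (to 1e-8) are broken towards shorter and then more
recent windows — parsimony and proximity to the event.

**Relative sliding window (SWR).** The same search, but lags count back
from each year's *own* event date, so a window covers different calendar
days each year. Because the anchor is the event itself, a relative cue
cannot be known before the event happens; `predict_from_cue()` therefore
refuses relative models, and the evaluation stage excludes SWR (with a
message) rather than silently predicting with it.

**Climate sensitivity profile (CSP).** Event day is regressed on each
single lag's temperature; the per-lag slope and $R^2$ profiles are smoothed
with a penalized cubic regression spline (mgcv, smoothing parameter by
GCV, basis dimension 50 by default) and thresholded: a lag is *sensitive*
when its smoothed coefficient lies at or beyond the 2.5% tail on the side
of the dominant effect (lower tail for a cooling–delaying, i.e. negative,
coefficient) and its smoothed $R^2$ is at or above the 97.5% quantile.
Thresholds are empirical (type-7) quantiles of the smoothed profiles over
all lags. The critical window is the longest run of consecutive sensitive
lags (ties towards the reference day), and the cue is the mean temperature
over it, fitted and predicted exactly like a sliding-window cue.

Because the strict 2.5%/97.5% rule marks only ~9 of 364 lags, two
practical behaviours follow. First, when every day of a genuinely
sensitive period is about equally informative the rule selects a short
sub-segment *within* the period rather than the period's centre; recovery
should be judged by overlap, not by midpoint. Second, on weakly
autocorrelated data the two marked sets may fail to intersect at all; this
is reported as an error by default, and `csp_profile(relax = TRUE)` widens
the tails stepwise (5%, 10%, 25%) until a window emerges, recording that
relaxation happened. The evaluation pipeline uses the relaxed form so that
every cross-validation fold yields a CSP cue.

**Penalized B-spline signal regression (PSR).** All 365 lags enter one
regression: $y = \alpha + \sum_d \beta(d)\, x_d + \varepsilon$, with the
coefficient function constrained to a cubic B-spline basis
($\beta = B\theta$, 20 basis functions by default, never more than $n-2$)
and a first-order difference penalty $\lambda\|D\theta\|^2$ whose null
space is the constant function. $\lambda$ is chosen by generalized
cross-validation on a 41-point log-spaced grid from $10^{-4}$ to $10^6$.
Pointwise standard errors come from the penalized-least-squares covariance
$\hat\sigma^2 M^{-1} G M^{-1}$ with $M = Z'Z + P$ and $G = Z'Z$; days with
$|\beta| > 2\,\mathrm{SE}$ are flagged *important*. Predictions use the
full coefficient function, with intervals
$\hat y \pm t_{n-\mathrm{edf}}\sqrt{\mathrm{se}_\mathrm{fit}^2 +
\hat\sigma^2}$. The temperature matrix enters in raw °C (no per-column
centring beyond the intercept).

**Growing degree-days (GDD).** The one mechanistic model: from a start
day $t_0$, every degree by which the daily mean exceeds a base temperature
$T_b$ accumulates, and the event is predicted on the first day the sum
reaches a requirement $F^*$. The parameters live in a bounded box
($t_0 \in [1, 200]$ day-of-year, $T_b \in [1, 10]$ °C,
$F^* \in [50, 1000]$ °C·days) and are fitted by minimizing squared
prediction error. The objective is a step function of all three parameters
(predicted dates are whole days), so fitting uses a seeded bounded
simulated-annealing search (geometric cooling, reflecting Gaussian
proposals, 3 restarts by default) followed by a deterministic polish over
shrinking steps along the axes *and* random directions — the latter matters
because $T_b$ and $F^*$ partially compensate each other along a ridge.
Uncertainty comes from a year-resampling percentile bootstrap (1,000
replicates by default; replicate fits start from the point estimate with a
reduced iteration budget). Prediction intervals are the min/max envelope
of predicted dates over the $2^3$ corner combinations of the per-parameter
confidence bounds — a conservative superset of any low/high pairing, which
the description "predict at the bounds of each parameter" leaves open.
Years whose accumulation never reaches $F^*$ are assigned 31 December, a
large but finite penalty that keeps the objective defined over the whole
box; such corners are flagged in the prediction output.

Two objective variants are exposed. `direct` (the default) minimizes
$\sum(\mathrm{pred}-\mathrm{obs})^2$. `regression` minimizes the residual
sum of squares of a regression of predicted on observed dates, which
matches a literal reading of the published procedure but tolerates bias
and rewards degenerate constant predictors (guarded against here by an
explicit penalty); the difference is documented rather than hidden.

## Evaluating predictions

`make_training_sets()` builds three split designs over a year range:

* `near_future` — the full range plus subsets shrunk in 10-year steps from
  either end (nine training sets for a 50-year range), each tested on the
  5 years after its end;
* `fixed_test` — the same training sets, all tested on the 5 years after
  the full range;
* `kfold` — consecutive 5-year folds (eleven for 55 years), each predicted
  from the complementary years.

`run_experiment()` re-identifies every cue from scratch on each training
set — nothing identified on the full data ever leaks into a fold — and
reports, per method and split and pooled: MAE, mean signed error
(predicted − observed; negative means predictions precede observations),
mean 95% prediction-interval width, and coverage (closed interval).
On plans with three or more splits it also fits the least-squares trend of
per-fold mean signed error against fold mid-year and reports the slope and
multiple $R^2$, per method and pooled over all methods and over the
regression-based subset (SWA/CSP/PSR); both a stacked (method-by-fold
points) and a fold-mean pooling are emitted, since either convention is
defensible for the pooled trend. Metrics are computed on real-valued
predictions; event days themselves are whole days by construction.

PSR basis size adapts to short training sets (`min(20, n-2)`), which the
10-year training subsets of the near-future design require.

## The synthetic generator

`simulate_climate()` produces daily means
$T(d) = \mu + \gamma\,(\mathrm{year}-\mathrm{year}_0) +
A\cos\!\big(2\pi(\mathrm{doy}-\phi)/365.25\big) + e(d)$
with stationary AR(1) noise ($e$ parameterized by its stationary SD, so
`noise_sd` keeps its meaning for any autocorrelation). The defaults are a
temperate maritime climate: mean 9.5 °C, amplitude 6.5 °C, maximum on day
200 (mid-July), daily noise SD 2.5 °C with lag-1 autocorrelation 0.7, and
(in the bundled scenario) a warming trend of 0.03 °C/yr over 1961–2015.

`simulate_phenology()` plants one of the three cue mechanisms the methods
assume — a fixed-window aggregate, a distributed coefficient function over
lags, or degree-day accumulation (reusing `gdd_event_date()` as the forward
model) — adds Gaussian annual noise and rounds to whole days, mirroring the
granularity of real event data. The relative-window variant solves the
self-consistency condition $d = a + b\cdot\mathrm{cue}(d)$ by exhaustive
search over candidate integer days (iteration can oscillate between
adjacent days because the cue is piecewise constant in the event day); the
accepted day is within one day of its own implied value. The bundled
demonstration scenario plants a mean-temperature cue over lags 81..14
before 20 May with slope −6 days/°C and intercept 76, giving mean event
days near the end of April and about 88% of variance attributable to the
cue. In recovery tests of the distributed mechanism the bump coefficient
function is scaled to integrate to the same −6 days/°C so that all three
mechanisms carry a comparable, realistic signal.

What the generator deliberately does *not* emulate: spatial structure,
the within-year heteroskedasticity of real temperature series, biotic
cues, and any drift in the cue–phenology relationship unless a warming
trend is requested. Passing recovery tests on this generator therefore
shows that each method works *when its own assumed mechanism is true and
stationary*; it does not certify performance on real data, where the
methods disagree with one another far more.

## Numerical choices and degenerate inputs

* Whole-day rounding of event dates uses R's `round()` (half to even).
* A cue with zero variance is a hard error in `fit_linear()`; inside the
  exhaustive search such candidates are ranked last (infinite AICc) rather
  than aborting a 267k-candidate scan, and a constant lag in the CSP
  profile is recorded as coefficient 0, $R^2$ 0 with a warning.
* AICc requires $n-k-1>0$: scoring an intercept-only model needs at least
  4 years, a slope model at least 5. The search refuses smaller samples.
* The vectorized search and the naive loop differ only by floating-point
  summation order; agreement is enforced at 1e-8 on AICc in the tests, and
  the ranked order is identical there.
* The annealing optimizer is deterministic given a seed; the bootstrap
  consumes one RNG stream sequentially, so (config, seed) pins every
  output byte.
* Simulation sizes in the tests (20 recovery seeds for the window search,
  10 for interval calibration, 5 for the thermal-time model; bootstrap
  replicate counts of 10–60 in pipeline tests against 1,000 for a real
  analysis) were chosen as the smallest sets that make the pass criteria
  statistically stable.

## Known limitations

* The CSP quantile rule localizes a *part* of the sensitive period, not
  its centre; its window should be read as "lies inside the sensitive
  period", and on weakly autocorrelated data the relaxation ladder may be
  needed at all.
* GDD confidence intervals inherit the optimizer's multimodality; the
  corner-envelope prediction intervals are intentionally conservative and
  several times wider than the regression-based methods'.
* The relative sliding window is identified but never used predictively,
  by construction.
* No method here models a changing cue–phenology relationship; the
  error-trend diagnostic is the tool for detecting that the assumption has
  failed.

## A worked run

```{r, eval = FALSE}
library(phenocue)

sim <- simulate_scenario(default_scenario(), seed = 1)
M <- build_climate_matrix(sim$climate, 1961:2010)
train <- subset(sim$phenology, year <= 2010)
train <- pheno_series(train$year, train$event_day)

search_absolute(train, M)           # exhaustive SWA scan
csp_profile(train, M, relax = TRUE) # sensitivity profile
fit_psr(train, M)                   # signal regression
fit_gdd(train, sim$climate, seed = 42) # thermal-time model

plan <- make_training_sets(c(1961, 2015), mode = "kfold")
run_experiment(sim$phenology, sim$climate,
               methods = c("swa", "csp", "psr", "gdd"), plan = plan)
```

The README shows the numbers this prints and how to regenerate the
package's headline quantities with `scripts/acceptance.R`.
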