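# popclim

Density-dependent population dynamics with lateral climate forcing.

popclim is for quantitative historians, population ecologists and
modellers who work with *coarse* demographic series — population sizes at
irregular historical dates — and want to test how climate acted on growth.
It implements, end to end, the analysis of per-capita growth rates on a
50-year grid: data preparation, two competing growth-rate model families,
nonlinear least-squares fitting, BIC model comparison, and free-running
simulation, plus a seeded synthetic-data generator so the whole pipeline
is testable without any external download.

## The models

Everything is expressed through the *R-function*, the realized per-capita
growth rate over one grid step as a function of the state at the interval
start, with `X = log N`:

```
R_t = X_{t+50} - X_t
```

Two families compete:

* **Exponential-additive** (density-independent; climate shifts growth
  directly):

  `R_t = R_m + Σ_j b_j · Temp_{t-50j}`

* **Ricker-lateral** (discrete logistic; climate moves the carrying
  capacity):

  `R_t = R_m - exp(a·X_t + β0 + Σ_j β_j · Temp_{t-50j})`

  with equilibrium `X* = (ln R_m - β0 - Σ β_j·Temp_j)/a`, linear in
  temperature — a *lateral* shift of the R-function along the population
  axis that leaves the slope at equilibrium, `-a·R_m`, unchanged. Lateral
  forcing makes climate and population size interact: the same cooling
  that is harmless to a sparse population can collapse one near its
  carrying capacity.

Candidate models (each family with lag sets {0} and {0, 1}) are ranked by
`BIC = -2·logLik + p·ln(n)` with Schwarz weights `w_i ∝ exp(-ΔBIC_i/2)`.

## Worked example

Generate the packaged warm-then-cold scenario (a Medieval-Warm-Period to
Little-Ice-Age style regime shift forcing a density-dependent population
over 800–1650), build the 17-interval regression frame, and rank the four
candidate models:

```r
library(popclim)

scn    <- preset("great_famine")
annual <- gen_temperature(scn$temperature)
out    <- gen_population(scn$population, annual)
frame  <- build_model_frame(out$pop, out$temps, c(800, 1650))
rank_models(frame, multistart = 16, seed = 1)
#> Model comparison, window 800-1650 (n = 17)
#>                 family lags loglik p  n   bic delta_bic weight    r2 pred_r
#> 1       ricker_lateral  0+1   34.9 6 17 -52.9     0.000 0.4698 0.545  0.489
#> 2       ricker_lateral    0   33.3 5 17 -52.3     0.511 0.3638 0.446  0.436
#> 3 exponential_additive    0   29.4 3 17 -50.2     2.640 0.1255 0.123  0.351
#> 4 exponential_additive  0+1   29.7 4 17 -48.0     4.884 0.0409 0.153  0.391
#>   converged  best
#> 1      TRUE  TRUE
#> 2      TRUE FALSE
#> 3      TRUE FALSE
#> 4      TRUE FALSE
```

Reading the table: both lateral (Ricker) models beat both additive
(exponential) models decisively — together they carry ~83% of the BIC
weight — so the data generated by a lateral mechanism are correctly
recognized as density-dependent with climate acting on the carrying
capacity. `r2` is the one-step variance explained; `pred_r` is the harder
test, the Pearson correlation between observed growth rates and a
free-running simulation started from the first value only.

At 17 observations the individual exponent coefficients of the best model
are loosely constrained (fitted tables at this series length routinely
contain extreme values), but the *equilibrium* they imply is robust:

```r
fit <- best_fit(rank_models(frame, multistart = 16, seed = 1))
equilibrium(fit$params, c(0.1, 0.1))    # warm-regime carrying capacity
#> [1] 4.092474
equilibrium(fit$params, c(-0.6, -0.6))  # cold-regime carrying capacity
#> [1] 3.79384
```

The fitted cooling response is a drop of ~0.3 log units in carrying
capacity — the lateral signature the scenario was built around.

A published comparison table for this analysis style ships as a plain-text
fixture; `check_table1()` re-derives its BIC and ΔBIC columns from the
printed log-likelihoods and parameter counts (n = 17) and reports every
discrepancy:

```r
check_table1()
#> Printed-table consistency at tolerance 0.05: PASS (max |BIC diff| 0.0196, max |dBIC diff| 0.0000)
```

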