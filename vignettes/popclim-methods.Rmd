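---
title: "Modelling long-run population dynamics under lateral climate forcing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-run population dynamics under lateral climate forcing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popclim)
```

## The problem

Pre-industrial agrarian populations grew slowly, collapsed occasionally, and
left only sparse records: population sizes at irregular historical dates and
proxy reconstructions of climate. The question popclim addresses is whether
such coarse series can discriminate between two mechanisms of climate action
on population growth:

* **additive (vertical) forcing** — climate shifts the per-capita growth
  rate up or down irrespective of population size, as in an exponential
  growth model with a climate covariate; or
* **lateral forcing** — climate moves the *carrying capacity*, so its
  effect on growth is mediated by how close the population already is to
  the limit its resources set. Under lateral forcing, a modest cooling can
  trigger a disproportionate collapse when it meets a population near
  equilibrium — the mechanism proposed for the fourteenth-century Great
  Famine at the transition from the Medieval Warm Period to the Little Ice
  Age.

## The R-function families

All modelling happens on the scale of the realized per-capita growth rate
over one grid step (50 years by default),

$$R_t = \log_e N_{t+50} - \log_e N_t = X_{t+50} - X_t,$$

with $X = \log_e N$. The relationship between $R_t$ and the state at the
interval start is the *R-function*. Two families are implemented.

**Exponential-additive** (density-independent):

$$R_t = R_m + \sum_j b_j\,\mathrm{Temp}_{t-50j}, \qquad j \in \{0\} \text{ or } \{0,1\}.$$

$R_m$ is the maximum per-capita growth rate per step; the $b_j$ (per °C)
act additively and the curve is flat in $X$.

**Ricker-lateral** (density-dependent, discrete logistic in exponential
form):

$$R_t = R_m - \exp\!\big(a X_t + \beta_0 + \textstyle\sum_j \beta_j\,\mathrm{Temp}_{t-50j}\big).$$

The exponent is stored as a single flat coefficient vector
$(a, \beta_0, \beta_j)$. Published tables of this model family are written
in exactly this flat form; it also avoids the identifiability knot between
the density coefficient and a separately-estimated competition constant
during optimization (the classical grouping $a(X - C)$ maps to the flat
form by $\beta_0 = -aC$, so nothing is lost).

Setting $R = 0$ gives the equilibrium (log carrying capacity)

$$X^*(\mathrm{Temp}) = \frac{\ln R_m - \beta_0 - \sum_j \beta_j \mathrm{Temp}_j}{a},$$

linear in temperature: a lateral shift. Two algebraic facts are the
signature of lateral forcing, and both are asserted as properties in the
test suite:

* $\partial X^*/\partial \mathrm{Temp}_j = -\beta_j / a$ — temperature
  moves the equilibrium;
* $\partial R/\partial X \rvert_{X^*} = -a R_m$ — the slope at equilibrium
  does not depend on temperature at all.

No positivity constraint is imposed on $a$ during fitting (published fits
contain both signs); $R_m > 0$ and $a \ne 0$ are required only when an
equilibrium is actually requested. Temperature lags deeper than one step
are not part of the model set.

## Data preparation conventions

* **Interpolation.** Census anchors are interpolated *linearly on the log
  scale* and anti-logged (geometric interpolation), never extrapolated: a
  window reaching outside the census span is an error. A 50-year default
  step keeps the fraction of interpolated values low for typical historical
  sources. Anchors on the grid are reproduced exactly (fixed-point
  property).
* **Growth-rate labelling.** $R$ for the interval $[t, t+50)$ is indexed by
  its start year $t$, and the regressors are $X_t$, $\mathrm{Temp}_t$ (mean
  anomaly over calendar years $t \dots t+49$) and $\mathrm{Temp}_{t-50}$
  (mean over $t-50 \dots t-1$). Published model tables write $R_{t+1}$ as a
  function of $X_t$ and $\mathrm{Temp}_t$; the convention here makes the
  contemporaneous 50-year mean the lag-0 covariate of the interval it
  overlaps. Whether that mean should instead trail the interval
  ($[t-49, t]$) is not decidable from the sources; the half-open $[t, t+50)$
  convention was chosen once and used throughout.
* **Bins.** Temperature bins are half-open $[t, t+50)$ means of exactly 50
  annual values; a gap in the annual series is a coverage error naming the
  missing span, not a silent NA.
* **Units.** Population units (thousands vs millions) only shift $X$ by a
  constant, which the intercept-like parameters absorb; the package does
  not impose a unit.

A window $800$–$1650$ at step 50 has 18 grid points and therefore 17 growth
intervals; the regression frame has exactly one row per interval.

## Fitting and model comparison

Fits minimize $\sum_t (R_t^{obs} - R_t^{model})^2$.

* The exponential-additive family is linear in its coefficients and is
  solved exactly by ordinary least squares.
* The Ricker-lateral family is fitted by Levenberg–Marquardt nonlinear
  least squares. Starting values come from a log-linearization: with a
  guess $R_m^0$ above every observed $R$, $\log(R_m^0 - R)$ is linear in
  $X$ and the temperature columns, and ordinary regression of it supplies
  the anchor start. `multistart` (default 32) seeded, jittered copies of
  the anchor guard against local minima; the converged start with the
  lowest residual sum of squares wins, ties broken by the smaller
  coefficient norm. Convergence tolerance is $10^{-10}$ on relative rss
  improvement, at most 500 iterations per start. On the benchmark
  scenarios below, wide multistarts and starts placed at the truth
  reproduce the anchor start's optimum, so in practice the anchor start
  already finds the global minimum.

Ranking uses the Gaussian likelihood with maximum-likelihood variance
$\hat\sigma^2 = \mathrm{rss}/n$,

$$\log L = -\tfrac{n}{2}\big(\log(2\pi\,\mathrm{rss}/n) + 1\big), \qquad
\mathrm{BIC} = -2\log L + p\log n,$$

$\Delta\mathrm{BIC}_i = \mathrm{BIC}_i - \min_j \mathrm{BIC}_j$, and Schwarz
weights $w_i \propto \exp(-\Delta_i/2)$. The parameter count defaults to
$p = k_{mean} + 1$, counting the residual variance. Published tables of
this analysis are internally inconsistent on this point (structurally
identical two-lag lateral models appear with $p = 5$ in some regions and
$p = 6$ in others), so `fit_model()` accepts a per-fit `p` override for
table-replication work; `check_table1()` uses each row's printed $p$, under
which every printed BIC is reproduced to within 0.02 (rounding of the
printed log-likelihoods). The printed BIC-weight columns of that table are
*not* reproducible from the printed $\Delta$BIC under the standard
$\exp(-\Delta/2)$ formula; the standard formula is what the package
computes, and no claim is made to replicate those printed weights.

A perfect fit ($\mathrm{rss} = 0$, e.g. on noise-free synthetic data) makes
the Gaussian likelihood unbounded; the package warns and propagates an
infinite likelihood rather than silently fabricating a finite BIC.

## Prediction: free-running vs one-step

Two prediction modes are deliberately distinct:

* `one_step_predictions()` evaluates the R-function at every *observed*
  row — the fitted values of the least-squares objective, which $r^2$
  summarizes;
* `simulate_trajectory()` iterates the deterministic skeleton forward from
  a single initial value, feeding each predicted state into the next step,
  with temperature as the only exogenous input. The Pearson correlation
  between observed growth rates and this free-running prediction
  (`prediction_correlation()`) is the stringent test of dynamical adequacy:
  on noisy data it cannot beat the one-step correlation in expectation, and
  the test suite asserts exactly that as a statistical property. Whether a
  published prediction figure shows free-running or one-step curves is
  often ambiguous; both are provided, with growth-rate correlation as the
  default comparison scale (correlation on $X$ can be computed from the
  returned path).

Simulations are noise-free (single deterministic trajectory). For
$a > 0$ and $aR_m < 2$ the discrete Ricker map is stable and the simulated
path converges to $X^*$ under constant forcing; the test suite probes this
standard stability window numerically.

## The synthetic-data generator

Real inputs for this kind of analysis are book-derived census figures and
a downloadable temperature reconstruction; neither ships with the package.
The generator produces data with the statistical structure the analysis
assumes, so every stage is testable end to end:

* `gen_temperature()`: piecewise-linear mean regimes plus AR(1) annual
  noise with innovation sd $\sigma\sqrt{1-\phi^2}$, so `sd` is the
  *marginal* sd. Defaults $\phi = 0.7$, sd 0.15 °C are of the order
  tree-ring reconstructions exhibit.
* `gen_population()`: iterates the chosen family with
  $\varepsilon_i \sim N(0, \sigma_R^2)$ added to each interval's growth
  rate — Gaussian, homoscedastic, on the log scale, exactly the error
  structure the Gaussian NLS likelihood assumes. That choice makes
  parameter recovery a clean test of the fitting stage. Observation error
  on population levels is kept separate, in `gen_census()` (lognormal,
  mean-one, given CV), so interpolation can be tested in isolation.
* Temperature and population noise use independent seeds: changing one
  stream leaves the other bit-identical.

**`preset("great_famine")`** encodes the motivating scenario: mean anomaly
+0.1 °C to 1250, linear cooling to −0.6 °C by 1450, flat thereafter,
forcing a *stable* Ricker-lateral population over 800–1650 (17 intervals).
The parameters keep the published whole-Europe magnitudes for $R_m$ (0.17)
and $|a|$ (0.62) but flip $a$ to the stabilizing sign, because several
published fits have $a < 0$, under which free-running dynamics are
explosive and long-horizon synthetic studies are ill-posed. The lateral
coefficients are scaled to $\beta = (-0.60, -0.25)$ per °C so that the
0.7 °C regime cooling lowers the equilibrium by about 0.8 log units — a
collapse of realistic magnitude rather than the dynamically absurd shift
the raw published exponent magnitudes would imply under a sign-flipped
$a$. These are generator choices, not estimates. `preset("null_exponential")`
drives the same climate through the additive family
($R = 0.22 + 0.29\,\mathrm{Temp}_t$) as the null case for model-selection
checks.

**Benchmark scenarios** (`benchmark_scenarios()`) used by the recovery and
selection studies run 200 intervals with truth
$R_m = 0.2, a = 0.5, \beta_0 = -3, \beta = (4, 2)$. The temperature mean
alternates between +0.1 and −0.1 °C with a 2000-year half-cycle. That
design was chosen up front after a small design study: with a flat mean-0
scenario the binned temperature barely moves, the population hugs a nearly
fixed equilibrium, and the density and climate coefficients are close to
collinear — recovery degrades sharply. Centennial-scale regime
alternation, which is also what real reconstructions show, keeps the
carrying capacity moving on the model's own time scale and identifies all
five coefficients jointly. The studies' problem sizes — 50 replicates for
recovery at growth-noise sd 0.02, 100 replicates per generator for
selection at sd 0.05 — are the package's chosen experiment sizes; at 50
replicates the per-coefficient median relative error is itself a noisy
statistic (its sampling sd is around one percentage point), which is worth
remembering when comparing runs under different seeds.

What the generator does *not* emulate: discrete mortality shocks (wars,
epidemics) on top of the smooth dynamics, multi-region coupling, irregular
real-census error structure beyond the lognormal CV model, and multiproxy
reconstruction artefacts. Passing tests on synthetic data therefore show
that the machinery is correct and the design identifiable under the
model's own assumptions — not that the model is true of any historical
population.

## Numerical and degenerate-input policy

* Errors are classed (`popclim_input_error`, `popclim_coverage_error`,
  `popclim_convergence_error`) so callers and the CLI can map them to exit
  codes; coverage errors name the missing span.
* `equilibrium()` refuses $R_m \le 0$ (no root) and $a = 0$ (degenerate).
* `r_squared()` and `prediction_correlation()` refuse constant observed
  series instead of returning NaN.
* All generators and fits are deterministic given their seeds; fits record
  how many starts converged.

## Reproducing the headline numbers

`scripts/acceptance.R` (see the README) recomputes, from scratch at a
given seed: the reproduction error of published BIC/ΔBIC columns from
their printed inputs, the recovery-study medians, the model-selection
rates, and the warm-cold preset's best-model $r^2$, Schwarz weight and
free-running prediction correlation.
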