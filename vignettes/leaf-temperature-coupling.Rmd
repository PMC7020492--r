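---
title: "Coupling a leaf energy budget into a pasture heat-stress model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling a leaf energy budget into a pasture heat-stress model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasturetemp)
```

## Why leaf temperature, not air temperature

Biophysical pasture models are almost always driven by air temperature, yet
a transpiring leaf is routinely a degree or two cooler than hot air and
warmer than cool air ("limited homeothermy").  When a species' heat-stress
onset sits at 30 °C of the daily maximum, that one or two degrees decides
whether a simulated sward is stressed at all.  `pasturetemp` computes leaf
temperature from ordinary weather variables with a leaf energy budget,
substitutes it for the daily maximum air temperature in a minimal pasture
growth model, and quantifies how much the choice of temperature changes the
simulated growth.

## The energy budget

The leaf temperature solver uses the Penman-linearized energy budget in
molar units:

$$T_l = T_a + \frac{\gamma^*}{s + \gamma^*}
  \left[\frac{R_{ni}}{g_{Hr} C_p} - \frac{D}{P_a\,\gamma^*}\right]$$

with

* $R_{ni}$ — isothermal net radiation, $SW_{abs} + LW_{in} -
  \epsilon\sigma T_a^4$, i.e. the radiation load the leaf would experience
  if it sat exactly at air temperature.  Using the isothermal form removes
  the unknown $T_l$ from the radiation term; the residual dependence is
  carried by the radiative conductance.
* $g_{Hr} = g_{Ha} + g_r$ — boundary-layer plus radiative conductance for
  heat.  Forced-convection forms are used:
  $g_{Ha} = 1.4 \cdot 0.135\sqrt{u/d}$,
  $g_{va} = 1.4 \cdot 0.147\sqrt{u/d}$ mol m⁻² s⁻¹, where $d = 0.72\times$
  the maximum leaf width in the direction of wind flow.
* $g_v$ — whole-leaf vapour conductance; each surface's stomatal
  conductance is combined in series with the boundary layer and the two
  surfaces sum.  Grasses are amphistomatous (both surfaces); dicots such as
  chicory are hypostomatous (abaxial term only), which halves the vapour
  path and is why broad hypostomatous leaves run hotter.
* $\gamma^* = \gamma\, g_{Hr}/g_v$ — apparent psychrometric constant, with
  $\gamma = 6.66\times10^{-4}$ C⁻¹ at 101.3 kPa, scaled by pressure.
* $s$ — slope of the saturation mole fraction, $(de_s/dT)/P_a$, from the
  closed form $e_s(T) = 0.611\exp(17.502\,T/(T+240.97))$ kPa.

A closed-stomata leaf ($g_v = 0$) is handled as the $\gamma^*\to\infty$
limit, $T_l = T_a + R_{ni}/(g_{Hr}C_p)$, rather than as an error.

### Checking the linearization

Linearizing $e_s(T_l)$ and $\sigma T_l^4$ about $T_a$ is an approximation,
so the package carries an independent oracle:
`energy_balance_oracle()` solves the full nonlinear balance
$R_{abs} - \epsilon\sigma T_l^4 - C_p g_{Ha}(T_l - T_a) -
\lambda g_v (e_s(T_l) - e_a)/P_a = 0$ by bisection on
$[T_a - 20, T_a + 20]$ to a residual below $10^{-3}$ W m⁻².  The test suite
sweeps a 500-point grid of air temperature (15–40 °C), stomatal conductance
(0.005–0.4 mol m⁻² s⁻¹) and vapour pressure deficit (0–3 kPa) and requires
agreement within 0.5 °C.  In practice agreement is better than 0.05 °C over
most of the grid.

```{r oracle}
w <- weather_record(t_air = 30, rh = 70, ppfd = 900, wind = 2)
tr <- leaf_traits(max_leaf_width = 0.005, gs_abaxial = 0.4)
c(linearized = leaf_temperature(w, tr)$t_leaf,
  nonlinear = energy_balance_oracle(w, tr))
```

### Radiation bookkeeping and its open choices

Several radiation conventions are not fixed by the physics and were chosen
once:

* **PPFD to shortwave.**  Chamber light is given as PPFD; it is converted
  with the quantum-to-energy factor 4.6 µmol J⁻¹ and multiplied by a
  shortwave absorptivity (default 0.5) plus an optional `nir_fraction`
  top-up (default 0, treating high-pressure sodium chamber lamps as
  PAR-dominated).  Both are fields of `leaf_traits()`.
* **Long-wave environment.**  In `"chamber"` mode the walls are assumed
  black at air temperature ($LW_{in} = \sigma T_a^4$); in `"field"` mode a
  clear-sky atmospheric emissivity $\epsilon_a = 9.2\times10^{-6}(T_a +
  273.15)^2$ is used.
* **Area basis.**  All radiation terms are per unit one-sided leaf area,
  with the "one-sided heated" 1.4 enhancement already inside
  $g_{Ha}$/$g_{va}$, so the $R_{ni}/g_{Hr}$ pairing is self-consistent.
* **Still air.**  Wind below 0.1 m s⁻¹ is floored to 0.1 (a free-convection
  stand-in) to avoid the $\sqrt{u}$ singularity.
* **Daily driver.**  For field series the budget is evaluated once per day
  at daily-maximum conditions: $T_a = T_{max}$, midday shortwave equal to
  the daily total spread sinusoidally over the daylight hours
  ($SW_{mid} = MJ \times 10^6 \pi / (2\,\mathrm{daylength_s})$), and $D$
  from the day's vapour pressure at $T_{max}$.  Only the daily maximum is
  ever substituted; minima are left untouched.

## The pasture model

The growth model is deliberately minimal — a four-factor multiplicative
daily model, not a full biophysical simulator (no nutrient cycling,
grazing, tillering or canopy light interception):

$$\Delta B = \max\left(0,\; P_{max}\; f_T(T_{mean})\; GLF_W\;
  S_{HT}\; f_L(I)\right)$$

* $f_T$ — trapezoid: zero at ≤ 5 °C, optimal on 15–23 °C, declining to zero
  at 35 °C (temperate pasture cardinal temperatures).
* $GLF_W$ — growth-limiting factor for water from a single-bucket soil:
  available water is depleted by $PET \times GLF_W$ and refilled by rain
  and irrigation; $GLF_W = \min(1, AW / (0.5\,PAWC))$.  Default plant
  available water capacity is 150 mm.
* $S_{HT}$ — high-temperature stress coefficient: 1 until the daily maximum
  strictly exceeds 30 °C, falling linearly to 0 at 35 °C.  On stressed days
  the running coefficient is pulled down (never up) and the recovery
  accumulator resets.
* $f_L$ — saturating light response $I/(I + I_{1/2})$ on daily radiation
  with $I_{1/2} = 5$ MJ m⁻² d⁻¹.

$P_{max}$ (150 kg C ha⁻¹ d⁻¹), the light response and the carbon-to-DM
factor (2.5) are calibration knobs; every comparison the package reports is
a response ratio or a relative difference in which they largely cancel.

### T-sum recovery

After a stress spell ends, each stress-free day contributes
$\max(0, 25 - T_{mean})$ heat units; the coefficient returns linearly from
its stressed value to 1 as the accumulated units reach the `t_sum`
parameter.  A day with a mean of 20 °C therefore contributes 5 units, and
with the default `t_sum = 100` full recovery takes exactly 20 such days.
The worked-example semantics (cooler days recover *faster*) force the
$\max(0, base - T_{mean})$ form; the linear partial-recovery interpolation
is this package's choice, since the reference model's internal curve is not
public.  `t_sum = 20` versus `t_sum = 50` is the comparison of scientific
interest: under the severe chamber regime, 20 restores the sward within a
7-day recovery phase while 50 leaves it visibly lagged.

### Management

* **Irrigation.**  50 mm is applied when cumulative PET minus rainfall over
  the trailing five days strictly exceeds 25 mm (applied irrigation counts
  against the running deficit).  Because a slow drizzle-season leak can
  drain the bucket without ever tripping a 5-day atmospheric deficit, the
  irrigated mode additionally tops the bucket up to the no-limitation level
  whenever it would otherwise drop below it — irrigated pasture is managed
  so that no water stress occurs, which is also what makes the irrigated
  leaf-temperature rule ($g_s = 0.4$ throughout) consistent.
* **Cutting.**  Standing biomass is harvested to a residual of
  1.4 t DM ha⁻¹ on the last day of each month.

## The two-pass coupling

Soil water status is not known before the model runs, so stomatal
conductance for the energy budget comes from a first pass driven by air
temperature:

1. run the model on air temperature and extract daily $GLF_W$;
2. allocate a stomatal conductance to each day by bin lookup (0.005 mol
   m⁻² s⁻¹ at $GLF_W \le 0.1$ up to 0.4 at $GLF_W > 0.9$; irrigated runs
   always use 0.4);
3. compute each day's leaf temperature and substitute it for $T_{max}$;
4. re-run the model.

$GLF_W$ is *not* iterated to convergence by default — the two-step
procedure is the method being studied — but `iterate` in
`two_pass_simulate()` adds fixed-point passes for sensitivity checks.

## Evaluation statistics

`adequacy_stats()` implements the agreement suite: mean bias (measured −
modelled, so over-prediction is negative), $R^2$ and Pearson's $r$, mean
prediction error (RMSE as a percentage of the observed mean; < 5 % is
excellent — other MPE variants exist, this one matches that usage),
modelling efficiency, variance ratio ($sd_{obs}/sd_{pred}$, so values below
1 mean the model over-disperses), Lin's bias-correction factor $C_b$, and
the concordance correlation coefficient $CCC = r\,C_b$.  The identity
$CCC = 2 s_{xy}/(s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ is used as an
independent cross-check in the tests.  `homeothermy_test()` regresses leaf
on air temperature and tests the slope against 0 and 1; an exact linear
relation (zero residual error) short-circuits the t-tests.

## Synthetic data: what it does and does not emulate

`chamber_weather()` reproduces the controlled-environment design: three
regimes (25/15, 30/20, 35/25 °C day/night) over a 35-day schedule of five
7-day phases (pre-treatment, treatment, recovery, treatment, recovery),
3-hour temperature ramps (the daily mean is the time-weighted trapezoid
mean), RH 70 %, PPFD 900 µmol m⁻² s⁻¹, wind 2 m s⁻¹.  The regime
temperatures are applied during the treatment phases and the control
temperatures otherwise; that is the only reading under which severe-stress
recovery phases can recover at all, and it matches the observed recovery
dynamics.  `watering_schedule()` encodes the watering arms: well-watered
plants at $GLF_W = 1$ throughout; water-stressed plants dry down during
each treatment from 1 on day 1 to 0.05 on day 7 (linear by default,
exponential available) and are re-watered in recovery.  The true dry-down
trajectory is only known graphically, so the shape is a configurable
placeholder.

`field_weather()` generates seeded multi-year daily weather with
southern-hemisphere sinusoidal seasonality, AR(1) temperature noise, Markov
rainfall occurrence with exponential amounts, and consistent radiation,
PET, humidity, vapour pressure and wind.  The warm-temperate profile is
hotter and drier than the cool-temperate one (more summer days above
30 °C); the parameters caricature a high-rainfall cool temperate and a
medium-rainfall warm temperate site and claim no fidelity to any real
station.  Consequently, passing tests demonstrate internal consistency and
the direction of the leaf-versus-air effects, not agreement with any
historical yield record.

```{r field, fig.width = 6, fig.height = 3}
res <- run_experiment(list(mode = "field", site = "warm-temperate",
                           n_years = 3, seed = 7,
                           management = "irrigated", t_sum = 20))
knitr::kable(res$by_month, digits = 2)
```

The irrigated warm-site uncertainty is largest in mid-summer, when
transpirational cooling keeps leaves below the 30 °C onset that air
temperature crosses — the same direction and seasonality as in the field
simulations the method was developed for (where irrigated summer months
showed tens-of-percent increases).  The magnitudes here depend on the
synthetic climate and the simplified growth model and are not comparable
site estimates.

## Numerical choices and degenerate inputs

* Saturation vapour pressure is valid on −20 … 60 °C; outside it the
  functions raise range errors rather than extrapolate.
* The bisection oracle errors informatively if the ±20 °C bracket contains
  no sign change (it reports the endpoint residuals).
* `glf_w` exactly on a lookup-bin edge belongs to the lower bin's upper
  edge (bins are left-open), so 0.1 maps to 0.005 and 1.0 to 0.4.
* The irrigation trigger is strict (deficit exactly 25 mm does not
  trigger); windows shorter than 5 days never trigger.
* Zero-variance series are rejected by `adequacy_stats()` and
  `homeothermy_test()` as degenerate rather than returning NaNs.

## Problem sizes

The test suite and the reproduction script are sized for a desk run: the
linearization sweep uses a 500-point grid, homeothermy simulations n = 294,
field workflows 3–6 synthetic years.  All generators are pure functions of
their seed, so every number in the tests is reproducible bit for bit.

## Known limitations

* Leaf, not canopy: no mutual shading, soil heat storage or canopy
  conductance, so field leaf temperatures are upper-leaf estimates.
* The growth model's absolute rates are calibration-dependent; only
  relative comparisons (response ratios, percentage uncertainty) are
  meaningful.
* The GLF-to-conductance lookup is a step function of ten bins; days near
  bin edges can flip conductance with tiny GLF changes.
* Measured-data statistics from thermal imagery (e.g. the 0.88 homeothermy
  slope) are represented by parameter-recovery simulations, not reproduced
  from data.
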