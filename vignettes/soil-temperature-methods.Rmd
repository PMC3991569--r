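---
title: "Methods: empirical soil-temperature modelling under snow"
author: "soiltemp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical soil-temperature modelling under snow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

`soiltemp` simulates daily soil temperature at a single depth as a
two-way relaxation: toward the air temperature above, attenuated by the
snowpack, and toward a constant lower-boundary temperature below.

$$T_{t+1} = T_t + \alpha\,(T_{AIR,t} - T_t) + \beta\,(T_{LOW} - T_t)$$

$$\alpha = \min\!\Big(1, \frac{\Delta t\,K_T}{C_A\,(2Z_S)^2}\Big)\,
  e^{-f_S D_S/1000}, \qquad
  \beta = \min\!\Big(1, \frac{\Delta t\,K_{T,LOW}}{C_{S,LOW}\,(2Z_l)^2}\Big)$$

This is an empirical reduction of the coupled water–heat conduction
problem in seasonally frozen soil. The reductions, and the assumptions
they carry, are:

- **No soil-moisture dynamics.** Thermal conductivity and heat capacity
  are constants over the simulation, so the model loses validity under
  very wet or very dry conditions. That limitation is inherited
  deliberately: the point of the model is to be drivable by air
  temperature and snow depth alone.
- **Latent heat as an apparent capacity.** Freezing and thawing are not
  tracked as an ice-content state; instead, whenever the previous-day
  soil temperature is at or below the ice threshold (default 0 °C) the
  heat capacity switches from $C_S$ to $C_S + C_{ICE}$. The switch is on
  the *previous* step's temperature, keeping the update explicit. The
  boundary case ($T_t$ exactly at the threshold) counts as frozen, the
  conservative choice since latent buffering is strongest at the freezing
  point.
- **Snow as a bulk exponential insulator.** The air coupling is damped by
  $e^{-f_S D_S/1000}$; snow depth in mm is converted to metres inside the
  factor so that $f_S$ in m$^{-1}$ (sampling range 0–10) produces sensible
  damping for decimetre snowpacks — e.g. 0.6 m of snow at $f_S = 5$ damps
  the coupling by $e^{-3} \approx 0.05$. The exponent is always
  non-positive: insulation can only weaken the coupling. The
  lower-boundary term is *not* snow-damped, since heat exchange with the
  deeper profile does not pass through the snowpack.
- **Lower boundary as a constant reservoir.** $T_{LOW}$ is treated as a
  calibrated constant (sampling range 0–1 °C, the typical deep-soil range
  at snow-dominated sites). The lower term uses the denominator
  $(2Z_l)^2$ by analogy with the surface term, with $Z_l$ the depth
  coordinate of the lower influence (default $2Z_S$). Setting
  $K_{T,LOW}=0$ removes the extension entirely and recovers the simpler
  surface-only model; additionally $f_S = 0$ recovers the bare
  air-coupling recursion. These nestings are exact, not approximate, and
  are asserted in the tests.

**Stability clamp.** For thin layers the raw fraction
$\Delta t\,K_T / (C_A (2Z_S)^2)$ exceeds 1 over much of the physical
parameter range (a 1 cm layer reaches it at $K_T \approx 0.001$). Each
fraction is therefore capped at 1, and if the damped $\alpha$ plus
$\beta$ still exceed 1 the pair is rescaled proportionally. Every update
is then a convex combination of $T_t$, $T_{AIR}$ and $T_{LOW}$, which
gives three properties the test-suite checks over thousands of random
parameter draws: boundedness between the driving temperatures, monotone
weakening of the step with snow depth, and geometric convergence under
constant forcing to the closed-form fixed point
$(\alpha a + \beta T_{LOW})/(\alpha+\beta)$. The proportional rescaling
preserves the fixed point because it preserves the $\alpha/\beta$ ratio.

**Initialisation.** $T_{init}$ defaults to the mean air temperature of
the first 14 forcing days — a cheap, unbiased guess of the shallow-soil
state. A 365-day spin-up (the default in calibration and the CLI) lets
the recursion forget it; with relaxation fractions of order $10^{-1}$ the
memory of the initial condition is gone within weeks.

## Parameters

| Parameter | Unit | Sampling range | Role |
|---|---|---|---|
| $C_S$ | J m⁻³ °C⁻¹ | 0.5–3.5 × 10⁶ | soil heat capacity |
| $K_T$ | W m⁻¹ °C⁻¹ | 0–1 | air–soil coupling rate |
| $C_{ICE}$ | J m⁻³ °C⁻¹ | 4–15 × 10⁶ | latent (freeze–thaw) capacity |
| $f_S$ | m⁻¹ | 0–10 | snow insulation strength |
| $T_{LOW}$ | °C | 0–1 | lower-boundary temperature |
| $K_{T,LOW}$ | W m⁻¹ °C⁻¹ | 0–1 | lower coupling rate |
| $C_{S,LOW}$ | J m⁻³ °C⁻¹ | 0.5–3.5 × 10⁶ | lower heat capacity |

Only the ratio $K_T/C_S$ (and likewise $K_{T,LOW}/C_{S,LOW}$) enters the
unfrozen dynamics, so the calibration is structurally equifinal: many
parameter sets fit equally well. This is not a defect to be engineered
away but a property to be diagnosed, which is what the posterior-CDF
sensitivity analysis does. $K_T$ is typically the most constrained
parameter; $C_{ICE}$ and $f_S$ are informative only in winters with
frozen soil and snow respectively.

A note on units: the coupling formulation treats $K_T$ in
W m⁻¹ °C⁻¹ throughout, the dimensionally consistent choice for a
conductivity entering $\Delta t K_T / (C (2Z)^2)$.

## Calibration

The Monte Carlo calibration draws each parameter independently and
uniformly from its range — no Latin hypercube, no correlation structure —
simulates each set over the identical forcing, and scores it with
Nash–Sutcliffe efficiency on the calibration window. Observations are
split by *count*, not by date: the first $\lceil 2n/3 \rceil$ non-missing
days form the calibration window, the rest validation. Counting
observations keeps the split meaningful for gappy series, and missing
days are excluded pairwise from every score. Validation skill is reported
as NS, $R^2$ (squared Pearson correlation) and RMSE but does not enter
the ranking; ranking uses calibration NS alone, because validation
metrics are a performance report, not a selection criterion. Ties are
broken by run index (lower first) so results are reproducible
bit-for-bit from the seed. The top 100 runs form the behavioral set; the
top 5000 feed the posterior CDFs, with each parameter normalised to
$[0,1]$ over its sampling range so the uniform prior is the diagonal and
the Kolmogorov–Smirnov distance from it is a direct sensitivity index.

The simulation engine is vectorised across parameter sets (the day loop
is the only sequential part) and the run matrix is processed in blocks of
5000, so the full 100 000-run calibration is feasible on one CPU and the
20 000-run recovery experiment used in the tests takes seconds.

## Bias correction

Distribution mapping fits parametric CDFs per calendar month — Gaussian
(mean, sd) for temperature, maximum-likelihood Gamma (shape, scale) for
wet-day precipitation — to the observed and climate-model control series,
then corrects any scenario value through
$F_{obs}^{-1}(F_{contr}(x))$. Choices made where the method leaves room:

- **Monthly windows.** Fitting per calendar month is what makes
  month-resolved change analysis meaningful, and is the standard variant
  of the method for seasonal climates.
- **Wet-day threshold 0.1 mm.** Days at or below it map to 0; only wetter
  days enter the Gamma fit. A fit window needs at least 30 usable values,
  otherwise the fit aborts naming the month and count. An optional
  wet-day frequency adaptation is not enabled by default.
- **Tail clipping.** CDF arguments are clipped to
  $[10^{-6}, 1 - 10^{-6}]$, so a scenario value beyond anything seen in
  the control period maps to a finite extreme quantile rather than an
  extrapolated tail. This sacrifices extreme-value fidelity for
  robustness, which is the right trade for monthly-mean impact analysis.
- **Variables are corrected independently** (the transfer is univariate);
  cross-variable dependence, e.g. temperature–precipitation correlation,
  passes through from the scenario series untouched.

The defining round-trip property — correcting the control series
reproduces the observed distribution's fitted parameters — is exact for
the Gaussian branch (the transfer is affine) and holds to fit tolerance
for the Gamma branch; the tests assert observed monthly means are
reproduced within 0.1 °C over 30 synthetic years.

## Snowpack and synthetic weather

Scenario-period snow depth is generally unobserved, so a single-layer
degree-day snowpack closes the loop: precipitation on days below
`T_thresh` (0 °C) accumulates as snow water equivalent, melt is
`melt_factor` (3 mm °C⁻¹ day⁻¹) times the excess above the threshold,
capped at the stock, and depth is SWE divided by a bulk density ratio
(0.25). These defaults are mid-range literature values for boreal
seasonal snowpacks. The model conserves mass exactly and is togglable off
whenever observed snow depth exists; projections driven by modelled snow
are conditional on it, and rain–snow partitioning around the freezing
point is the single largest structural uncertainty in warm-winter
scenarios.

The weather generator produces `T_AIR` as an annual sinusoid plus AR(1)
noise, and precipitation as Bernoulli wet days with Gamma amounts. Its
defaults emulate a middle-boreal site: annual mean 2.4 °C, seasonal
amplitude 12 °C (monthly means from about −10 °C to +14 °C), AR(1)
coefficient 0.7 with marginal sd 3 °C, wet-day probability 0.45 with
Gamma(0.8, 4.4) amounts giving ≈ 580 mm yr⁻¹. The noise is parameterised
by its *marginal* standard deviation so changing the persistence does not
change the spread. What the generator does **not** emulate: weather-front
structure beyond lag-1 persistence, seasonal heteroscedasticity (real
boreal winters are more variable than summers), temperature–precipitation
correlation, and multi-year climate variability. Passing the recovery
tests therefore shows the calibration machinery is sound — it does not
show the model will reach the same skill on real observations, where
structural error joins observation noise.

## Problem sizes in the tests and acceptance script

The recovery experiment uses 3 scored years after a 1-year spin-up,
0.3 °C observation noise, 10 % missing days and 20 000 Monte Carlo runs —
enough for the best run to exceed NS 0.95, for the behavioral median of
$K_T$ to land within ±0.2 W m⁻¹ °C⁻¹ of truth, and for the
sensitive/insensitive KS contrast between $K_T$ and $C_{ICE}$ to be
unambiguous, while keeping a full suite run in tens of seconds. The
bias-correction round trip uses 30 synthetic years (≈ 390 values per
month window); the pipeline smoke test calibrates 2000 runs and projects
a three-member pseudo-ensemble. `scripts/acceptance.R` reruns all three
studies from a single seed.

## Known limitations

- Constant thermal properties: no soil-moisture feedback, so very wet or
  very dry spells are outside the model's validity.
- A single constant $T_{LOW}$ cannot represent deep-soil seasonality;
  the extension improves mid-profile simulations, not deep ones.
- The apparent-capacity switch is binary at the threshold; real latent
  buffering is spread over a freezing range of a degree or so.
- Degree-day snow has no energy balance, canopy interception or
  compaction; snow density is constant.
- Behavioral projection reduces 100 runs to a per-day median — robust,
  but it discards parameter-uncertainty spread within a member; the
  across-member ensemble spread is retained in the delta tables. Annual
  standard deviations are computed across days within each year (the
  within-year seasonal spread), matching how annual summaries are usually
  drawn with error bars.
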