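# soiltemp

Snow cover decouples soil temperature from air temperature: an insulated
boreal soil can sit near 0 °C through a −20 °C winter, and the response of
soils to a warming climate therefore cannot be read off air-temperature
projections alone. `soiltemp` is an R toolkit for studying this problem in
seasonally frozen, snow-covered forest soils. It provides

- an empirical daily-timestep **soil-temperature model** with exponential
  snow-insulation damping, an apparent (latent-heat) heat capacity for
  frozen soil, and a lower-boundary heat-flow extension;
- **distribution-mapping (quantile-mapping) bias correction** of climate-model
  temperature and precipitation series onto local observations;
- **Monte Carlo calibration** with Nash–Sutcliffe scoring, posterior-CDF
  parameter-sensitivity analysis and behavioral-run selection;
- a degree-day **snowpack model** and a synthetic **weather generator** for
  building test fixtures with known truth;
- **ensemble projection** summaries (monthly/seasonal/annual deltas,
  ensemble medians) and a command-line interface.

It is aimed at catchment and climate-impact modellers who need a
defensible, fast soil-temperature component rather than a full coupled
water–heat PDE solver.

## The model

Soil temperature `T` at layer depth `Z_S` is advanced one day at a time:

```
T(t+1) = T(t) + α · (T_AIR − T(t)) + β · (T_LOW − T(t))

α = min(1, Δt·K_T / (C_A · (2 Z_S)²)) · exp(−f_S · D_S / 1000)
β = min(1, Δt·K_T_LOW / (C_S_LOW · (2 Z_l)²))
C_A = C_S                (T(t) above the ice threshold)
      C_S + C_ICE        (at or below it)
```

with `Δt = 86 400 s`, air temperature `T_AIR` (°C), snow depth `D_S` (mm),
thermal conductivity `K_T` (W m⁻¹ °C⁻¹), volumetric heat capacity `C_S`
(J m⁻³ °C⁻¹), latent-part capacity `C_ICE`, empirical snow parameter `f_S`
(m⁻¹), and a constant lower-boundary temperature `T_LOW` whose influence
enters through `K_T_LOW`, `C_S_LOW` and the depth coordinate `Z_l`. If
`α + β > 1` both are scaled proportionally, so every update is a convex
combination of `T(t)`, `T_AIR` and `T_LOW` — the simulated temperature is
always bounded by its drivers. Setting `K_T_LOW = 0` recovers the
snow-damped surface model, and additionally `f_S = 0` the bare
air-coupling recursion.

Bias correction follows the distribution-mapping transfer
`x → F_obs⁻¹(F_contr(x))` fitted per calendar month — Gaussian CDFs for
temperature, Gamma CDFs for wet-day precipitation (wet-day threshold
0.1 mm). Calibration samples the seven parameters independently and
uniformly from their physical ranges (e.g. `K_T` 0–1 W m⁻¹ °C⁻¹, `C_S`
0.5–3.5 × 10⁶ J m⁻³ °C⁻¹), scores each run with Nash–Sutcliffe efficiency
on the first two-thirds of non-missing observations, and keeps the top 100
runs as the behavioral set for projection.

## Worked example

A parameter-recovery experiment: simulate a middle-boreal site with known
parameters, add 0.3 °C observation noise and 10 % missing days, then
calibrate blind and project a +3 °C scenario.

```r
library(soiltemp)

params <- soil_layer_params(C_S = 2e6, K_T = 0.5, C_ICE = 8e6, f_S = 5,
                            T_LOW = 0.5, K_T_LOW = 0.3, C_S_LOW = 2e6,
                            Z_S = 0.1)
weather <- simulate_snowpack(
  generate_synthetic_weather(weather_gen_params(seed = 42), n_years = 4))
config <- simulation_config(spinup_days = 365)
fixture <- generate_soil_fixture(weather, params, obs_noise_sd = 0.3,
                                 missing_frac = 0.1, seed = 43,
                                 config = config)

calib <- run_monte_carlo(fixture$observations, weather, n_runs = 5000,
                         seed = 44, Z_S = 0.1, config = config)
calib
#> Monte Carlo calibration: 5000 runs (seed 44 )
#>   best calibration NS 0.9972 (validation NS 0.9968, RMSE 0.303)

behavioral <- select_behavioral(calib, 100)
median(behavioral$K_T)               # truth was 0.5
#> [1] 0.5946124
ks_distance_uniform(calib, "K_T", 2000)    # sensitive parameter
#> [1] 0.21
ks_distance_uniform(calib, "C_ICE", 2000)  # insensitive parameter
#> [1] 0.039

scen <- weather; scen$t_air <- scen$t_air + 3; scen$d_s <- NULL
scen <- simulate_snowpack(scen)       # snowpack re-derived from warm climate
proj <- run_ensemble(behavioral, list(warm3 = scen), weather,
                     Z_S = 0.1, config = config)
seasonal_rollup(subset(proj$deltas, member == "warm3"))
#>   season      delta
#> 1    DJF -0.1716593
#> 2    MAM  1.7681287
#> 3    JJA  2.5950140
#> 4    SON  2.0907890
```

The calibration recovers the fit almost perfectly (NS ≈ 0.997) and
concentrates the thermal conductivity near its generating value while
leaving the latent-heat capacity unconstrained — the classic
sensitive/insensitive (equifinality) contrast. The projection shows the
snow effect this package exists for: under +3 °C of air warming the
*winter* soil barely changes (here it even cools slightly, because the
insulating snowpack shrinks) while spring–autumn soils warm by 1.8–2.6 °C.

## Command-line interface

`inst/cli/soiltemp.R` wraps the same functions:

```sh
Rscript inst/cli/soiltemp.R make-fixtures --config site.yml --out-dir fixtures
Rscript inst/cli/soiltemp.R calibrate --config site.yml \
    --forcing fixtures/forcing.csv --obs fixtures/observations.csv \
    --out-dir calib --n-runs 100000 --seed 1
Rscript inst/cli/soiltemp.R bias-correct --obs-forcing obs.csv \
    --control-forcing control.csv --scenario-forcing scenario.csv \
    --out scenario_bc.csv
Rscript inst/cli/soiltemp.R project --config site.yml \
    --behavioral calib/behavioral.csv --control-forcing obs.csv \
    --scenario-forcings m1.csv,m2.csv --out-dir proj
```

Site configuration is a small YAML file (site name, layer depths in cm,
snow-model and simulation settings); depths are converted to metres at
load and a 0 cm surface layer is simulated as 1 cm.

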