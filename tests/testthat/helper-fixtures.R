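# Shared fixtures: a reference parameter set, snowpack-filled synthetic
# weather, and a site-config file for CLI tests. Everything is generated
# in code under fixed seeds.

ref_params <- function(...) {
  defaults <- list(C_S = 2e6, K_T = 0.5, C_ICE = 8e6, f_S = 5, T_LOW = 0.5,
                   K_T_LOW = 0.3, C_S_LOW = 2e6, Z_S = 0.1)
  do.call(soil_layer_params, utils::modifyList(defaults, list(...)))
}

test_weather <- function(n_years = 4, seed = 101, ...) {
  wg <- weather_gen_params(seed = seed, ...)
  simulate_snowpack(generate_synthetic_weather(wg, n_years))
}

# Independent uniform draw from the default Monte Carlo ranges.
draw_params <- function(Z_S = 0.1) {
  r <- parameter_ranges()
  soil_layer_params(
    C_S = runif(1, r$C_S[1], r$C_S[2]),
    K_T = runif(1, r$K_T[1], r$K_T[2]),
    C_ICE = runif(1, r$C_ICE[1], r$C_ICE[2]),
    f_S = runif(1, r$f_S[1], r$f_S[2]),
    T_LOW = runif(1, r$T_LOW[1], r$T_LOW[2]),
    K_T_LOW = runif(1, r$K_T_LOW[1], r$K_T_LOW[2]),
    C_S_LOW = runif(1, r$C_S_LOW[1], r$C_S_LOW[2]),
    Z_S = Z_S)
}

write_test_config <- function(dir, n_years = 4, seed = 11,
                              obs_noise_sd = 0.3, missing_frac = 0.1) {
  path <- file.path(dir, "site.yml")
  cfg <- list(
    site = "Synthetic North",
    depths_cm = list(top = 10, middle = 29, bottom = 40),
    seed = seed,
    weather = list(annual_mean_T = 2.4, seasonal_amplitude = 12,
                   n_years = n_years),
    snow = list(T_thresh = 0, melt_factor = 3, density_ratio = 0.25),
    truth = list(C_S = 2e6, K_T = 0.5, C_ICE = 8e6, f_S = 5, T_LOW = 0.5,
                 K_T_LOW = 0.3, C_S_LOW = 2e6),
    fixture = list(obs_noise_sd = obs_noise_sd,
                   missing_frac = missing_frac),
    simulation = list(spinup_days = 365)
  )
  yaml::write_yaml(cfg, path)
  path
}

# Straight-line reimplementation of one recursion step from the model
# formulas, kept deliberately separate from the package internals so it
# can serve as an oracle.
oracle_step <- function(T_prev, t_air, d_s, p, dt = 86400, thr = 0) {
  C_A <- if (T_prev > thr) p$C_S else p$C_S + p$C_ICE
  alpha <- min(1, dt * p$K_T / (C_A * (2 * p$Z_S)^2)) *
    exp(-p$f_S * d_s / 1000)
  beta <- min(1, dt * p$K_T_LOW / (p$C_S_LOW * (2 * p$Z_l)^2))
  s <- alpha + beta
  if (s > 1) {
    alpha <- alpha / s
    beta <- beta / s
  }
  T_prev + alpha * (t_air - T_prev) + beta * (p$T_LOW - T_prev)
}

oracle_trajectory <- function(T0, t_air, d_s, p, dt = 86400, thr = 0) {
  out <- numeric(length(t_air))
  T_cur <- T0
  for (i in seq_along(t_air)) {
    T_cur <- oracle_step(T_cur, t_air[i], d_s[i], p, dt, thr)
    out[i] <- T_cur
  }
  out
}
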