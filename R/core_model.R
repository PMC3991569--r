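#' Apparent heat capacity of the soil
#'
#' The volumetric heat capacity used in the daily recursion. Above the ice
#' threshold it is the plain soil capacity `C_S`; at or below the threshold
#' the latent contribution of freezing/thawing is added, giving
#' `C_S + C_ICE`. The larger frozen-side capacity slows temperature change,
#' which is how the model represents the latent-heat buffering of
#' freeze-thaw without tracking ice content.
#'
#' @param params A [soil_layer_params()] object.
#' @param T_prev Soil temperature at the previous step, degC (vectorised).
#' @param ice_threshold Switching temperature, degC (default 0).
#' @return Apparent heat capacity, J m^-3 degC^-1.
#' @export
#' @examples
#' p <- soil_layer_params(2e6, 0.5, 8e6, 5, 0.5, 0, 2e6, Z_S = 0.1)
#' apparent_heat_capacity(p, T_prev = c(5, -1, 0))
apparent_heat_capacity <- function(params, T_prev, ice_threshold = 0) {
  validate_soil_layer_params(params)
  ifelse(T_prev > ice_threshold, params$C_S, params$C_S + params$C_ICE)
}

#' Snow insulation damping factor
#'
#' Exponential attenuation `exp(-f_S * D_S / 1000)` of the air-soil
#' coupling by a snowpack of depth `d_s` millimetres. The depth is
#' converted to metres inside the factor so that `f_S` in m^-1 gives
#' physically sensible damping for decimetre snowpacks. The value lies in
#' (0, 1]: 1 for bare ground or `f_S = 0`, approaching 0 under deep snow.
#'
#' @param f_S Empirical snow parameter, m^-1 (non-negative).
#' @param d_s Snow depth, mm (non-negative; vectorised).
#' @return Dimensionless damping factor in (0, 1].
#' @export
#' @examples
#' snow_damping_factor(5, 100)  # exp(-0.5)
snow_damping_factor <- function(f_S, d_s) {
  if (any(f_S < 0)) stop("snow_damping_factor: f_S must be non-negative",
                         call. = FALSE)
  if (any(d_s < 0)) stop("snow_damping_factor: d_s must be non-negative",
                         call. = FALSE)
  exp(-f_S * d_s / 1000)
}

# Per-run relaxation fractions toward air and lower-boundary temperature.
# alpha_raw is capped at 1 before snow damping; beta likewise. When the
# damped alpha plus beta exceeds 1 the pair is scaled proportionally so the
# update stays a convex combination of T_prev, T_AIR and T_LOW (needed
# because a 1 cm layer drives dt*K_T/(C_A*(2 Z_S)^2) far above 1 over much
# of the sampling range).
relaxation_fractions <- function(dt, K_T, C_A, Z_S, K_T_LOW, C_S_LOW, Z_l,
                                 damp) {
  alpha <- pmin(1, dt * K_T / (C_A * (2 * Z_S)^2)) * damp
  beta <- pmin(1, dt * K_T_LOW / (C_S_LOW * (2 * Z_l)^2))
  s <- alpha + beta
  over <- s > 1
  if (any(over)) {
    alpha[over] <- alpha[over] / s[over]
    beta[over] <- beta[over] / s[over]
  }
  list(alpha = alpha, beta = beta)
}

#' One daily step of the soil-temperature recursion
#'
#' Advances the soil temperature one day:
#' `T_next = T_prev + alpha * (T_AIR - T_prev) + beta * (T_LOW - T_prev)`
#' where `alpha = min(1, dt * K_T / (C_A * (2 Z_S)^2)) * exp(-f_S * D_S/1000)`
#' couples the layer to the air through the snowpack, and
#' `beta = min(1, dt * K_T_LOW / (C_S_LOW * (2 Z_l)^2))` couples it to the
#' lower boundary (not snow-damped). `C_A` is the apparent heat capacity
#' evaluated at `T_prev`. If `alpha + beta > 1` both are scaled
#' proportionally so the update remains a convex combination, which bounds
#' `T_next` between the minimum and maximum of `T_prev`, `T_AIR`, `T_LOW`.
#'
#' @param T_prev Soil temperature at the previous day, degC.
#' @param t_air Air temperature for the day, degC.
#' @param d_s Snow depth for the day, mm.
#' @param params A [soil_layer_params()] object.
#' @param config A [simulation_config()] object (supplies `dt` and the ice
#'   threshold).
#' @return Soil temperature after the step, degC.
#' @export
#' @examples
#' p <- soil_layer_params(2e6, 0.5, 8e6, f_S = 0, T_LOW = 0, K_T_LOW = 0,
#'                        C_S_LOW = 2e6, Z_S = 0.1)
#' step_soil_temperature(5, t_air = 10, d_s = 0, p)  # 7.7
step_soil_temperature <- function(T_prev, t_air, d_s, params,
                                  config = simulation_config()) {
  validate_soil_layer_params(params)
  if (!is.finite(T_prev)) {
    stop("step_soil_temperature: T_prev must be finite", call. = FALSE)
  }
  C_A <- apparent_heat_capacity(params, T_prev, config$ice_threshold)
  damp <- snow_damping_factor(params$f_S, d_s)
  fr <- relaxation_fractions(config$dt, params$K_T, C_A, params$Z_S,
                             params$K_T_LOW, params$C_S_LOW, params$Z_l,
                             damp)
  T_prev + fr$alpha * (t_air - T_prev) + fr$beta * (params$T_LOW - T_prev)
}

# Vectorised engine: runs the recursion for many parameter sets at once
# over one forcing series. params_df has one row per run with the seven
# calibratable parameters plus Z_S and Z_l. Returns an (n_days x n_runs)
# matrix of soil temperatures, before spin-up removal. The day loop is the
# only sequential part; all per-run arithmetic is vectorised, which is what
# makes 1e4-1e5 Monte Carlo runs tractable.
simulate_matrix <- function(forcing, params_df, config = simulation_config(),
                            T_init = NULL) {
  check_contiguous(forcing$date)
  if (is.null(forcing$d_s)) {
    stop("simulate: forcing has no snow depth (d_s); supply observations ",
         "or fill it with simulate_snowpack()", call. = FALSE)
  }
  if (anyNA(forcing$t_air)) {
    stop("simulate: missing t_air within the simulated span", call. = FALSE)
  }
  if (anyNA(forcing$d_s)) {
    stop("simulate: missing d_s within the simulated span", call. = FALSE)
  }
  n_days <- nrow(forcing)
  if (n_days < 1) stop("simulate: empty forcing series", call. = FALSE)
  n_runs <- nrow(params_df)
  dt <- config$dt
  thr <- config$ice_threshold
  if (is.null(T_init)) T_init <- config$T_init
  if (is.null(T_init)) {
    T_init <- mean(forcing$t_air[seq_len(min(14L, n_days))])
  }

  Z_S <- params_df$Z_S
  Z_l <- params_df$Z_l
  # alpha before snow damping has two states only (frozen / unfrozen), so
  # both are precomputed per run.
  a_unfrozen <- pmin(1, dt * params_df$K_T / (params_df$C_S * (2 * Z_S)^2))
  a_frozen <- pmin(1, dt * params_df$K_T /
                        ((params_df$C_S + params_df$C_ICE) * (2 * Z_S)^2))
  beta0 <- pmin(1, dt * params_df$K_T_LOW /
                     (params_df$C_S_LOW * (2 * Z_l)^2))
  T_LOW <- params_df$T_LOW
  f_S <- params_df$f_S

  out <- matrix(NA_real_, n_days, n_runs)
  T_cur <- rep(T_init, n_runs)
  t_air <- forcing$t_air
  d_s_m <- forcing$d_s / 1000
  for (i in seq_len(n_days)) {
    frozen <- T_cur <= thr
    damp_i <- if (d_s_m[i] > 0) exp(-f_S * d_s_m[i]) else 1
    alpha <- ifelse(frozen, a_frozen, a_unfrozen) * damp_i
    beta <- beta0
    s <- alpha + beta
    over <- s > 1
    if (any(over)) {
      alpha[over] <- alpha[over] / s[over]
      beta[over] <- beta[over] / s[over]
    }
    T_cur <- T_cur + alpha * (t_air[i] - T_cur) + beta * (T_LOW - T_cur)
    out[i, ] <- T_cur
  }
  if (config$spinup_days > 0) {
    if (config$spinup_days >= n_days) {
      stop("simulate: spinup_days (", config$spinup_days,
           ") must be smaller than the forcing length (", n_days, ")",
           call. = FALSE)
    }
    out <- out[-seq_len(config$spinup_days), , drop = FALSE]
  }
  out
}

params_as_row <- function(params) {
  as.data.frame(unclass(params))
}

#' Simulate a daily soil-temperature series
#'
#' Iterates the daily recursion (see [step_soil_temperature()]) over a
#' contiguous forcing series, starting from `config$T_init` (by default the
#' mean air temperature of the first 14 forcing days) and dropping the
#' first `config$spinup_days` days from the output.
#'
#' @param forcing A [forcing_series()] with contiguous daily dates, no
#'   missing `t_air`, and a `d_s` column.
#' @param params A [soil_layer_params()] object.
#' @param config A [simulation_config()] object.
#' @return A data frame of class `soil_temperature_series` with columns
#'   `date` and `t_z` (simulated soil temperature at depth `Z_S`, degC),
#'   aligned to the forcing dates after spin-up removal.
#' @export
simulate_series <- function(forcing, params, config = simulation_config()) {
  validate_soil_layer_params(params)
  m <- simulate_matrix(forcing, params_as_row(params), config)
  date <- forcing$date
  if (config$spinup_days > 0) date <- date[-seq_len(config$spinup_days)]
  out <- data.frame(date = date, t_z = m[, 1])
  class(out) <- c("soil_temperature_series", "data.frame")
  out
}

#' @export
print.soil_temperature_series <- function(x, ...) {
  cat("Simulated soil temperature:", nrow(x), "days,",
      format(x$date[1]), "to", format(x$date[nrow(x)]), "\n")
  cat(sprintf("  range %.2f to %.2f degC\n", min(x$t_z), max(x$t_z)))
  invisible(x)
}
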