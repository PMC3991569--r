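#' Degree-day snowpack model parameters
#'
#' Settings for the single-layer degree-day snowpack model used to supply
#' snow depth when it is not observed (e.g. for scenario runs).
#'
#' @param T_thresh Rain/snow partition temperature, degC. Precipitation on
#'   days colder than this accumulates as snow; melt is proportional to the
#'   excess above it.
#' @param melt_factor Degree-day melt factor, mm SWE degC^-1 day^-1.
#' @param density_ratio Snowpack density relative to liquid water,
#'   dimensionless in (0, 1]; converts snow water equivalent (SWE) to snow
#'   depth as `D_S = SWE / density_ratio`.
#' @return An object of class `snow_model_params`.
#' @export
snow_model_params <- function(T_thresh = 0, melt_factor = 3,
                              density_ratio = 0.25) {
  if (melt_factor < 0) {
    stop("snow_model_params: melt_factor must be non-negative", call. = FALSE)
  }
  if (density_ratio <= 0 || density_ratio > 1) {
    stop("snow_model_params: density_ratio must be in (0, 1]", call. = FALSE)
  }
  structure(list(T_thresh = T_thresh, melt_factor = melt_factor,
                 density_ratio = density_ratio),
            class = "snow_model_params")
}

#' Simulate snow depth with a degree-day snowpack model
#'
#' Runs a single-layer snow water equivalent (SWE) balance over the
#' forcing series: on each day, precipitation falls as snow when
#' `t_air < T_thresh`, and melt removes
#' `min(stock, melt_factor * max(0, t_air - T_thresh))`. Snow depth is
#' `SWE / density_ratio` so it always satisfies the mass balance and never
#' goes negative. This is deliberately the minimal defensible snowpack
#' representation - a gap-filler for runs without observed snow depth, not
#' an energy-balance snow model.
#'
#' @param forcing A [forcing_series()] with `t_air` and `precip`.
#' @param params A [snow_model_params()] object.
#' @return The forcing series with its `d_s` column filled (mm).
#' @export
#' @examples
#' f <- forcing_series(as.Date("2001-01-01") + 0:2,
#'                     t_air = c(-5, -5, 2), precip = c(10, 0, 0))
#' simulate_snowpack(f, snow_model_params())$d_s  # 40 40 16
simulate_snowpack <- function(forcing, params = snow_model_params()) {
  if (is.null(forcing$precip)) {
    stop("simulate_snowpack: forcing has no precip column", call. = FALSE)
  }
  if (anyNA(forcing$t_air) || anyNA(forcing$precip)) {
    stop("simulate_snowpack: t_air and precip must have no missing values",
         call. = FALSE)
  }
  n <- nrow(forcing)
  swe <- numeric(n)
  stock <- 0
  for (i in seq_len(n)) {
    snow_in <- if (forcing$t_air[i] < params$T_thresh) forcing$precip[i] else 0
    stock <- stock + snow_in
    melt <- min(stock,
                params$melt_factor * max(0, forcing$t_air[i] - params$T_thresh))
    stock <- stock - melt
    swe[i] <- stock
  }
  forcing$d_s <- swe / params$density_ratio
  forcing
}

#' Synthetic weather generator parameters
#'
#' Settings for the sinusoid-plus-AR(1) daily weather generator used to
#' build test fixtures. The defaults emulate a middle-boreal site on the
#' northern Swedish climate gradient (annual mean near 2.4 degC, around
#' 580 mm/yr of precipitation).
#'
#' @param annual_mean_T Annual mean air temperature, degC.
#' @param seasonal_amplitude Amplitude of the seasonal sinusoid, degC.
#' @param ar1_coeff Lag-1 autocorrelation of the temperature noise, in
#'   `[0, 1)`.
#' @param noise_sd Marginal standard deviation of the AR(1) temperature
#'   noise, degC.
#' @param wet_day_prob Probability that a day is wet.
#' @param precip_gamma_shape,precip_gamma_scale Gamma parameters of wet-day
#'   precipitation amounts, mm.
#' @param peak_doy Day of year at which the seasonal sinusoid crosses its
#'   mean going up; the warmest day falls a quarter period (about 91 days)
#'   later.
#' @param seed Integer seed making the generated series reproducible.
#' @return An object of class `weather_gen_params`.
#' @export
weather_gen_params <- function(annual_mean_T = 2.4, seasonal_amplitude = 12,
                               ar1_coeff = 0.7, noise_sd = 3,
                               wet_day_prob = 0.45,
                               precip_gamma_shape = 0.8,
                               precip_gamma_scale = 4.4,
                               peak_doy = 110, seed = 1L) {
  if (noise_sd < 0) stop("weather_gen_params: noise_sd must be >= 0",
                         call. = FALSE)
  if (ar1_coeff < 0 || ar1_coeff >= 1) {
    stop("weather_gen_params: ar1_coeff must be in [0, 1)", call. = FALSE)
  }
  if (wet_day_prob < 0 || wet_day_prob > 1) {
    stop("weather_gen_params: wet_day_prob must be in [0, 1]", call. = FALSE)
  }
  if (precip_gamma_shape <= 0 || precip_gamma_scale <= 0) {
    stop("weather_gen_params: Gamma shape and scale must be > 0",
         call. = FALSE)
  }
  structure(list(annual_mean_T = annual_mean_T,
                 seasonal_amplitude = seasonal_amplitude,
                 ar1_coeff = ar1_coeff, noise_sd = noise_sd,
                 wet_day_prob = wet_day_prob,
                 precip_gamma_shape = precip_gamma_shape,
                 precip_gamma_scale = precip_gamma_scale,
                 peak_doy = peak_doy, seed = as.integer(seed)),
            class = "weather_gen_params")
}

#' Generate synthetic daily weather
#'
#' Produces a daily air-temperature and precipitation series:
#' `T_AIR = annual_mean_T + seasonal_amplitude *
#' sin(2 pi (doy - peak_doy) / 365.25) + AR(1) noise`, with precipitation
#' drawn as Bernoulli(wet_day_prob) times Gamma(shape, scale). The AR(1)
#' noise is parameterised by its marginal standard deviation, so the
#' day-to-day persistence (`ar1_coeff`) does not change the overall spread.
#' Calling `set.seed` internally, the output is fully determined by the
#' parameter object.
#'
#' @param params A [weather_gen_params()] object.
#' @param n_years Number of calendar years to generate (starting
#'   2001-01-01).
#' @return A [forcing_series()] with `t_air` and `precip` (no `d_s`; fill
#'   it with [simulate_snowpack()] if needed).
#' @export
generate_synthetic_weather <- function(params, n_years) {
  stopifnot(inherits(params, "weather_gen_params"), n_years >= 1)
  start <- as.Date("2001-01-01")
  end <- as.Date(sprintf("%d-12-31", 2000 + n_years))
  date <- seq(start, end, by = "day")
  n <- length(date)
  doy <- as.POSIXlt(date)$yday + 1
  seasonal <- params$annual_mean_T + params$seasonal_amplitude *
    sin(2 * pi * (doy - params$peak_doy) / 365.25)

  set.seed(params$seed)
  if (params$noise_sd > 0) {
    innov_sd <- params$noise_sd * sqrt(1 - params$ar1_coeff^2)
    e <- as.numeric(stats::arima.sim(list(ar = params$ar1_coeff), n,
                                     sd = innov_sd))
  } else {
    e <- numeric(n)
  }
  t_air <- seasonal + e
  wet <- stats::rbinom(n, 1, params$wet_day_prob)
  amount <- stats::rgamma(n, shape = params$precip_gamma_shape,
                          scale = params$precip_gamma_scale)
  forcing_series(date, t_air, precip = wet * amount)
}

#' Generate a synthetic soil-temperature observation fixture
#'
#' Runs the soil-temperature model with known ("true") parameters over a
#' synthetic weather series, adds Gaussian observation noise and masks a
#' fraction of days at random. The hidden truth is returned alongside, so
#' calibration code can be exercised as a parameter-recovery experiment.
#'
#' @param weather A [forcing_series()] with `d_s` filled.
#' @param true_params The generating [soil_layer_params()].
#' @param obs_noise_sd Observation noise standard deviation, degC.
#' @param missing_frac Fraction of days masked as missing (independently at
#'   random).
#' @param seed Integer seed for noise and masking.
#' @param config A [simulation_config()] for the truth simulation.
#' @return A list of class `soil_fixture` with elements `observations` (a
#'   data frame `date`, `value` with NAs at masked days), `clean` (the
#'   noise-free simulation) and `truth` (the generating parameters).
#' @export
generate_soil_fixture <- function(weather, true_params, obs_noise_sd = 0.3,
                                  missing_frac = 0, seed = 1L,
                                  config = simulation_config()) {
  stopifnot(missing_frac >= 0, missing_frac < 1, obs_noise_sd >= 0)
  sim <- simulate_series(weather, true_params, config)
  set.seed(as.integer(seed))
  value <- sim$t_z
  if (obs_noise_sd > 0) value <- value + stats::rnorm(length(value), 0,
                                                      obs_noise_sd)
  if (missing_frac > 0) {
    masked <- stats::runif(length(value)) < missing_frac
    value[masked] <- NA_real_
  }
  structure(list(observations = data.frame(date = sim$date, value = value),
                 clean = sim, truth = true_params),
            class = "soil_fixture")
}
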