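test_that("apparent heat capacity switches at the ice threshold", {
  p <- ref_params(C_S = 2e6, C_ICE = 8e6)
  expect_equal(apparent_heat_capacity(p, 5), 2e6)
  expect_equal(apparent_heat_capacity(p, -1), 1e7)
  # the boundary itself counts as frozen
  p2 <- ref_params(C_S = 0.5e6, C_ICE = 4e6)
  expect_equal(apparent_heat_capacity(p2, 0), 4.5e6)
})

test_that("snow damping factor is the mm-converted exponential", {
  expect_equal(snow_damping_factor(0, 500), 1)
  expect_equal(snow_damping_factor(5, 0), 1)
  expect_equal(snow_damping_factor(5, 100), exp(-0.5), tolerance = 1e-12)
  expect_error(snow_damping_factor(-1, 0), "non-negative")
  expect_error(snow_damping_factor(1, -5), "non-negative")
})

test_that("single steps match hand evaluation of the recursion", {
  p <- ref_params(f_S = 0, T_LOW = 0, K_T_LOW = 0)
  expect_equal(step_soil_temperature(5, 10, 0, p), 7.7)
  p_snow <- ref_params(T_LOW = 0, K_T_LOW = 0)
  expect_equal(step_soil_temperature(5, 10, 100, p_snow),
               5 + 0.54 * 5 * exp(-0.5), tolerance = 1e-9)
  # frozen branch: larger apparent capacity slows the step
  expect_equal(step_soil_temperature(-1, 5, 0, p), -0.352)
})

test_that("invalid parameters and inputs are rejected", {
  expect_error(soil_layer_params(-1, 0.5, 8e6, 5, 0.5, 0.3, 2e6, 0.1),
               "strictly positive")
  expect_error(soil_layer_params(2e6, -0.5, 8e6, 5, 0.5, 0.3, 2e6, 0.1),
               "non-negative")
  expect_error(soil_layer_params(2e6, 0.5, 8e6, 5, 0.5, 0.3, 2e6,
                                 Z_S = 0.1, Z_l = 0.05), "Z_l")
  expect_error(step_soil_temperature(NaN, 5, 0, ref_params()), "finite")
  expect_error(simulation_config(dt = 0), "dt")
})

test_that("simulate_series holds constant forcing at its fixed point", {
  days <- as.Date("2001-01-01") + 0:199
  f <- forcing_series(days, t_air = rep(4, 200), d_s = rep(0, 200))
  p <- ref_params(K_T_LOW = 0, f_S = 0)
  sim <- simulate_series(f, p, simulation_config(T_init = 4))
  expect_equal(sim$t_z, rep(4, 200))
  expect_equal(sim$date, days)
})

test_that("simulate_series drops spin-up and rejects forcing gaps", {
  f <- test_weather(2)
  sim <- simulate_series(f, ref_params(),
                         simulation_config(spinup_days = 100))
  expect_equal(nrow(sim), nrow(f) - 100)
  expect_equal(sim$date, f$date[-(1:100)])
  gap <- f[-5, ]
  expect_error(simulate_series(gap, ref_params()),
               format(f$date[4]))
  expect_error(simulate_series(f[0:0, ], ref_params()))
})

test_that("a multi-day run matches the independent manual recursion", {
  set.seed(42)
  t_air <- runif(10, -10, 15)
  d_s <- c(0, 0, 50, 120, 300, 300, 80, 0, 10, 0)
  days <- as.Date("2001-01-01") + 0:9
  f <- forcing_series(days, t_air, d_s = d_s)
  p <- ref_params()
  sim <- simulate_series(f, p, simulation_config(T_init = 5))
  expect_equal(sim$t_z, oracle_trajectory(5, t_air, d_s, p),
               tolerance = 1e-12)
})

test_that("snow-free and lower-free limits nest the simpler models exactly", {
  f <- test_weather(2, seed = 33)
  # f_S = 0 makes snow depth irrelevant
  p0 <- ref_params(f_S = 0)
  f_zero <- f
  f_zero$d_s <- 0
  expect_identical(simulate_series(f, p0, simulation_config())$t_z,
                   simulate_series(f_zero, p0, simulation_config())$t_z)
  # K_T_LOW = 0 and f_S = 0 reduce to the bare base recursion
  p_base <- ref_params(f_S = 0, K_T_LOW = 0)
  sim <- simulate_series(f, p_base, simulation_config(T_init = 2))
  base <- numeric(nrow(f))
  T_cur <- 2
  dt <- 86400
  for (i in seq_len(nrow(f))) {
    C_A <- if (T_cur > 0) p_base$C_S else p_base$C_S + p_base$C_ICE
    T_cur <- T_cur + min(1, dt * p_base$K_T / (C_A * (2 * p_base$Z_S)^2)) *
      (f$t_air[i] - T_cur)
    base[i] <- T_cur
  }
  expect_identical(sim$t_z, base)
})

test_that("every step is bounded by its three driving temperatures", {
  set.seed(7)
  for (i in 1:400) {
    p <- draw_params(Z_S = runif(1, 0.01, 0.6))
    T_prev <- runif(1, -15, 20)
    t_air <- runif(1, -25, 25)
    d_s <- runif(1, 0, 1500)
    T_next <- step_soil_temperature(T_prev, t_air, d_s, p)
    lo <- min(T_prev, t_air, p$T_LOW)
    hi <- max(T_prev, t_air, p$T_LOW)
    expect_gte(T_next, lo - 1e-12)
    expect_lte(T_next, hi + 1e-12)
  }
})

test_that("deeper snow weakens the pull away from the previous state", {
  set.seed(8)
  for (i in 1:200) {
    p <- draw_params()
    p$K_T_LOW <- 0  # isolate the snow-damped surface term
    T_prev <- runif(1, -10, 10)
    t_air <- runif(1, -20, 20)
    depths <- sort(runif(3, 0, 1200))
    disp <- vapply(depths, function(d) {
      abs(step_soil_temperature(T_prev, t_air, d, p) - T_prev)
    }, numeric(1))
    expect_true(all(diff(disp) <= 1e-12))
  }
})

test_that("frozen soil moves strictly slower than unfrozen soil would", {
  set.seed(9)
  for (i in 1:100) {
    p <- draw_params()
    T_prev <- runif(1, -10, -0.1)
    t_air <- runif(1, 2, 20)
    with_ice <- step_soil_temperature(T_prev, t_air, 0, p)
    no_ice <- p
    no_ice$C_ICE <- 1e-9  # effectively C_A = C_S
    without <- step_soil_temperature(T_prev, t_air, 0, no_ice)
    # skip the saturated regime where both fractions clamp to 1
    dt <- 86400
    a_raw <- dt * p$K_T / ((p$C_S + p$C_ICE) * (2 * p$Z_S)^2)
    if (a_raw < 1) {
      expect_lt(abs(with_ice - T_prev), abs(without - T_prev))
    }
  }
})

test_that("parameter JSON round-trips with exact field names", {
  p <- ref_params()
  path <- tempfile(fileext = ".json")
  write_layer_params(p, path)
  keys <- names(jsonlite::read_json(path))
  expect_setequal(keys, c("C_S", "K_T", "C_ICE", "f_S", "T_LOW", "K_T_LOW",
                          "C_S_LOW", "Z_S", "Z_l"))
  expect_equal(read_layer_params(path), p)
})
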