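test_that("calibration/validation split follows the two-thirds count rule", {
  obs <- data.frame(date = as.Date("2001-01-01") + 0:299,
                    value = rnorm(300))
  sp <- split_calibration_validation(obs)
  expect_equal(sum(sp$calibration), 200)
  expect_equal(sum(sp$validation), 100)
  obs301 <- data.frame(date = as.Date("2001-01-01") + 0:300,
                       value = rnorm(301))
  sp301 <- split_calibration_validation(obs301)
  expect_equal(sum(sp301$calibration), 201)
  expect_equal(sum(sp301$validation), 100)
  # masks partition the non-missing days, skipping NAs, in time order
  obs$value[c(10, 250)] <- NA
  sp2 <- split_calibration_validation(obs)
  expect_equal(sum(sp2$calibration & sp2$validation), 0)
  expect_equal(which(sp2$calibration | sp2$validation),
               which(!is.na(obs$value)))
  expect_lt(max(which(sp2$calibration)), min(which(sp2$validation)))
  expect_error(split_calibration_validation(data.frame(
    date = as.Date("2001-01-01") + 0:9, value = rnorm(10))), ">= 30")
})

test_that("goodness-of-fit statistics match their formulas", {
  obs <- c(1, 2, 3, 4)
  sim <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(nash_sutcliffe(obs, sim), 0.98)
  expect_equal(rmse(obs, sim), sqrt(0.025), tolerance = 1e-9)
  expect_equal(nash_sutcliffe(obs, obs), 1)
  expect_equal(nash_sutcliffe(obs, rep(mean(obs), 4)), 0)
  expect_equal(rmse(obs, obs), 0)
  expect_equal(r_squared(obs, obs), 1)
  # R-squared ignores an offset that RMSE sees
  expect_equal(r_squared(obs, obs + 1), 1)
  expect_equal(rmse(obs, obs + 1), 1)
  # missing values drop out pairwise
  expect_equal(nash_sutcliffe(c(obs, NA), c(sim, 99)), 0.98)
  expect_error(nash_sutcliffe(rep(2, 5), 1:5), "constant")
  expect_error(r_squared(1:5, rep(2, 5)), "constant")
})

test_that("Monte Carlo runs are reproducible and stay inside their ranges", {
  w <- test_weather(3, seed = 55)
  fx <- generate_soil_fixture(w, ref_params(), obs_noise_sd = 0.3,
                              missing_frac = 0.1, seed = 56,
                              config = simulation_config(spinup_days = 365))
  r1 <- run_monte_carlo(fx$observations, w, n_runs = 200, seed = 9,
                        Z_S = 0.1, block_size = 64)
  r2 <- run_monte_carlo(fx$observations, w, n_runs = 200, seed = 9,
                        Z_S = 0.1, block_size = 200)
  expect_identical(r1$parameters, r2$parameters)
  expect_equal(r1$scores, r2$scores)
  rng <- parameter_ranges()
  for (nm in names(rng)) {
    expect_true(all(r1$parameters[[nm]] >= rng[[nm]][1] &
                      r1$parameters[[nm]] <= rng[[nm]][2]))
  }
  # ranks are a permutation ordered by calibration NS
  expect_setequal(r1$scores$rank, 1:200)
  expect_equal(order(-r1$scores$ns_cal), order(r1$scores$rank))
  expect_true(all(r1$scores$ns_cal <= 1))
  # block scoring agrees with the scalar statistics on one run
  config <- simulation_config(spinup_days = 365)
  p17 <- do.call(soil_layer_params, c(as.list(r1$parameters[17, ]),
                                      list(Z_S = 0.1)))
  sim <- simulate_series(w, p17, config)
  cal <- r1$windows$calibration
  expect_equal(r1$scores$ns_cal[17],
               nash_sutcliffe(fx$observations$value[cal],
                              sim$t_z[match(fx$observations$date[cal],
                                            sim$date)]),
               tolerance = 1e-9)
})

test_that("behavioral selection returns the top runs in rank order", {
  w <- test_weather(3, seed = 57)
  fx <- generate_soil_fixture(w, ref_params(), obs_noise_sd = 0.3,
                              seed = 58,
                              config = simulation_config(spinup_days = 365))
  res <- run_monte_carlo(fx$observations, w, n_runs = 150, seed = 10,
                         Z_S = 0.1)
  beh <- select_behavioral(res, 25)
  expect_equal(nrow(beh), 25)
  expect_equal(beh$ns_cal, sort(res$scores$ns_cal, decreasing = TRUE)[1:25])
  all_runs <- select_behavioral(res, 150)
  expect_equal(nrow(all_runs), 150)
  expect_error(select_behavioral(res, 151), "exceeds")
  # top-100 flag is nested inside top-5000 (both capped at n_runs here)
  expect_true(all(res$scores$top100 <= res$scores$top5000))
})

test_that("posterior CDFs are uniform for ignored parameters", {
  # scores decoupled from the parameters: an insensitive parameter's
  # posterior over any top-k subset stays KS-close to uniform
  w <- test_weather(3, seed = 59)
  fx <- generate_soil_fixture(w, ref_params(), obs_noise_sd = 0.3,
                              seed = 60,
                              config = simulation_config(spinup_days = 365))
  res <- run_monte_carlo(fx$observations, w, n_runs = 400, seed = 12,
                         Z_S = 0.1)
  tab <- posterior_cdf(res, "C_ICE", top_k = 400)  # all runs = prior
  expect_equal(nrow(tab), 400)
  expect_true(all(diff(tab$cdf) > 0))
  expect_true(all(tab$value >= 0 & tab$value <= 1))
  # full sample against uniform: KS below the 1% critical band
  expect_lt(ks_distance_uniform(res, "C_ICE", 400),
            1.63 / sqrt(400))
  expect_error(posterior_cdf(res, "bogus"), "unknown parameter")
  expect_error(posterior_cdf(res, "K_T", top_k = 401), "exceeds")
})

test_that("calibration results persist as a run table plus metadata", {
  w <- test_weather(3, seed = 61)
  fx <- generate_soil_fixture(w, ref_params(), obs_noise_sd = 0.3,
                              seed = 62,
                              config = simulation_config(spinup_days = 365))
  res <- run_monte_carlo(fx$observations, w, n_runs = 50, seed = 13,
                         Z_S = 0.1)
  dir <- file.path(tempdir(), "calib-out")
  write_calibration_result(res, dir)
  tab <- read.csv(file.path(dir, "calibration.csv"))
  expect_equal(nrow(tab), 50)
  expect_true(all(c("C_S", "K_T", "ns_cal", "ns_val", "r2_val", "rmse_val",
                    "rank") %in% names(tab)))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$seed, 13)
  expect_equal(meta$n_runs, 50)
  unlink(dir, recursive = TRUE)
})
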