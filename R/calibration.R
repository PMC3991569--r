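#' Split observations into calibration and validation windows
#'
#' Partitions the non-missing observations by count, in time order: the
#' first `ceiling(2n/3)` go to calibration, the remainder to validation.
#' Splitting by observation count rather than by a fixed date keeps the
#' windows comparable across series with large gaps.
#'
#' @param obs Observed daily series: data frame with `date` and `value`
#'   (NAs mark missing days).
#' @return A list with logical masks `calibration` and `validation` over
#'   the rows of `obs`. The masks are disjoint and together cover exactly
#'   the non-missing rows.
#' @export
split_calibration_validation <- function(obs) {
  ok <- !is.na(obs$value)
  n <- sum(ok)
  if (n < 30) {
    stop("split_calibration_validation: only ", n,
         " non-missing observations (need >= 30)", call. = FALSE)
  }
  idx <- which(ok)
  n_cal <- ceiling(2 * n / 3)
  cal <- logical(nrow(obs))
  val <- logical(nrow(obs))
  cal[idx[seq_len(n_cal)]] <- TRUE
  val[idx[seq(n_cal + 1, n)]] <- TRUE
  list(calibration = cal, validation = val)
}

#' Goodness-of-fit statistics
#'
#' Nash-Sutcliffe efficiency `1 - SSE/SST`, root mean square error, and the
#' squared Pearson correlation of observed and simulated values. All are
#' computed over pairwise complete (both non-missing) days only. NS is 1
#' for a perfect fit and 0 for a model no better than the observed mean.
#'
#' @param obs,sim Numeric vectors of equal length.
#' @return A single number.
#' @export
#' @examples
#' nash_sutcliffe(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))  # 0.98
nash_sutcliffe <- function(obs, sim) {
  p <- paired_values(obs, sim)
  if (stats::sd(p$obs) == 0) {
    stop("nash_sutcliffe: observations are constant (undefined denominator)",
         call. = FALSE)
  }
  1 - sum((p$obs - p$sim)^2) / sum((p$obs - mean(p$obs))^2)
}

#' @rdname nash_sutcliffe
#' @export
rmse <- function(obs, sim) {
  p <- paired_values(obs, sim)
  sqrt(mean((p$obs - p$sim)^2))
}

#' @rdname nash_sutcliffe
#' @export
r_squared <- function(obs, sim) {
  p <- paired_values(obs, sim)
  if (stats::sd(p$obs) == 0 || stats::sd(p$sim) == 0) {
    stop("r_squared: constant series (undefined correlation)", call. = FALSE)
  }
  stats::cor(p$obs, p$sim)^2
}

paired_values <- function(obs, sim) {
  if (length(obs) != length(sim)) {
    stop("obs and sim must have the same length", call. = FALSE)
  }
  ok <- !is.na(obs) & !is.na(sim)
  if (sum(ok) < 2) {
    stop("need at least 2 paired non-missing values", call. = FALSE)
  }
  list(obs = obs[ok], sim = sim[ok])
}

#' Monte Carlo calibration of the soil-temperature model
#'
#' Draws `n_runs` parameter sets uniformly and independently from their
#' ranges, simulates each over the forcing, and scores it against the
#' observations: Nash-Sutcliffe efficiency on the calibration window
#' (the first two-thirds of non-missing observations), and NS, R-squared
#' and RMSE on the validation window. Runs are ranked by calibration NS,
#' descending, with ties broken by run index. Missing observations are
#' excluded pairwise from all scores. All runs use the identical forcing.
#'
#' The simulation is vectorised across parameter sets and processed in
#' blocks, so the default 100 000 runs are feasible on one CPU; use a
#' smaller `n_runs` for tests.
#'
#' @param obs Observed soil-temperature series (`date`, `value`); its dates
#'   must lie inside the forcing span after spin-up.
#' @param forcing A [forcing_series()] with `d_s`, covering the observation
#'   span plus spin-up.
#' @param ranges A [parameter_ranges()] object.
#' @param n_runs Number of Monte Carlo runs.
#' @param seed Integer seed; the whole result is reproducible from it.
#' @param Z_S Layer depth, m.
#' @param Z_l Space coordinate of the lower temperature influence, m
#'   (default `2 * Z_S`).
#' @param config A [simulation_config()]; its `spinup_days` leading days
#'   are dropped before aligning with observations.
#' @param block_size Runs simulated per block (memory/speed trade-off).
#' @return An object of class `calibration_result`: list with `parameters`
#'   (data frame `n_runs` x 7), `scores` (data frame with `ns_cal`,
#'   `ns_val`, `r2_val`, `rmse_val`, `rank`, `top5000`, `top100`), plus
#'   `seed`, `n_runs`, `ranges`, `Z_S`, `Z_l` and the window masks.
#' @export
run_monte_carlo <- function(obs, forcing, ranges = parameter_ranges(),
                            n_runs = 100000L, seed = 1L, Z_S,
                            Z_l = 2 * Z_S,
                            config = simulation_config(spinup_days = 365L),
                            block_size = 5000L) {
  stopifnot(n_runs >= 1, Z_S > 0, Z_l > Z_S)
  n_runs <- as.integer(n_runs)
  set.seed(as.integer(seed))
  params <- sample_parameters(ranges, n_runs)
  params$Z_S <- Z_S
  params$Z_l <- Z_l

  sim_dates <- forcing$date
  if (config$spinup_days > 0) {
    sim_dates <- sim_dates[-seq_len(config$spinup_days)]
  }
  pos <- match(obs$date, sim_dates)
  if (anyNA(pos[!is.na(obs$value)])) {
    stop("run_monte_carlo: observations fall outside the simulated span ",
         "(forcing minus spin-up)", call. = FALSE)
  }
  windows <- split_calibration_validation(obs)
  cal_idx <- pos[windows$calibration]
  val_idx <- pos[windows$validation]
  obs_cal <- obs$value[windows$calibration]
  obs_val <- obs$value[windows$validation]
  sst_cal <- sum((obs_cal - mean(obs_cal))^2)
  if (sst_cal == 0) {
    stop("run_monte_carlo: calibration observations are constant",
         call. = FALSE)
  }

  ns_cal <- ns_val <- r2_val <- rmse_val <- numeric(n_runs)
  sst_val <- sum((obs_val - mean(obs_val))^2)
  for (start in seq(1L, n_runs, by = block_size)) {
    end <- min(start + block_size - 1L, n_runs)
    rows <- start:end
    m <- simulate_matrix(forcing, params[rows, , drop = FALSE], config)
    sim_cal <- m[cal_idx, , drop = FALSE]
    sim_val <- m[val_idx, , drop = FALSE]
    ns_cal[rows] <- 1 - colSums((sim_cal - obs_cal)^2) / sst_cal
    ns_val[rows] <- 1 - colSums((sim_val - obs_val)^2) / sst_val
    rmse_val[rows] <- sqrt(colMeans((sim_val - obs_val)^2))
    r2_val[rows] <- apply(sim_val, 2, function(s) {
      if (stats::sd(s) == 0) NA_real_ else stats::cor(obs_val, s)^2
    })
  }

  ord <- order(-ns_cal, seq_len(n_runs))
  rank <- integer(n_runs)
  rank[ord] <- seq_len(n_runs)
  scores <- data.frame(ns_cal = ns_cal, ns_val = ns_val, r2_val = r2_val,
                       rmse_val = rmse_val, rank = rank,
                       top5000 = rank <= min(5000L, n_runs),
                       top100 = rank <= min(100L, n_runs))
  structure(list(parameters = params[names(ranges)], scores = scores,
                 seed = as.integer(seed), n_runs = n_runs, ranges = ranges,
                 Z_S = Z_S, Z_l = Z_l, windows = windows,
                 spinup_days = config$spinup_days),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Monte Carlo calibration:", x$n_runs, "runs (seed", x$seed, ")\n")
  best <- which.min(x$scores$rank)
  cat(sprintf("  best calibration NS %.4f (validation NS %.4f, RMSE %.3f)\n",
              x$scores$ns_cal[best], x$scores$ns_val[best],
              x$scores$rmse_val[best]))
  invisible(x)
}

#' Posterior parameter CDF over the top-ranked runs
#'
#' Empirical cumulative distribution of one parameter over the `top_k`
#' best-ranked runs, on the parameter's range normalised to `[0, 1]`. A
#' sensitive parameter concentrates (its CDF departs from the diagonal); an
#' insensitive one stays close to uniform.
#'
#' @param result A [run_monte_carlo()] result.
#' @param parameter Parameter name (one of the seven calibratable fields).
#' @param top_k Number of top-ranked runs to use.
#' @return A data frame with columns `value` (sorted normalised parameter
#'   values) and `cdf` (empirical probabilities `1/k ... 1`).
#' @export
posterior_cdf <- function(result, parameter, top_k = 5000L) {
  stopifnot(inherits(result, "calibration_result"))
  if (!parameter %in% names(result$parameters)) {
    stop("posterior_cdf: unknown parameter '", parameter, "'", call. = FALSE)
  }
  if (result$n_runs < top_k) {
    stop("posterior_cdf: top_k (", top_k, ") exceeds n_runs (",
         result$n_runs, ")", call. = FALSE)
  }
  sel <- result$scores$rank <= top_k
  r <- result$ranges[[parameter]]
  v <- sort((result$parameters[[parameter]][sel] - r[1]) / (r[2] - r[1]))
  data.frame(value = v, cdf = seq_along(v) / length(v))
}

#' Kolmogorov-Smirnov distance of a posterior CDF from uniform
#'
#' Measures how far the top-ranked runs' distribution of a parameter is
#' from the uniform sampling distribution - a simple sensitivity index:
#' larger distance means the calibration constrains the parameter more.
#'
#' @inheritParams posterior_cdf
#' @return The KS statistic (sup-norm distance from the U(0,1) CDF).
#' @export
ks_distance_uniform <- function(result, parameter, top_k = 5000L) {
  tab <- posterior_cdf(result, parameter, top_k)
  n <- nrow(tab)
  i <- seq_len(n)
  max(pmax(i / n - tab$value, tab$value - (i - 1) / n))
}

#' Select the behavioral parameter sets
#'
#' The `top_n` parameter rows by calibration-window Nash-Sutcliffe
#' efficiency (ties broken by run index, lower first) - the sets retained
#' for projecting future conditions.
#'
#' @param result A [run_monte_carlo()] result.
#' @param top_n Number of behavioral runs to keep.
#' @return A data frame of the `top_n` parameter rows plus their `ns_cal`,
#'   ordered by rank.
#' @export
select_behavioral <- function(result, top_n = 100L) {
  stopifnot(inherits(result, "calibration_result"))
  if (result$n_runs < top_n) {
    stop("select_behavioral: top_n (", top_n, ") exceeds n_runs (",
         result$n_runs, ")", call. = FALSE)
  }
  sel <- order(result$scores$rank)[seq_len(top_n)]
  out <- result$parameters[sel, , drop = FALSE]
  out$ns_cal <- result$scores$ns_cal[sel]
  rownames(out) <- NULL
  out
}

#' Persist a calibration result
#'
#' Writes the full run table (seven parameters plus scores and rank, one
#' row per run) as CSV and the run metadata (seed, number of runs, layer
#' geometry, spin-up, window sizes) as JSON.
#'
#' @param result A [run_monte_carlo()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_calibration_result <- function(result, dir) {
  stopifnot(inherits(result, "calibration_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cbind(result$parameters, result$scores)
  utils::write.csv(tab, file.path(dir, "calibration.csv"), row.names = FALSE)
  meta <- list(seed = result$seed, n_runs = result$n_runs,
               Z_S = result$Z_S, Z_l = result$Z_l,
               spinup_days = result$spinup_days,
               n_calibration = sum(result$windows$calibration),
               n_validation = sum(result$windows$validation))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
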