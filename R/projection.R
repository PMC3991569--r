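#' Monthly climatology of a daily series
#'
#' Calendar-month means over all years of the series. Accepts any data
#' frame with a `date` column and a single value column (`value`, `t_z` or
#' `t_air`).
#'
#' @param series Daily series data frame.
#' @return A data frame with columns `month` (1-12) and `mean`.
#' @export
monthly_climatology <- function(series) {
  v <- series_value(series)
  span <- as.integer(max(series$date) - min(series$date))
  mon <- as.POSIXlt(series$date)$mon + 1
  if (span < 364 || length(unique(mon)) < 12) {
    stop("monthly_climatology: need at least one full year covering all ",
         "12 months", call. = FALSE)
  }
  means <- tapply(v, factor(mon, levels = 1:12), mean, na.rm = TRUE)
  data.frame(month = 1:12, mean = as.numeric(means))
}

#' Annual means and standard deviations
#'
#' Per calendar year: the mean and the standard deviation of the daily
#' values (the spread of the seasonal cycle within the year, the quantity
#' usually drawn as error bars on annual summaries).
#'
#' @param series Daily series data frame (see [monthly_climatology()]).
#' @return A data frame with columns `year`, `annual_mean`, `annual_sd`.
#' @export
annual_summary <- function(series) {
  v <- series_value(series)
  if (as.integer(max(series$date) - min(series$date)) < 364) {
    stop("annual_summary: need at least one full year", call. = FALSE)
  }
  yr <- as.POSIXlt(series$date)$year + 1900
  data.frame(
    year = sort(unique(yr)),
    annual_mean = as.numeric(tapply(v, yr, mean, na.rm = TRUE)),
    annual_sd = as.numeric(tapply(v, yr, stats::sd, na.rm = TRUE))
  )
}

#' Month-resolved change between scenario and control
#'
#' Monthly climatologies of both series computed by the same procedure,
#' and their difference (scenario minus control) per calendar month.
#'
#' @param scenario,control Daily series data frames.
#' @return A data frame with columns `month`, `control_mean`,
#'   `scenario_mean`, `delta`.
#' @export
seasonal_delta <- function(scenario, control) {
  cs <- monthly_climatology(scenario)
  cc <- monthly_climatology(control)
  data.frame(month = 1:12, control_mean = cc$mean, scenario_mean = cs$mean,
             delta = cs$mean - cc$mean)
}

#' Roll monthly deltas up to meteorological seasons
#'
#' DJF/MAM/JJA/SON means of the monthly `delta` column.
#'
#' @param delta_tab A [seasonal_delta()] table.
#' @return A data frame with columns `season` and `delta`.
#' @export
seasonal_rollup <- function(delta_tab) {
  season <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA", "JJA", "JJA",
              "SON", "SON", "SON", "DJF")[delta_tab$month]
  agg <- tapply(delta_tab$delta, factor(season,
                                        levels = c("DJF", "MAM", "JJA",
                                                   "SON")), mean)
  data.frame(season = names(agg), delta = as.numeric(agg),
             row.names = NULL)
}

series_value <- function(series) {
  for (col in c("value", "t_z", "t_air")) {
    if (!is.null(series[[col]])) return(series[[col]])
  }
  stop("series must have a 'value', 't_z' or 't_air' column", call. = FALSE)
}

#' Project an ensemble of climate scenarios through the behavioral runs
#'
#' For each ensemble member's forcing, simulates every behavioral
#' parameter set and reduces them to a single per-day median series; the
#' identical reduction is applied to the control forcing. Member-level
#' summaries follow: monthly climatologies and scenario-minus-control
#' deltas (12 rows per member), annual means with standard deviations, and
#' the ensemble median of the monthly summaries across members.
#'
#' @param behavioral Behavioral parameter sets from [select_behavioral()]
#'   (any data frame with the seven calibratable columns).
#' @param members Named list of scenario [forcing_series()], one per
#'   ensemble member; each must have `d_s`.
#' @param control_forcing Control-period [forcing_series()] with `d_s`.
#' @param Z_S Layer depth, m.
#' @param Z_l Lower temperature influence coordinate, m.
#' @param config A [simulation_config()].
#' @return An object of class `ensemble_projection`: list with
#'   `member_series` (named list of median daily series), `control_series`,
#'   `deltas` (tidy data frame member x month), `annual` (member, year,
#'   annual mean/sd), and `ensemble` (per-month ensemble-median control
#'   mean, scenario mean and delta).
#' @export
run_ensemble <- function(behavioral, members, control_forcing, Z_S,
                         Z_l = 2 * Z_S, config = simulation_config()) {
  if (nrow(behavioral) < 1) {
    stop("run_ensemble: behavioral set is empty", call. = FALSE)
  }
  if (is.null(names(members)) || any(!nzchar(names(members)))) {
    names(members) <- paste0("member_", seq_along(members))
  }
  pcols <- c("C_S", "K_T", "C_ICE", "f_S", "T_LOW", "K_T_LOW", "C_S_LOW")
  miss <- setdiff(pcols, names(behavioral))
  if (length(miss)) {
    stop("run_ensemble: behavioral set lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pset <- behavioral[pcols]
  pset$Z_S <- Z_S
  pset$Z_l <- Z_l

  median_series <- function(forcing, label) {
    m <- tryCatch(simulate_matrix(forcing, pset, config),
                  error = function(e) {
                    stop("run_ensemble: member '", label, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
    date <- forcing$date
    if (config$spinup_days > 0) date <- date[-seq_len(config$spinup_days)]
    med <- if (ncol(m) == 1) m[, 1] else apply(m, 1, stats::median)
    data.frame(date = date, value = med)
  }

  control_series <- median_series(control_forcing, "control")
  member_series <- mapply(median_series, members, names(members),
                          SIMPLIFY = FALSE)

  deltas <- do.call(rbind, lapply(names(member_series), function(nm) {
    d <- seasonal_delta(member_series[[nm]], control_series)
    cbind(member = nm, d)
  }))
  annual <- do.call(rbind, lapply(names(member_series), function(nm) {
    a <- annual_summary(member_series[[nm]])
    cbind(member = nm, a)
  }))
  ens <- stats::aggregate(deltas[c("control_mean", "scenario_mean",
                                   "delta")],
                          by = list(month = deltas$month), stats::median)
  structure(list(member_series = member_series,
                 control_series = control_series,
                 deltas = deltas, annual = annual, ensemble = ens),
            class = "ensemble_projection")
}

#' @export
print.ensemble_projection <- function(x, ...) {
  cat("Ensemble projection:", length(x$member_series), "member(s)\n")
  cat(sprintf("  annual ensemble-median delta %.2f degC\n",
              mean(x$ensemble$delta)))
  invisible(x)
}

#' Write ensemble-projection summary tables
#'
#' Tidy CSVs: `deltas.csv` (member, month, control mean, scenario mean,
#' delta), `annual.csv` (member, year, annual mean and sd) and
#' `ensemble.csv` (per-month ensemble medians).
#'
#' @param projection An [run_ensemble()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ensemble_projection <- function(projection, dir) {
  stopifnot(inherits(projection, "ensemble_projection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(projection$deltas, file.path(dir, "deltas.csv"),
                   row.names = FALSE)
  utils::write.csv(projection$annual, file.path(dir, "annual.csv"),
                   row.names = FALSE)
  utils::write.csv(projection$ensemble, file.path(dir, "ensemble.csv"),
                   row.names = FALSE)
  invisible(dir)
}
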