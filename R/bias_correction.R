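#' Fit a distribution map for one variable and calendar month
#'
#' Distribution mapping (quantile mapping) corrects a climate-model series
#' by matching its cumulative distribution function in a control period to
#' the observed CDF. This function fits the two parametric CDFs for one
#' calendar-month window: Gaussian (mean, sd) for temperature, Gamma
#' (shape, scale) for precipitation. For precipitation only wet days -
#' values above `wet_threshold` - enter the Gamma fit, by maximum
#' likelihood.
#'
#' @param obs Observed daily series: a data frame with `date` and `value`.
#' @param contr Climate-model control-run daily series, same layout.
#' @param variable `"temperature"` or `"precipitation"`.
#' @param month Calendar month 1-12 defining the fitting window.
#' @param wet_threshold Wet-day threshold, mm (precipitation only).
#' @return An object of class `distribution_map` holding the fitted
#'   parameter pairs for both sides.
#' @export
fit_distribution_map <- function(obs, contr,
                                 variable = c("temperature", "precipitation"),
                                 month, wet_threshold = 0.1) {
  variable <- match.arg(variable)
  month <- as.integer(month)
  stopifnot(month >= 1, month <= 12)
  ov <- month_values(obs, month)
  cv <- month_values(contr, month)
  if (variable == "precipitation") {
    ov <- ov[ov > wet_threshold]
    cv <- cv[cv > wet_threshold]
  }
  for (side in list(list(x = ov, lab = "observed"),
                    list(x = cv, lab = "control"))) {
    if (length(side$x) < 30) {
      stop("fit_distribution_map: month ", month, " has only ",
           length(side$x), " usable ", side$lab, " values for ", variable,
           " (need >= 30)", call. = FALSE)
    }
  }
  if (variable == "temperature") {
    family <- "Gaussian"
    obs_params <- c(mean(ov), stats::sd(ov))
    contr_params <- c(mean(cv), stats::sd(cv))
    if (obs_params[2] <= 0 || contr_params[2] <= 0) {
      stop("fit_distribution_map: degenerate (constant) temperature in ",
           "month ", month, call. = FALSE)
    }
  } else {
    family <- "Gamma"
    obs_params <- fit_gamma(ov)
    contr_params <- fit_gamma(cv)
  }
  structure(list(variable = variable, month = month, family = family,
                 obs_params = obs_params, contr_params = contr_params,
                 wet_threshold = wet_threshold),
            class = "distribution_map")
}

month_values <- function(series, month) {
  v <- series$value[as.POSIXlt(series$date)$mon + 1 == month]
  v[!is.na(v)]
}

# Gamma MLE; returns c(shape, scale).
fit_gamma <- function(x) {
  fit <- fitdistrplus::fitdist(x, "gamma", method = "mle")
  est <- fit$estimate
  c(unname(est["shape"]), 1 / unname(est["rate"]))
}

#' Apply a fitted distribution map to values
#'
#' The quantile-mapping transfer `F_obs^-1(F_contr(x))`: each value is
#' assigned its non-exceedance probability under the fitted control-period
#' CDF and mapped to the observed quantile at that probability. The
#' transfer is monotone non-decreasing in `x`. Probabilities are clipped to
#' `[1e-6, 1 - 1e-6]` so scenario values beyond the fitted range map to
#' finite extremes rather than extrapolated tails. Precipitation at or
#' below the wet-day threshold maps to 0.
#'
#' @param x Numeric values to correct (vectorised).
#' @param map A fitted [fit_distribution_map()] object.
#' @return Corrected values, same length as `x`.
#' @export
apply_distribution_map <- function(x, map) {
  if (!inherits(map, "distribution_map")) {
    stop("apply_distribution_map: map must be a fitted distribution_map",
         call. = FALSE)
  }
  eps <- 1e-6
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (map$family == "Gaussian") {
    p <- stats::pnorm(x[ok], map$contr_params[1], map$contr_params[2])
    p <- pmin(pmax(p, eps), 1 - eps)
    out[ok] <- stats::qnorm(p, map$obs_params[1], map$obs_params[2])
  } else {
    xo <- x[ok]
    res <- numeric(length(xo))
    wet <- xo > map$wet_threshold
    p <- stats::pgamma(xo[wet], shape = map$contr_params[1],
                       scale = map$contr_params[2])
    p <- pmin(pmax(p, eps), 1 - eps)
    res[wet] <- stats::qgamma(p, shape = map$obs_params[1],
                              scale = map$obs_params[2])
    res[!wet] <- 0
    out[ok] <- res
  }
  out
}

#' Fit distribution maps for all twelve months
#'
#' Convenience wrapper fitting one [fit_distribution_map()] per calendar
#' month for each requested variable, from observed and control forcing
#' series.
#'
#' @param obs_forcing,contr_forcing [forcing_series()] objects covering the
#'   control period (temperature in `t_air`, precipitation in `precip`).
#' @param variables Which variables to fit.
#' @param wet_threshold Wet-day threshold, mm.
#' @return An object of class `distribution_map_set`: a list of
#'   `distribution_map`s keyed `"<variable>_<month>"`.
#' @export
fit_distribution_maps <- function(obs_forcing, contr_forcing,
                                  variables = c("temperature",
                                                "precipitation"),
                                  wet_threshold = 0.1) {
  maps <- list()
  for (v in variables) {
    col <- if (v == "temperature") "t_air" else "precip"
    for (side in list(obs_forcing, contr_forcing)) {
      if (is.null(side[[col]])) {
        stop("fit_distribution_maps: forcing lacks column '", col,
             "' needed for ", v, call. = FALSE)
      }
    }
    obs <- data.frame(date = obs_forcing$date, value = obs_forcing[[col]])
    contr <- data.frame(date = contr_forcing$date,
                        value = contr_forcing[[col]])
    for (m in 1:12) {
      maps[[paste(v, m, sep = "_")]] <-
        fit_distribution_map(obs, contr, v, m, wet_threshold)
    }
  }
  class(maps) <- "distribution_map_set"
  maps
}

#' Bias-correct a scenario forcing series
#'
#' Applies the calendar-month distribution maps to every day of a scenario
#' series: temperature through the Gaussian maps, precipitation (when
#' present in the series and the map set) through the Gamma maps. Dates are
#' unchanged.
#'
#' @param scen A [forcing_series()] to correct.
#' @param maps A [fit_distribution_maps()] set covering all 12 months of
#'   each corrected variable.
#' @return The corrected forcing series.
#' @export
bias_correct_series <- function(scen, maps) {
  if (!inherits(maps, "distribution_map_set")) {
    stop("bias_correct_series: maps must be a distribution_map_set",
         call. = FALSE)
  }
  mon <- as.POSIXlt(scen$date)$mon + 1
  vars <- unique(vapply(maps, function(m) m$variable, character(1)))
  for (v in vars) {
    col <- if (v == "temperature") "t_air" else "precip"
    if (is.null(scen[[col]])) next
    corrected <- scen[[col]]
    for (m in sort(unique(mon))) {
      key <- paste(v, m, sep = "_")
      if (is.null(maps[[key]])) {
        stop("bias_correct_series: no ", v, " map for month ", m,
             call. = FALSE)
      }
      idx <- mon == m
      corrected[idx] <- apply_distribution_map(scen[[col]][idx], maps[[key]])
    }
    scen[[col]] <- corrected
  }
  scen
}

#' Serialise distribution maps to a tabular file
#'
#' One row per (variable, month): family, observed and control parameter
#' pairs, wet-day threshold.
#'
#' @param maps A `distribution_map_set`.
#' @param path CSV file path.
#' @return `write_distribution_maps()` returns `path` invisibly;
#'   `read_distribution_maps()` returns the `distribution_map_set`.
#' @export
write_distribution_maps <- function(maps, path) {
  stopifnot(inherits(maps, "distribution_map_set"))
  rows <- lapply(unname(maps), function(m) {
    data.frame(variable = m$variable, month = m$month, family = m$family,
               p1_obs = m$obs_params[1], p2_obs = m$obs_params[2],
               p1_contr = m$contr_params[1], p2_contr = m$contr_params[2],
               wet_threshold = m$wet_threshold)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution_maps
#' @export
read_distribution_maps <- function(path) {
  tab <- utils::read.csv(path)
  maps <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    maps[[paste(r$variable, r$month, sep = "_")]] <-
      structure(list(variable = r$variable, month = r$month,
                     family = r$family,
                     obs_params = c(r$p1_obs, r$p2_obs),
                     contr_params = c(r$p1_contr, r$p2_contr),
                     wet_threshold = r$wet_threshold),
                class = "distribution_map")
  }
  class(maps) <- "distribution_map_set"
  maps
}
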