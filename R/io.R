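#' Read and write single-variable daily series
#'
#' CSV with header `date,value`, ISO-8601 dates, missing values as empty
#' fields. Gaps (absent dates) are preserved on read; they only become an
#' error when such a series is used as simulation forcing.
#'
#' @param path CSV file path.
#' @param series A data frame with `date` and `value` columns.
#' @return `read_daily_series()` returns a data frame `date`, `value`;
#'   `write_daily_series()` returns `path` invisibly.
#' @export
read_daily_series <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("read_daily_series: ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  date <- as.Date(tab$date, format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop("read_daily_series: unparseable date '",
         tab$date[which(is.na(date))[1]], "' in ", path, call. = FALSE)
  }
  if (anyDuplicated(date)) {
    stop("read_daily_series: duplicate date ",
         format(date[duplicated(date)][1]), " in ", path, call. = FALSE)
  }
  ord <- order(date)
  data.frame(date = date[ord], value = as.numeric(tab$value)[ord])
}

#' @rdname read_daily_series
#' @export
write_daily_series <- function(series, path) {
  out <- data.frame(date = format(series$date, "%Y-%m-%d"),
                    value = series_value(series))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write forcing series as CSV
#'
#' Daily CSV with columns `date`, `t_air` and optionally `d_s` and
#' `precip`; the same schema the synthetic weather generator emits.
#'
#' @param path CSV file path.
#' @param forcing A [forcing_series()].
#' @return `read_forcing_csv()` returns a [forcing_series()];
#'   `write_forcing_csv()` returns `path` invisibly.
#' @export
read_forcing_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "t_air") %in% names(tab))) {
    stop("read_forcing_csv: ", path, " must have columns date and t_air",
         call. = FALSE)
  }
  date <- as.Date(tab$date, format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop("read_forcing_csv: unparseable date '",
         tab$date[which(is.na(date))[1]], "' in ", path, call. = FALSE)
  }
  forcing_series(date, tab$t_air, d_s = tab$d_s, precip = tab$precip)
}

#' @rdname read_forcing_csv
#' @export
write_forcing_csv <- function(forcing, path) {
  out <- as.data.frame(forcing)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a site configuration file
#'
#' YAML document describing one site: its name, the soil-layer depths in
#' centimetres with labels top/middle/bottom, file paths, simulation and
#' snow-model settings, weather-generator settings and parameter-range
#' overrides. Depths are converted to metres at load; a 0 cm (surface)
#' depth is coerced to 0.01 m, since a zero-thickness layer is simulated
#' as a 1 cm layer.
#'
#' @param path YAML file path.
#' @return A list of class `site_config` with `depths_m` (named numeric,
#'   strictly increasing top to bottom) and the remaining settings.
#' @export
read_site_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("site", "depths_cm")) {
    if (is.null(cfg[[key]])) {
      stop("read_site_config: missing config key '", key, "' in ", path,
           call. = FALSE)
    }
  }
  depths <- unlist(cfg$depths_cm)
  if (any(depths < 0)) {
    stop("read_site_config: depths must be non-negative", call. = FALSE)
  }
  depths_m <- pmax(depths, 1) / 100  # 0 cm simulated as 1 cm depth
  if (is.unsorted(depths_m, strictly = TRUE)) {
    stop("read_site_config: depths must be strictly increasing top to ",
         "bottom", call. = FALSE)
  }
  cfg$depths_m <- depths_m
  cfg$simulation <- utils::modifyList(
    list(spinup_days = 365L, ice_threshold = 0, dt = 86400),
    as.list(cfg$simulation))
  cfg$snow <- utils::modifyList(
    list(T_thresh = 0, melt_factor = 3, density_ratio = 0.25),
    as.list(cfg$snow))
  class(cfg) <- "site_config"
  cfg
}

config_simulation <- function(cfg) {
  simulation_config(dt = cfg$simulation$dt,
                    T_init = cfg$simulation$T_init,
                    spinup_days = cfg$simulation$spinup_days,
                    ice_threshold = cfg$simulation$ice_threshold)
}

config_ranges <- function(cfg) {
  if (is.null(cfg$ranges)) return(parameter_ranges())
  do.call(parameter_ranges, lapply(cfg$ranges, unlist))
}

config_depth <- function(cfg, layer) {
  if (!layer %in% names(cfg$depths_m)) {
    stop("unknown layer '", layer, "'; config defines: ",
         paste(names(cfg$depths_m), collapse = ", "), call. = FALSE)
  }
  unname(cfg$depths_m[[layer]])
}
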