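#' Daily forcing series
#'
#' Container for the daily climate series that drives the soil-temperature
#' recursion: air temperature, snow depth and (optionally) precipitation.
#'
#' @param date A `Date` vector, strictly increasing.
#' @param t_air Daily mean air temperature, degC.
#' @param d_s Snow depth, mm. Optional at construction; required by
#'   [simulate_series()] (fill it from observations or with
#'   [simulate_snowpack()]).
#' @param precip Precipitation, mm/day. Optional; used only by the snowpack
#'   model.
#'
#' @return A data frame of class `forcing_series` with columns `date`,
#'   `t_air` and, when supplied, `d_s` and `precip`.
#' @export
forcing_series <- function(date, t_air, d_s = NULL, precip = NULL) {
  date <- as.Date(date)
  if (anyNA(date)) stop("forcing_series: unparseable dates", call. = FALSE)
  if (anyDuplicated(date)) {
    stop("forcing_series: duplicate date: ",
         format(date[duplicated(date)][1]), call. = FALSE)
  }
  if (is.unsorted(date, strictly = TRUE)) {
    stop("forcing_series: dates must be strictly increasing", call. = FALSE)
  }
  if (length(t_air) != length(date)) {
    stop("forcing_series: t_air must match date in length", call. = FALSE)
  }
  out <- data.frame(date = date, t_air = as.numeric(t_air))
  if (!is.null(d_s)) {
    d_s <- as.numeric(d_s)
    if (length(d_s) != length(date)) {
      stop("forcing_series: d_s must match date in length", call. = FALSE)
    }
    if (any(d_s < 0, na.rm = TRUE)) {
      stop("forcing_series: snow depth d_s must be non-negative",
           call. = FALSE)
    }
    out$d_s <- d_s
  }
  if (!is.null(precip)) {
    precip <- as.numeric(precip)
    if (length(precip) != length(date)) {
      stop("forcing_series: precip must match date in length", call. = FALSE)
    }
    if (any(precip < 0, na.rm = TRUE)) {
      stop("forcing_series: precip must be non-negative", call. = FALSE)
    }
    out$precip <- precip
  }
  class(out) <- c("forcing_series", "data.frame")
  out
}

#' @export
print.forcing_series <- function(x, ...) {
  cat("Daily forcing series:", nrow(x), "days,",
      format(x$date[1]), "to", format(x$date[nrow(x)]), "\n")
  cat("  columns:", paste(setdiff(names(x), "date"), collapse = ", "), "\n")
  invisible(x)
}

# Contiguity check used at simulation time; names the first gap.
check_contiguous <- function(date, what = "forcing") {
  d <- diff(as.integer(date))
  if (any(d != 1L)) {
    i <- which(d != 1L)[1]
    stop(what, " dates are not contiguous daily: gap after ",
         format(date[i]), " (next is ", format(date[i + 1]), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}
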