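#' Soil-layer parameter set
#'
#' Bundles the seven calibratable parameters of the extended empirical
#' soil-temperature model together with the layer geometry. Units are SI
#' with temperatures in degrees Celsius.
#'
#' @param C_S Volumetric specific heat of the soil, J m^-3 degC^-1.
#' @param K_T Soil thermal conductivity, W m^-1 degC^-1.
#' @param C_ICE Additional (apparent) heat capacity due to freezing and
#'   thawing - the latent part - J m^-3 degC^-1. Active only while the soil
#'   is at or below the ice threshold.
#' @param f_S Empirical snow insulation parameter, m^-1. Zero disables the
#'   snow damping entirely.
#' @param T_LOW Lower-boundary soil temperature, degC (treated as constant).
#' @param K_T_LOW Thermal conductivity of the lower soil, W m^-1 degC^-1.
#'   Zero disables the lower-boundary heat-flow extension.
#' @param C_S_LOW Volumetric specific heat of the lower soil, J m^-3 degC^-1.
#' @param Z_S Depth of the simulated layer, m.
#' @param Z_l Space coordinate of the lower temperature influence, m. Must
#'   exceed `Z_S`; defaults to `2 * Z_S`.
#'
#' @return An object of class `soil_layer_params` (a named list).
#' @seealso [parameter_ranges()], [simulate_series()]
#' @export
#' @examples
#' p <- soil_layer_params(C_S = 2e6, K_T = 0.5, C_ICE = 8e6, f_S = 5,
#'                        T_LOW = 0.5, K_T_LOW = 0.3, C_S_LOW = 2e6,
#'                        Z_S = 0.1)
#' p$K_T
soil_layer_params <- function(C_S, K_T, C_ICE, f_S, T_LOW, K_T_LOW,
                              C_S_LOW, Z_S, Z_l = 2 * Z_S) {
  p <- list(C_S = C_S, K_T = K_T, C_ICE = C_ICE, f_S = f_S,
            T_LOW = T_LOW, K_T_LOW = K_T_LOW, C_S_LOW = C_S_LOW,
            Z_S = Z_S, Z_l = Z_l)
  p <- lapply(p, as.numeric)
  class(p) <- "soil_layer_params"
  validate_soil_layer_params(p)
  p
}

validate_soil_layer_params <- function(p) {
  num <- unlist(p)
  if (any(!is.finite(num))) {
    stop("soil_layer_params: all fields must be finite numbers", call. = FALSE)
  }
  if (p$C_S <= 0 || p$C_ICE <= 0 || p$C_S_LOW <= 0) {
    stop("soil_layer_params: C_S, C_ICE and C_S_LOW must be strictly positive",
         call. = FALSE)
  }
  if (p$K_T < 0 || p$K_T_LOW < 0 || p$f_S < 0) {
    stop("soil_layer_params: K_T, K_T_LOW and f_S must be non-negative",
         call. = FALSE)
  }
  if (p$Z_S <= 0) stop("soil_layer_params: Z_S must be > 0", call. = FALSE)
  if (p$Z_l <= p$Z_S) {
    stop("soil_layer_params: Z_l must exceed Z_S", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.soil_layer_params <- function(x, ...) {
  cat("Soil layer parameters (depth", x$Z_S, "m, lower influence at",
      x$Z_l, "m)\n")
  flds <- c("C_S", "K_T", "C_ICE", "f_S", "T_LOW", "K_T_LOW", "C_S_LOW")
  for (f in flds) cat(sprintf("  %-8s %g\n", f, x[[f]]))
  invisible(x)
}

#' Simulation configuration
#'
#' Timestep and initialisation settings for the daily recursion.
#'
#' @param dt Timestep in seconds; the model is formulated for a daily step
#'   (86400 s).
#' @param T_init Initial soil temperature, degC. `NULL` (the default) means
#'   initialise from the mean air temperature of the first 14 forcing days.
#' @param spinup_days Number of leading days dropped from the output so the
#'   recursion can forget its initial condition. 365 is recommended for
#'   calibration work.
#' @param ice_threshold Soil temperature at or below which the latent-heat
#'   capacity `C_ICE` is active, degC.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 86400, T_init = NULL, spinup_days = 0L,
                              ice_threshold = 0) {
  if (dt <= 0) stop("simulation_config: dt must be > 0", call. = FALSE)
  spinup_days <- as.integer(spinup_days)
  if (is.na(spinup_days) || spinup_days < 0) {
    stop("simulation_config: spinup_days must be a non-negative integer",
         call. = FALSE)
  }
  structure(list(dt = dt, T_init = T_init, spinup_days = spinup_days,
                 ice_threshold = ice_threshold),
            class = "simulation_config")
}

#' Monte Carlo parameter ranges
#'
#' Lower and upper sampling bounds for the seven calibratable parameters.
#' The defaults are the standard ranges used for grey-box calibration of
#' this model family: C_S and C_S_LOW 0.5-3.5e6 J m^-3 degC^-1, K_T and
#' K_T_LOW 0-1 W m^-1 degC^-1, C_ICE 4-15e6 J m^-3 degC^-1, f_S 0-10 m^-1,
#' T_LOW 0-1 degC.
#'
#' @param ... Named overrides, each a numeric vector `c(lower, upper)`,
#'   e.g. `K_T = c(0.2, 0.8)`.
#' @return An object of class `parameter_ranges`: a named list of
#'   `c(lower, upper)` pairs.
#' @export
parameter_ranges <- function(...) {
  ranges <- list(
    C_S     = c(0.5e6, 3.5e6),
    K_T     = c(0, 1),
    C_ICE   = c(4e6, 15e6),
    f_S     = c(0, 10),
    T_LOW   = c(0, 1),
    K_T_LOW = c(0, 1),
    C_S_LOW = c(0.5e6, 3.5e6)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(ranges))
    if (length(bad)) {
      stop("parameter_ranges: unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ranges[names(over)] <- over
  }
  for (nm in names(ranges)) {
    r <- as.numeric(ranges[[nm]])
    if (length(r) != 2 || any(!is.finite(r)) || r[1] >= r[2]) {
      stop("parameter_ranges: range for ", nm,
           " must be c(lower, upper) with lower < upper", call. = FALSE)
    }
    ranges[[nm]] <- r
  }
  class(ranges) <- "parameter_ranges"
  ranges
}

#' Sample parameter sets uniformly from their ranges
#'
#' Independent uniform draws per parameter per run, the sampling scheme of
#' the Monte Carlo calibration.
#'
#' @param ranges A [parameter_ranges()] object.
#' @param n Number of parameter sets to draw.
#' @return A data frame with `n` rows and one column per calibratable
#'   parameter.
#' @export
sample_parameters <- function(ranges, n) {
  stopifnot(inherits(ranges, "parameter_ranges"), n >= 1)
  out <- lapply(ranges, function(r) stats::runif(n, r[1], r[2]))
  as.data.frame(out)
}

#' Read and write soil-layer parameters as JSON
#'
#' Flat key-value JSON with the exact field names of
#' [soil_layer_params()].
#'
#' @param params A `soil_layer_params` object.
#' @param path File path.
#' @return `read_layer_params()` returns a `soil_layer_params` object;
#'   `write_layer_params()` returns `path` invisibly.
#' @export
write_layer_params <- function(params, path) {
  stopifnot(inherits(params, "soil_layer_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layer_params
#' @export
read_layer_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("C_S", "K_T", "C_ICE", "f_S", "T_LOW", "K_T_LOW", "C_S_LOW", "Z_S")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("read_layer_params: missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  do.call(soil_layer_params, x[c(need, intersect("Z_l", names(x)))])
}
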