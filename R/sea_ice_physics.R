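#' Brine salinity from ice temperature
#'
#' Computes the salinity of the brine held in sea-ice channels from the ice
#' temperature, using the closed form
#' \deqn{S_b = 1000 \, (1 - 54.11/T)^{-1}}
#' with \eqn{T} in degrees Celsius. In the bottommost centimetres of
#' first-year sea ice during the spring bloom, temperatures of roughly
#' -1.8 C (the seawater freezing point) to -3 C correspond to brine
#' salinities of about 32.2 to 52.5: the cells live in brine that is saltier
#' than the underlying seawater, which is why melt processing (dilution to
#' bulk salinities < 12) exposes them to strong osmotic stress.
#'
#' @param temperature Numeric vector of ice temperatures in degrees Celsius.
#'   Must lie in \code{[-22.9, 0)}; the relation is not used outside the
#'   range in which it is customarily applied.
#' @return Numeric vector of practical (dimensionless) brine salinities.
#'   Strictly decreasing in temperature on the valid range.
#' @examples
#' brine_salinity(c(-1.8, -3.0))
#' @export
brine_salinity <- function(temperature) {
  if (!is.numeric(temperature) || anyNA(temperature)) {
    stop("`temperature` must be numeric with no missing values", call. = FALSE)
  }
  if (any(temperature >= 0)) {
    stop("ice temperature must be below 0 degrees C (freezing)", call. = FALSE)
  }
  if (any(temperature < -22.9)) {
    stop("brine salinity relation is only valid for temperatures >= -22.9 degrees C",
         call. = FALSE)
  }
  1000 / (1 - 54.11 / temperature)
}

#' Conservative dilution line
#'
#' A dilution (conservative mixing) line from a reference
#' (salinity, concentration) point through the origin. Nutrient
#' concentrations in an ice melt that merely reflect trapped, diluted
#' seawater fall on this line; samples well above it carry a
#' non-conservative addition such as an intracellular pool released during
#' melt.
#'
#' @param concentration Reference nutrient concentration, umol L^-1 (e.g. the
#'   season-average 2-m water-column concentration). Must be >= 0.
#' @param salinity Reference practical salinity, > 0.
#' @return An object of class \code{"dilution_line"}.
#' @examples
#' dl <- dilution_line(14.7, 32)
#' dilution_concentration(dl, 16)
#' @export
dilution_line <- function(concentration, salinity) {
  stopifnot(length(concentration) == 1L, length(salinity) == 1L)
  if (!is.finite(concentration) || concentration < 0) {
    stop("reference concentration must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(salinity) || salinity <= 0) {
    stop("reference salinity must be finite and > 0", call. = FALSE)
  }
  structure(list(concentration = concentration, salinity = salinity),
            class = "dilution_line")
}

#' @export
print.dilution_line <- function(x, ...) {
  cat(sprintf("Dilution line through the origin: %.3g umol L^-1 at salinity %.3g\n",
              x$concentration, x$salinity))
  invisible(x)
}

#' Concentration expected from conservative dilution
#'
#' Evaluates a dilution line at given sample salinities: the concentration a
#' sample would have if its nutrient content came only from conservative
#' mixing of the reference water with fresh melt.
#'
#' @param line A [dilution_line()].
#' @param salinity Numeric vector of sample practical salinities, >= 0.
#' @return Numeric vector of concentrations, umol L^-1.
#' @export
dilution_concentration <- function(line, salinity) {
  stopifnot(inherits(line, "dilution_line"))
  if (!is.numeric(salinity) || anyNA(salinity) || any(salinity < 0)) {
    stop("sample salinity must be numeric and >= 0", call. = FALSE)
  }
  line$concentration * salinity / line$salinity
}

#' Classify samples relative to a dilution line
#'
#' Labels each (salinity, concentration) sample as lying \code{"above"},
#' \code{"on"}, or \code{"below"} the dilution line. A sample is "on" the
#' line when its concentration is within a relative tolerance of the line
#' value (with an absolute floor near the origin, where the relative band
#' collapses).
#'
#' @param salinity,concentration Numeric vectors of equal length.
#' @param line A [dilution_line()].
#' @param rel_tolerance Half-width of the "on" band as a fraction of the line
#'   value; in (0, 1). Default 0.15.
#' @param abs_floor Minimum half-width of the "on" band in umol L^-1,
#'   protecting the classification near zero salinity. Default 0.2.
#' @return A character vector with elements in
#'   \code{c("above", "on", "below")}; zero-length input gives a zero-length
#'   result.
#' @export
classify_vs_dilution_line <- function(salinity, concentration, line,
                                      rel_tolerance = 0.15, abs_floor = 0.2) {
  stopifnot(inherits(line, "dilution_line"),
            length(salinity) == length(concentration))
  if (!is.numeric(rel_tolerance) || rel_tolerance <= 0 || rel_tolerance >= 1) {
    stop("`rel_tolerance` must lie in (0, 1)", call. = FALSE)
  }
  if (length(salinity) == 0L) return(character(0))
  expected <- dilution_concentration(line, salinity)
  band <- pmax(rel_tolerance * expected, abs_floor)
  delta <- concentration - expected
  ifelse(abs(delta) <= band, "on", ifelse(delta > 0, "above", "below"))
}
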