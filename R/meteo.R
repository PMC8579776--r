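# Weather handling: saturation vapor pressure, VPD, flight-window means.

#' Saturation vapor pressure (Tetens / FAO-56 form)
#'
#' Computes the saturation vapor pressure of air at temperature `ta_c` using
#' the Tetens formulation with FAO-56 constants:
#' \deqn{e_s = 0.6108 \exp\left(\frac{17.27\,T_a}{T_a + 237.3}\right)}
#' This is the standard agrometeorological form; it is strictly increasing
#' in temperature.
#'
#' @param ta_c Air temperature in degrees C (vectorized). Must exceed -40.
#' @return Saturation vapor pressure in kPa.
#' @examples
#' saturation_vapor_pressure(0)   # 0.6108
#' saturation_vapor_pressure(25)
#' @export
saturation_vapor_pressure <- function(ta_c) {
  if (any(!is.finite(ta_c))) stop("ta_c must be finite")
  if (any(ta_c <= -40)) stop("ta_c out of physical range (<= -40 degC)")
  0.6108 * exp(17.27 * ta_c / (ta_c + 237.3))
}

#' Slope of the saturation vapor pressure curve
#'
#' The derivative of [saturation_vapor_pressure()] with respect to air
#' temperature (FAO-56), used by the energy-balance lower limit of the crop
#' water stress index.
#'
#' @param ta_c Air temperature in degrees C.
#' @return Slope in kPa per degree C.
#' @export
svp_slope <- function(ta_c) {
  4098 * saturation_vapor_pressure(ta_c) / (ta_c + 237.3)^2
}

#' Vapor pressure deficit
#'
#' VPD is the difference between the saturation vapor pressure at air
#' temperature and the actual vapor pressure:
#' `vpd = es(ta) * (1 - rh/100)`. It quantifies the atmospheric demand for
#' water and drives transpirational cooling.
#'
#' @param ta_c Air temperature, degrees C.
#' @param rh_pct Relative humidity, percent, in `[0, 100]`.
#' @return VPD in kPa (non-negative).
#' @examples
#' vapor_pressure_deficit(32.83, 38.78)  # ~3.05 kPa
#' @export
vapor_pressure_deficit <- function(ta_c, rh_pct) {
  if (any(!is.finite(rh_pct)) || any(rh_pct < 0) || any(rh_pct > 100)) {
    stop("rh_pct must lie in [0, 100]")
  }
  saturation_vapor_pressure(ta_c) * (1 - rh_pct / 100)
}

#' Read a minute-resolution weather series
#'
#' Expects a CSV with columns `timestamp` (ISO-8601), `ta_c`, `rh_pct`,
#' `ws_ms` and optionally `vpd_kpa`. If `vpd_kpa` is absent it is derived
#' from `ta_c` and `rh_pct`.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `weather_series`, ordered by timestamp.
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "ta_c", "rh_pct", "ws_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("weather CSV missing columns: ", paste(miss, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                            "%Y-%m-%dT%H:%M:%OS",
                                            "%Y-%m-%d %H:%M:%OS",
                                            "%Y-%m-%d %H:%M",
                                            "%Y-%m-%d"))
  weather_series(df)
}

#' Construct a weather series
#'
#' Validates and orders a data frame of minute weather records.
#'
#' @param df Data frame with `timestamp` (POSIXct), `ta_c`, `rh_pct`, `ws_ms`
#'   and optionally `vpd_kpa`.
#' @return The validated `weather_series` data frame.
#' @export
weather_series <- function(df) {
  if (any(df$rh_pct < 0 | df$rh_pct > 100, na.rm = TRUE)) {
    stop("rh_pct outside [0, 100]")
  }
  if (any(df$ws_ms < 0, na.rm = TRUE)) stop("ws_ms must be non-negative")
  df <- df[order(df$timestamp), , drop = FALSE]
  if (any(duplicated(df$timestamp))) stop("timestamps must be strictly increasing")
  if (!"vpd_kpa" %in% names(df)) {
    df$vpd_kpa <- vapor_pressure_deficit(df$ta_c, df$rh_pct)
  }
  rownames(df) <- NULL
  class(df) <- c("weather_series", "data.frame")
  df
}

#' Flight-window mean weather
#'
#' Averages air temperature, relative humidity and wind speed over all
#' records falling in the half-open window `[start, start + duration_min)`,
#' then recomputes VPD from the mean temperature and mean humidity (so a
#' flight is summarized by one consistent Ta/RH/VPD triple).
#'
#' @param series A [weather_series()].
#' @param start Window start (POSIXct or ISO-8601 string).
#' @param duration_min Window length in minutes (default 17, a typical
#'   survey flight).
#' @return One-row data frame: `ta_c`, `rh_pct`, `ws_ms`, `vpd_kpa`, `n_records`.
#' @export
flight_mean_weather <- function(series, start, duration_min = 17) {
  if (is.character(start)) start <- as.POSIXct(start, tz = "UTC")
  end <- start + duration_min * 60
  sel <- series$timestamp >= start & series$timestamp < end
  if (!any(sel)) stop("no weather records in the flight window")
  ta <- mean(series$ta_c[sel])
  rh <- mean(series$rh_pct[sel])
  data.frame(ta_c = ta, rh_pct = rh, ws_ms = mean(series$ws_ms[sel]),
             vpd_kpa = vapor_pressure_deficit(ta, rh), n_records = sum(sel))
}

#' Flight-campaign weather summary shipped with the package
#'
#' Returns the flight-level weather table for the five survey dates of the
#' tomato salinity field trial the package's defaults emulate: date, start
#' time, mean air temperature, relative humidity, wind speed and the
#' reported VPD for each 17-minute flight.
#'
#' @return Data frame with columns `flight_date`, `start_time`, `ta_c`,
#'   `rh_pct`, `ws_ms`, `vpd_kpa`.
#' @export
flight_weather_table <- function() {
  path <- system.file("extdata", "flight_weather.csv", package = "thermopheno",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Masking-variant temperature dispersion summary shipped with the package
#'
#' Per-flight maximum and mean of the per-plant standard deviation of plant
#' temperature under two vegetation-mask variants: the green-red vegetation
#' index threshold alone (`grvi`), and the same threshold combined with the
#' air-temperature ceiling Tp < Ta + 9 degC (`grvi_ta9`). Used to summarize
#' how much the temperature ceiling tightens per-plant dispersion.
#'
#' @return Data frame with columns `flight_date`, `mask`, `max_sigma_c`,
#'   `mean_sigma_c`.
#' @export
mask_sigma_table <- function() {
  path <- system.file("extdata", "mask_sigma_summary.csv",
                      package = "thermopheno", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
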