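#' Constants for the international barometric formula
#'
#' @param T0 Sea-level standard temperature, K.
#' @param lapse Temperature gradient dT/dh, K per m.
#' @param kappa Heat-capacity ratio (dimensionless).
#' @return A list of class `barometric_constants`.
#' @export
barometric_constants <- function(T0 = 288.15, lapse = 0.0065, kappa = 1.235) {
  stopifnot(T0 > 0, lapse > 0, kappa > 0)
  structure(list(T0 = T0, lapse = lapse, kappa = kappa),
            class = "barometric_constants")
}

#' Barometric altitude from tag pressure
#'
#' International barometric formula:
#' \deqn{h = \frac{T_0}{dT/dh}\left(1 - (p_h/p_0)^{(\kappa-1)/\kappa}\right)}
#' with defaults T0 = 288.15 K, dT/dh = 0.0065 K/m, kappa = 1.235, so the
#' exponent is 0.235/1.235. Because geolocation gives only approximate
#' positions, the result is altitude above sea level, never above ground.
#'
#' @param p_h Pressure measured at the bird, hPa.
#' @param p_0 Sea-level pressure at the bird's position, hPa.
#' @param constants A [barometric_constants()] object.
#' @return Altitude in m ASL; vectorised.
#' @export
pressure_to_altitude <- function(p_h, p_0, constants = barometric_constants()) {
  if (any(!is.finite(p_h) & !is.na(p_h)) || any(p_h <= 0, na.rm = TRUE) ||
      any(p_0 <= 0, na.rm = TRUE))
    stop("pressures must be positive", call. = FALSE)
  e <- (constants$kappa - 1) / constants$kappa
  constants$T0 / constants$lapse * (1 - (p_h / p_0)^e)
}

#' Inverse of [pressure_to_altitude()]: pressure at a given altitude
#'
#' @param h Altitude, m ASL.
#' @inheritParams pressure_to_altitude
#' @return Pressure in hPa.
#' @export
altitude_to_pressure <- function(h, p_0, constants = barometric_constants()) {
  if (any(p_0 <= 0, na.rm = TRUE)) stop("p_0 must be positive", call. = FALSE)
  e <- (constants$kappa - 1) / constants$kappa
  p_0 * (1 - h * constants$lapse / constants$T0)^(1 / e)
}

#' Flight altitude at a twilight event
#'
#' Mean of the two pressure-derived altitude samples closest to the event:
#' the nearest sample on each side when both sides have one inside the
#' search window, otherwise the two nearest overall.
#'
#' @param altitude A data frame with columns `time` (POSIXct UTC) and `alt`
#'   (m ASL), 30-min cadence, NA rows allowed (gaps).
#' @param event_time POSIXct of the twilight event.
#' @param window Half-width of the search window, seconds (default 90 min).
#' @return Mean altitude (m), or `NA_real_` if fewer than two usable samples
#'   fall inside the window (missing-data signal).
#' @export
altitude_at_twilight <- function(altitude, event_time, window = 90 * 60) {
  dt <- as.numeric(altitude$time) - as.numeric(event_time)
  ok <- abs(dt) <= window & !is.na(altitude$alt)
  if (sum(ok) < 2L) return(NA_real_)
  dt <- dt[ok]; alt <- altitude$alt[ok]
  before <- dt <= 0
  if (any(before) && any(!before)) {
    i1 <- which(before)[which.max(dt[before])]   # nearest at-or-before
    i2 <- which(!before)[which.min(dt[!before])] # nearest after
    mean(c(alt[i1], alt[i2]))
  } else {
    mean(alt[order(abs(dt))[1:2]])
  }
}

#' Baseline flight altitude around a twilight event
#'
#' Mean altitude over the 6 h before and 6 h after the event, excluding the
#' hour centred on the event itself, i.e. over
#' `[t - 6.5 h, t - 0.5 h] U [t + 0.5 h, t + 6.5 h]`.
#'
#' @inheritParams altitude_at_twilight
#' @param half_window Outer half-width, seconds (default 6.5 h).
#' @param exclude Half-width of the excluded twilight hour, seconds.
#' @param min_coverage Minimum fraction of the expected 30-min samples that
#'   must be present (default 0.5).
#' @return Mean altitude (m), or `NA_real_` on insufficient coverage.
#' @export
baseline_altitude <- function(altitude, event_time, half_window = 6.5 * 3600,
                              exclude = 0.5 * 3600, min_coverage = 0.5) {
  dt <- as.numeric(altitude$time) - as.numeric(event_time)
  inwin <- abs(dt) <= half_window & abs(dt) > exclude & !is.na(altitude$alt)
  expected <- 2 * (half_window - exclude) / 1800
  if (sum(inwin) < min_coverage * expected) return(NA_real_)
  mean(altitude$alt[inwin])
}

#' Twilight-ascent statistic for one event
#'
#' Ascent height is the altitude at the twilight (mean of the two nearest
#' samples) minus the baseline altitude over the surrounding 12 h (twilight
#' hour excluded). An event counts as an ascent when the height reaches the
#' threshold (inclusive); the default 300 m follows the convention that
#' roughly half of observed ascents reach it, and 100 m is a supported
#' alternative.
#'
#' @inheritParams altitude_at_twilight
#' @param threshold Ascent threshold, m (default 300).
#' @param ... Passed on to [baseline_altitude()].
#' @return A one-row data frame: `event_time`, `altitude_at_twilight`,
#'   `baseline_altitude`, `ascent_height`, `is_ascent`. Missing-data signals
#'   propagate as NA (and `is_ascent` NA).
#' @export
ascent_height <- function(altitude, event_time, threshold = 300,
                          window = 90 * 60, ...) {
  at <- altitude_at_twilight(altitude, event_time, window = window)
  bl <- baseline_altitude(altitude, event_time, ...)
  h <- at - bl
  data.frame(event_time = event_time,
             altitude_at_twilight = at,
             baseline_altitude = bl,
             ascent_height = h,
             is_ascent = if (is.na(h)) NA else h >= threshold)
}

#' Distance to the horizon from a given height
#'
#' Line-of-sight distance `sqrt(2 R h)` over a spherical Earth
#' (R = 6371 km). A 300-m ascent, for example, pushes the horizon out to
#' about 62 km, enough to reveal a 10-km thundercloud some 60 km beyond the
#' sea-level horizon.
#'
#' @param h Height above the surface, m. Must be >= 0.
#' @return Distance in km.
#' @export
horizon_distance <- function(h) {
  if (any(h < 0, na.rm = TRUE)) stop("height must be non-negative", call. = FALSE)
  sqrt(2 * 6371 * (h / 1000))
}

#' How much earlier the sun is seen from a given height
#'
#' The horizon dip `acos(R / (R + h))` converted to time at the mean solar
#' angular rate of 0.25 degrees per minute. From 300 m the sun appears
#' roughly two minutes before it does at sea level.
#'
#' @param h Height above the surface, m. Must be >= 0.
#' @return Advance in minutes.
#' @export
sunrise_advance <- function(h) {
  if (any(h < 0, na.rm = TRUE)) stop("height must be non-negative", call. = FALSE)
  R <- 6371e3
  acos(R / (R + h)) * 180 / pi / 0.25
}
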