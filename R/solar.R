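#' Solar elevation angle
#'
#' Geometric elevation of the sun above the horizon, computed from the NOAA
#' general solar position equations (fractional-year ephemeris, equation of
#' time, declination, hour angle). Accuracy is a few hundredths of a degree,
#' ample for twilight work where the sun moves roughly 0.25 degrees per
#' minute.
#'
#' @param lat,lon Position in decimal degrees (WGS-84, north/east positive).
#' @param time `POSIXct` time(s), UTC.
#' @return Solar elevation in degrees; vectorised over `time` (and over
#'   `lat`/`lon` if they have matching length).
#' @export
solar_elevation <- function(lat, lon, time) {
  stopifnot(all(abs(lat) <= 90))
  time <- as.POSIXct(time, tz = "UTC")
  lt <- .local_solar(lat, lon, time)
  asin(pmin(1, pmax(-1,
    sin(lt$lat_r) * sin(lt$decl) +
      cos(lt$lat_r) * cos(lt$decl) * cos(lt$ha)
  ))) * 180 / pi
}

# NOAA (Meeus-based) ephemeris shared by elevation and twilight search:
# solar declination and equation of time from Julian centuries, with the
# sun's equation of center and apparent-longitude nutation correction.
.local_solar <- function(lat, lon, time) {
  d2r <- pi / 180
  jc <- (as.numeric(time) / 86400 + 2440587.5 - 2451545) / 36525
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M <- (357.52911 + jc * (35999.05029 - 0.0001537 * jc)) * d2r
  ecc <- 0.016708634 - jc * (0.000042037 + 1.267e-7 * jc)
  C <- sin(M) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M) * (0.019993 - 0.000101 * jc) + sin(3 * M) * 0.000289
  omega <- (125.04 - 1934.136 * jc) * d2r
  l_app <- (L0 + C - 0.00569 - 0.00478 * sin(omega)) * d2r
  eps <- (23.439291 - jc * (0.0130042 + jc * (1.64e-7 - 5.04e-7 * jc)) +
    0.00256 * cos(omega)) * d2r
  decl <- asin(sin(eps) * sin(l_app))
  y <- tan(eps / 2)^2
  L0r <- L0 * d2r
  eqtime <- 4 / d2r * (y * sin(2 * L0r) - 2 * ecc * sin(M) +
    4 * ecc * y * sin(M) * cos(2 * L0r) - 0.5 * y^2 * sin(4 * L0r) -
    1.25 * ecc^2 * sin(2 * M))                 # minutes
  hour <- as.numeric(time) %% 86400 / 3600
  tst <- hour * 60 + eqtime + 4 * lon          # true solar time, minutes
  ha <- (tst / 4 - 180) * d2r                  # hour angle, radians
  list(decl = decl, ha = ha, lat_r = lat * d2r, eqtime = eqtime)
}

#' Time of a twilight event
#'
#' Finds the instant the sun crosses a given elevation on a given date:
#' dawn is the rising crossing (before local solar noon), dusk the setting
#' crossing (after). The default elevation 0 corresponds to sunrise/sunset;
#' -6 and -12 give the civil and nautical twilight bounds.
#'
#' @param lat,lon Position in decimal degrees.
#' @param date A `Date` (or string coercible to one); the civil day, UTC.
#' @param type `"dawn"` or `"dusk"`.
#' @param elevation Threshold solar elevation in degrees (default 0).
#' @return A `POSIXct` (UTC) found to better than one second, or `NA` when
#'   the sun does not cross the elevation that day (polar day/night).
#' @export
twilight_time <- function(lat, lon, date, type = c("dawn", "dusk"),
                          elevation = 0) {
  type <- match.arg(type)
  date <- as.Date(date)
  if (length(date) > 1L) {
    out <- vapply(seq_along(date), function(i)
      as.numeric(twilight_time(lat, lon, date[i], type, elevation)),
      numeric(1))
    return(.POSIXct(out, tz = "UTC"))
  }
  day0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  # local solar noon in UTC minutes-of-day: tst == 720
  noon_guess <- 720 - 4 * lon
  noon <- day0 + 60 * noon_guess
  win <- if (type == "dawn") c(-12 * 3600, 0) else c(0, 12 * 3600)
  f <- function(s) solar_elevation(lat, lon, noon + s) - elevation
  lo <- f(win[1]); hi <- f(win[2])
  # dawn rises from lo to hi; dusk falls from lo(noon) to hi(midnight)
  if (is.na(lo) || is.na(hi) || sign(lo) == sign(hi)) {
    # no crossing in window: refine by scanning (handles near-grazing days)
    s <- seq(win[1], win[2], by = 300)
    v <- f(s)
    idx <- which(diff(sign(v)) != 0)
    if (length(idx) == 0L) return(.POSIXct(NA_real_, tz = "UTC"))
    win <- c(s[idx[1]], s[idx[1] + 1])
  }
  r <- stats::uniroot(f, lower = win[1], upper = win[2], tol = 0.5)
  noon + r$root
}
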