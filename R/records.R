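#' Complete the twilight set with astronomical events
#'
#' The ascent statistic needs one dawn and one dusk per day, but on days
#' when the light sensor recorded only an unnatural event (bird inside the
#' cavity) the twilight time must come from solar geometry instead. For
#' each civil day in the deployment this returns the detected natural event
#' where one exists and otherwise the astronomical crossing computed at the
#' position linearly interpolated along the supplied track (pinned to the
#' colony outside the natural-event span).
#'
#' @param events Data frame from [flag_unnatural()].
#' @param track Data frame `time`, `lat`, `lon` (median positions of the
#'   natural events).
#' @param colony Named vector `c(lat = , lon = )`.
#' @param dates Vector of civil dates to cover.
#' @param sun_elev Solar elevation defining the twilight, degrees.
#' @return Data frame `time`, `type`, `natural`, `source`, `lat`, `lon`
#'   (position along the track), one row per day and type where a time
#'   exists.
#' @export
complete_twilights <- function(events, track, colony, dates, sun_elev = 0) {
  nat <- events[!is.na(events$natural) & events$natural, ]
  nat_date <- as.Date(nat$time)
  rows <- list()
  for (d in as.list(dates)) {
    for (ty in c("dawn", "dusk")) {
      hit <- nat$type == ty & nat_date == d
      if (any(hit)) {
        tm <- nat$time[which(hit)[1]]
        src <- "observed-threshold"; natu <- TRUE
      } else {
        # position guess for the astronomical fallback
        noon <- as.POSIXct(paste(d, "12:00:00"), tz = "UTC")
        p <- interpolate_position(track, noon, colony = colony)
        tm <- twilight_time(p$lat, p$lon, d, ty, elevation = sun_elev)
        src <- "computed-astronomical"; natu <- FALSE
      }
      if (!is.na(tm)) {
        p <- interpolate_position(track, tm, colony = colony)
        rows[[length(rows) + 1]] <-
          data.frame(time = tm, type = ty, natural = natu, source = src,
                     lat = p$lat, lon = p$lon)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$time), ]
}

#' Barometric altitude series for a tag
#'
#' Converts the 30-min pressure channel to altitude ASL using the sea-level
#' pressure read from the weather grid at the bird's interpolated position
#' at each sample time.
#'
#' @param series A [sensor_series()].
#' @param track Data frame `time`, `lat`, `lon` used for the position.
#' @param grid A [weather_grid()].
#' @param colony Named vector for edge pinning.
#' @param constants [barometric_constants()].
#' @return Data frame `time`, `alt` (m ASL; NA where pressure is missing or
#'   the position leaves the grid).
#' @export
altitude_series <- function(series, track, grid, colony,
                            constants = barometric_constants()) {
  p <- series$pressure
  pos <- interpolate_position(track, p$time, colony = colony)
  k <- .window_index(grid, p$time)
  cell <- .nearest_cell(grid, pos$lat, pos$lon)
  ok <- cell$ok & k >= 1 & k <= length(grid$time) & !is.na(p$value)
  p0 <- rep(NA_real_, nrow(p))
  p0[ok] <- grid$vars$mslp[cbind(cell$i[ok], cell$j[ok], k[ok])]
  data.frame(time = p$time,
             alt = ifelse(ok, pressure_to_altitude(p$value, p0, constants),
                          NA_real_))
}

#' Assemble per-twilight ascent records for one individual
#'
#' One row per twilight event: the ascent statistic (altitude at twilight,
#' 12-h baseline, height, threshold flag), the phase of the event position,
#' and the weather annotation with 24-h change factors — the table the
#' regression consumes.
#'
#' @param series A [sensor_series()].
#' @param twilights Data frame from [complete_twilights()].
#' @param track Data frame `time`, `lat`, `lon`: positions for this
#'   realisation (median track or one bootstrap draw).
#' @param grid A [weather_grid()].
#' @param colony Named vector `c(lat = , lon = )`.
#' @param threshold Ascent threshold, m (default 300).
#' @param constants [barometric_constants()].
#' @return Data frame with identifiers, `seq` (twilight order), event
#'   fields, ascent fields, `flight_alt` (the 12-h baseline) and weather
#'   columns.
#' @export
build_ascent_records <- function(series, twilights, track, grid, colony,
                                 threshold = 300,
                                 constants = barometric_constants()) {
  alt <- altitude_series(series, track, grid, colony, constants)
  pos <- interpolate_position(track, twilights$time, colony = colony)
  asc <- do.call(rbind, lapply(seq_len(nrow(twilights)), function(i)
    ascent_height(alt, twilights$time[i], threshold = threshold)))
  wx <- annotate_weather(data.frame(time = twilights$time,
                                    lat = pos$lat, lon = pos$lon), grid)
  data.frame(individual = series$individual_id,
             population = series$population_id,
             seq = seq_len(nrow(twilights)),
             time = twilights$time, type = twilights$type,
             natural = twilights$natural, source = twilights$source,
             lat = pos$lat, lon = pos$lon,
             phase = phase_of_position(pos$lat, pos$lon, colony),
             altitude_at_twilight = asc$altitude_at_twilight,
             flight_alt = asc$baseline_altitude,
             ascent_height = asc$ascent_height,
             is_ascent = asc$is_ascent,
             wx[, setdiff(names(wx), c("time", "lat", "lon"))],
             stringsAsFactors = FALSE)
}
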