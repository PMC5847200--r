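#' Gridded weather field
#'
#' Regular lat/lon grid (2.5 degrees by default, matching global reanalysis
#' products) at 6-h steps, carrying mean sea-level pressure (hPa),
#' temperature at 2 m (K), relative humidity (%) and scalar wind speed
#' (m/s) at the 1000-mbar level — the level aerial foragers occupy most of
#' the time.
#'
#' @param lat,lon Vectors of grid-cell centres, degrees, regular spacing.
#' @param time POSIXct vector of 6-h window starts, UTC.
#' @param mslp,t2m,rh,wind Arrays `[lat, lon, time]`.
#' @return An object of class `weather_grid`.
#' @export
weather_grid <- function(lat, lon, time, mslp, t2m, rh, wind) {
  stopifnot(length(unique(round(diff(lat), 6))) <= 1,
            length(unique(round(diff(lon), 6))) <= 1)
  time <- as.POSIXct(time, tz = "UTC")
  if (length(time) > 1 && any(diff(as.numeric(time)) != 21600))
    stop("time steps must be uniform at 6 h", call. = FALSE)
  dims <- c(length(lat), length(lon), length(time))
  for (v in list(mslp, t2m, rh, wind)) stopifnot(all(dim(v) == dims))
  structure(list(lat = lat, lon = lon, time = time,
                 vars = list(mslp = mslp, t2m = t2m, rh = rh, wind = wind)),
            class = "weather_grid")
}

#' @export
print.weather_grid <- function(x, ...) {
  cat(sprintf("<weather_grid> %d x %d cells, %d six-hour steps (%s .. %s)\n",
              length(x$lat), length(x$lon), length(x$time),
              format(min(x$time)), format(max(x$time))))
  invisible(x)
}

# Index of the 6-h window containing t; an event exactly on a boundary is
# assigned to the window starting at that boundary.
.window_index <- function(grid, t) {
  floor((as.numeric(t) - as.numeric(grid$time[1])) / 21600) + 1
}

.nearest_cell <- function(grid, lat, lon) {
  i <- round((lat - grid$lat[1]) / diff(grid$lat[1:2])) + 1
  j <- round((lon - grid$lon[1]) / diff(grid$lon[1:2])) + 1
  list(i = i, j = j,
       ok = i >= 1 & i <= length(grid$lat) & j >= 1 & j <= length(grid$lon))
}

#' Annotate twilight events with weather and 24-h change factors
#'
#' For each event the 6-h forecast window containing it is selected and the
#' nearest grid cell to the (interpolated) position is read out. Change
#' factors are the differences between that window and the windows 24 h
#' before and 24 h after, for pressure, temperature and humidity; the model
#' uses their absolute values ("stable versus changing weather",
#' disregarding sign), but signed versions are kept alongside. Wind enters
#' as a state variable only, never as a change factor.
#'
#' @param track Data frame with columns `time` (POSIXct), `lat`, `lon`: the
#'   position at each twilight event.
#' @param grid A [weather_grid()].
#' @return Data frame, one row per event: `mslp`, `t2m`, `rh`, `wind`,
#'   absolute deltas `dmslp_before/after`, `dtemp_*`, `drh_*`, their signed
#'   counterparts (`*_signed`), and `in_domain`. Events outside the grid's
#'   spatial or temporal domain get NA values and `in_domain = FALSE`.
#' @export
annotate_weather <- function(track, grid) {
  stopifnot(inherits(grid, "weather_grid"),
            all(c("time", "lat", "lon") %in% names(track)))
  n <- nrow(track)
  k <- .window_index(grid, track$time)
  cell <- .nearest_cell(grid, track$lat, track$lon)
  ok <- cell$ok & k >= 1 & k <= length(grid$time)
  pick <- function(var, kk) {
    out <- rep(NA_real_, n)
    use <- ok & kk >= 1 & kk <= length(grid$time)
    if (any(use))
      out[use] <- grid$vars[[var]][cbind(cell$i[use], cell$j[use], kk[use])]
    out
  }
  out <- data.frame(time = track$time, lat = track$lat, lon = track$lon,
                    in_domain = ok)
  for (v in c("mslp", "t2m", "rh", "wind")) out[[v]] <- pick(v, k)
  dv <- c(mslp = "dmslp", t2m = "dtemp", rh = "drh")
  for (v in names(dv)) {
    now <- out[[v]]
    before <- now - pick(v, k - 4L)  # 24 h = four 6-h steps
    after  <- pick(v, k + 4L) - now
    out[[paste0(dv[[v]], "_before_signed")]] <- before
    out[[paste0(dv[[v]], "_after_signed")]]  <- after
    out[[paste0(dv[[v]], "_before")]] <- abs(before)
    out[[paste0(dv[[v]], "_after")]]  <- abs(after)
  }
  out
}

#' z-transform a covariate
#'
#' Centre on the mean and scale by the standard deviation (n - 1
#' denominator), so effect sizes of model factors are comparable.
#'
#' @param x Numeric vector with at least two distinct non-NA values.
#' @return Standardised vector (mean 0, sd 1 over non-NA entries).
#' @export
z_transform <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2) stop("z_transform needs at least 2 values", call. = FALSE)
  s <- stats::sd(v)
  if (s == 0)
    stop(structure(class = c("degenerate_factor", "error", "condition"),
                   list(message = "zero variance: degenerate factor",
                        call = sys.call(-1))))
  (x - mean(v)) / s
}

#' Serialise a weather grid to long-format CSV
#'
#' Plain-text interchange for the grid: columns `time`, `lat`, `lon`,
#' `mslp`, `t2m`, `rh`, `wind`. [read_weather_csv()] restores an identical
#' [weather_grid()].
#'
#' @param grid A `weather_grid`.
#' @param path File path.
#' @export
write_weather_csv <- function(grid, path) {
  idx <- expand.grid(lat = grid$lat, lon = grid$lon,
                     time = format(grid$time, "%Y-%m-%dT%H:%M:%SZ"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(time = idx$time, lat = idx$lat, lon = idx$lon)
  for (v in names(grid$vars)) df[[v]] <- as.vector(grid$vars[[v]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  tim <- sort(unique(as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC")))
  dims <- c(length(lat), length(lon), length(tim))
  o <- order(match(as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC"), tim),
             match(df$lon, lon), match(df$lat, lat))
  mk <- function(v) array(df[[v]][o], dim = dims)
  weather_grid(lat, lon, tim, mk("mslp"), mk("t2m"), mk("rh"), mk("wind"))
}
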