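#' Per-individual multi-sensor tag series
#'
#' Container for one tag deployment: light and activity every 5 min,
#' pressure and temperature every 30 min, all timestamps UTC. Gaps are kept
#' as explicit NA values, never interpolated here; each downstream
#' operation declares its own gap tolerance.
#'
#' @param individual_id,population_id Identifier strings.
#' @param light,activity Data frames with columns `time` (POSIXct UTC) and
#'   `value`, 5-min cadence.
#' @param pressure,temperature Data frames with columns `time` and `value`,
#'   30-min cadence; pressure in hPa, temperature in deg C.
#' @return An object of class `sensor_series`.
#' @export
sensor_series <- function(individual_id, population_id,
                          light, activity, pressure, temperature) {
  chk <- function(df, name) {
    stopifnot(is.data.frame(df), all(c("time", "value") %in% names(df)))
    df$time <- as.POSIXct(df$time, tz = "UTC")
    if (is.unsorted(as.numeric(df$time), strictly = TRUE))
      stop(name, ": timestamps must be strictly increasing", call. = FALSE)
    df[, c("time", "value")]
  }
  light <- chk(light, "light"); activity <- chk(activity, "activity")
  pressure <- chk(pressure, "pressure"); temperature <- chk(temperature, "temperature")
  if (any(activity$value < 0, na.rm = TRUE))
    stop("activity must be non-negative", call. = FALSE)
  pv <- pressure$value
  if (any(pv <= 300 | pv >= 1100, na.rm = TRUE))
    stop("pressure outside plausible range (300, 1100) hPa", call. = FALSE)
  structure(list(individual_id = as.character(individual_id),
                 population_id = as.character(population_id),
                 light = light, activity = activity,
                 pressure = pressure, temperature = temperature),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat("<sensor_series>", x$individual_id, "(population", x$population_id, ")\n")
  for (ch in c("light", "activity", "pressure", "temperature")) {
    df <- x[[ch]]
    cat(sprintf("  %-12s %6d samples  %s .. %s\n", ch, nrow(df),
                format(min(df$time)), format(max(df$time))))
  }
  invisible(x)
}

.check_burst <- function(samples, n = 32, range_g = 16) {
  if (length(samples) != n)
    stop("malformed burst: expected ", n, " samples, got ", length(samples),
         call. = FALSE)
  if (any(abs(samples) > range_g, na.rm = TRUE))
    stop("malformed burst: sample outside sensor range", call. = FALSE)
  invisible(samples)
}

#' Activity score from a raw acceleration burst
#'
#' The tag samples vertical (z-axis) acceleration at 10 Hz for 3.2 s and
#' stores the cumulative absolute change across the burst — a proxy for
#' wing-flapping intensity. Deployed tags store only this summary; the raw
#' burst form exists so simulated tags can be generated from first
#' principles.
#'
#' @param samples Numeric vector of 32 z-axis acceleration values (g).
#' @param range_g Sensor range, g (default 16).
#' @return Non-negative activity score: `sum(abs(diff(samples)))`.
#' @export
activity_from_burst <- function(samples, range_g = 16) {
  .check_burst(samples, range_g = range_g)
  sum(abs(diff(samples)))
}

#' Pitch proxy from a raw acceleration burst
#'
#' Mean z-axis acceleration over the 3.2-s burst: the gravitational
#' component indicating body-axis angle. Recorded by the tags but not used
#' by the ascent analysis.
#'
#' @inheritParams activity_from_burst
#' @return Mean acceleration (g).
#' @export
pitch_from_burst <- function(samples, range_g = 16) {
  .check_burst(samples, range_g = range_g)
  mean(samples)
}

#' Write / read the tag CSV dialect
#'
#' One file per individual, long format with columns
#' `timestamp` (ISO-8601 UTC), `channel`, `value`. Round-trips a
#' [sensor_series()] exactly (values printed at full precision).
#'
#' @param x A `sensor_series`.
#' @param path File path.
#' @export
write_tag_csv <- function(x, path) {
  stopifnot(inherits(x, "sensor_series"))
  rows <- do.call(rbind, lapply(c("light", "activity", "pressure", "temperature"),
    function(ch) data.frame(
      timestamp = format(x[[ch]]$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      channel = ch, value = sprintf("%.10g", x[[ch]]$value),
      stringsAsFactors = FALSE)))
  rows$value[rows$value == "NA"] <- ""
  header <- sprintf("# individual_id=%s population_id=%s",
                    x$individual_id, x$population_id)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tag_csv
#' @export
read_tag_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
    regexec("individual_id=(\\S+) population_id=(\\S+)", header))[[1]]
  if (length(m) != 3L) stop("not a tag CSV: missing id header", call. = FALSE)
  df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
  get <- function(ch) {
    d <- df[df$channel == ch, ]
    data.frame(time = as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"),
               value = d$value)
  }
  sensor_series(m[2], m[3], get("light"), get("activity"),
                get("pressure"), get("temperature"))
}

#' Read a deployment manifest
#'
#' YAML file mapping individuals to populations, colony coordinates and
#' deployment windows:
#' ```yaml
#' individuals:
#'   - id: CH001
#'     population: baden
#'     colony: {lat: 47.47, lon: 8.31}
#'     deployed: 2014-07-15
#'     retrieved: 2015-06-15
#'     file: CH001.csv
#' ```
#'
#' @param path Path to the YAML manifest.
#' @return A data frame with one row per individual.
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(y$individuals, function(ind)
    data.frame(id = ind$id, population = ind$population,
               colony_lat = ind$colony$lat, colony_lon = ind$colony$lon,
               deployed = as.Date(ind$deployed),
               retrieved = as.Date(ind$retrieved),
               file = if (is.null(ind$file)) NA_character_ else ind$file,
               stringsAsFactors = FALSE)))
}
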