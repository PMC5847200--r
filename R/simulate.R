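#' Configuration for the synthetic annual cycle
#'
#' Defines the study conditions the generator emulates: a colony in the
#' European mid-latitudes, an autumn migration to a West-African
#' non-breeding site and a spring return, tag sampling at 5 min (light,
#' activity) and 30 min (pressure, temperature), per-phase twilight-ascent
#' probabilities with dawn favoured over dusk, and a synthetic synoptic
#' weather field with travelling fronts.
#'
#' @param colony_lat,colony_lon Colony coordinates, degrees.
#' @param colony_elev Colony ground elevation, m ASL.
#' @param start,end Deployment window (Date or string).
#' @param autumn_start,autumn_end,spring_start,spring_end Migration windows.
#' @param nb_lat,nb_lon Non-breeding residence site, degrees.
#' @param p_dawn_ascent Named numeric: dawn ascent probability per phase
#'   (`breeding`, `migration`, `nonbreeding`), each in `[0, 1]`.
#' @param dusk_odds Odds ratio of a dusk ascent relative to dawn (default
#'   0.5: dawn ascents twice as likely on the odds scale).
#' @param ascent_mean,ascent_sd Drawn ascent height, m (truncated at 0).
#' @param nonascent_mean Named numeric: mean twilight altitude offset (m)
#'   at non-ascent twilights per phase (the mild twilight altitude peak at
#'   non-breeding, a slight dip during migration).
#' @param nonascent_sd Spread of the non-ascent offset, m.
#' @param ascent_threshold Height defining a true ascent, m.
#' @param cruise_alt Named numeric: typical altitude (m ASL) for
#'   `breeding_day`, `migration_glide`, `migration_bout`, `nonbreeding`.
#' @param alt_wander_sd Within-day altitude wander innovation sd, m per
#'   5-min step (AR(1), coefficient 0.95); 0 freezes the flight level.
#' @param day_alt_sd Day-to-day cruising-altitude offset sd, m (AR(1)
#'   across days, coefficient 0.5).
#' @param nb_diurnal_amp Amplitude of the diurnal altitude cycle at the
#'   non-breeding site, m (higher by day).
#' @param light_max Light-sensor ceiling, arbitrary units.
#' @param light_k Logistic width (degrees solar elevation) of the light
#'   transfer function; the threshold `light_max / 2` is crossed at solar
#'   elevation 0.
#' @param light_noise_sd,pressure_noise_sd Sensor noise, light units / hPa.
#' @param activity Named numeric: `flap_mean`, `flap_sd`, `glide_mean`,
#'   `glide_sd`, `rest_mean`, `rest_sd` in raw cumulative-change units.
#' @param cavity_p Probability a breeding-phase twilight is spent inside
#'   the cavity (light truncated to zero, producing an unnatural event).
#' @param nb_jitter_sd Daily position jitter at the non-breeding site, deg.
#' @param base_mslp Background mean sea-level pressure, hPa.
#' @param front_freq Expected number of fronts per 30 days.
#' @param front_amp Peak pressure anomaly of a front, hPa.
#' @param grid_lat,grid_lon Weather-grid bounding box, degrees.
#' @param grid_res Weather-grid resolution, degrees.
#' @param seed Integer master seed; every random draw derives from it.
#' @return An object of class `sim_config` (a validated list; the light
#'   threshold implied by the transfer function is stored as
#'   `light_threshold`).
#' @export
sim_config <- function(colony_lat = 47.47, colony_lon = 8.31,
                       colony_elev = 400,
                       start = "2014-07-15", end = "2015-06-10",
                       autumn_start = "2014-09-05", autumn_end = "2014-10-05",
                       spring_start = "2015-03-20", spring_end = "2015-04-18",
                       nb_lat = 10.5, nb_lon = -11,
                       p_dawn_ascent = c(breeding = 0.05, migration = 0.25,
                                         nonbreeding = 0.5),
                       dusk_odds = 0.5,
                       ascent_mean = 400, ascent_sd = 100,
                       nonascent_mean = c(breeding = 0, migration = -60,
                                          nonbreeding = 120),
                       nonascent_sd = 90,
                       ascent_threshold = 300,
                       cruise_alt = c(breeding_day = 800,
                                      migration_glide = 1200,
                                      migration_bout = 2500,
                                      nonbreeding = 900),
                       alt_wander_sd = 20, day_alt_sd = 220,
                       nb_diurnal_amp = 150,
                       light_max = 64, light_k = 1.5,
                       light_noise_sd = 1, pressure_noise_sd = 0.5,
                       activity = c(flap_mean = 40, flap_sd = 8,
                                    glide_mean = 5, glide_sd = 2,
                                    rest_mean = 0.5, rest_sd = 0.4),
                       cavity_p = 0.9,
                       nb_jitter_sd = 0.15,
                       base_mslp = 1013.25, front_freq = 4, front_amp = 12,
                       grid_lat = c(-12.5, 60), grid_lon = c(-20, 42.5),
                       grid_res = 2.5,
                       seed = 42) {
  cfg <- list(colony_lat = colony_lat, colony_lon = colony_lon,
              colony_elev = colony_elev,
              start = as.Date(start), end = as.Date(end),
              autumn_start = as.Date(autumn_start),
              autumn_end = as.Date(autumn_end),
              spring_start = as.Date(spring_start),
              spring_end = as.Date(spring_end),
              nb_lat = nb_lat, nb_lon = nb_lon,
              p_dawn_ascent = p_dawn_ascent, dusk_odds = dusk_odds,
              ascent_mean = ascent_mean, ascent_sd = ascent_sd,
              nonascent_mean = nonascent_mean, nonascent_sd = nonascent_sd,
              ascent_threshold = ascent_threshold,
              cruise_alt = cruise_alt,
              alt_wander_sd = alt_wander_sd, day_alt_sd = day_alt_sd,
              nb_diurnal_amp = nb_diurnal_amp,
              light_max = light_max, light_k = light_k,
              light_threshold = light_max / 2,
              light_noise_sd = light_noise_sd,
              pressure_noise_sd = pressure_noise_sd,
              activity = activity, cavity_p = cavity_p,
              nb_jitter_sd = nb_jitter_sd,
              base_mslp = base_mslp, front_freq = front_freq,
              front_amp = front_amp,
              grid_lat = grid_lat, grid_lon = grid_lon, grid_res = grid_res,
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  p <- cfg$p_dawn_ascent
  if (!all(c("breeding", "migration", "nonbreeding") %in% names(p)) ||
      any(p < 0 | p > 1))
    stop("invalid config: p_dawn_ascent must name all phases with values in [0, 1]",
         call. = FALSE)
  if (cfg$cavity_p < 0 || cfg$cavity_p > 1)
    stop("invalid config: cavity_p must be in [0, 1]", call. = FALSE)
  d <- c(cfg$start, cfg$autumn_start, cfg$autumn_end,
         cfg$spring_start, cfg$spring_end, cfg$end)
  if (is.unsorted(as.numeric(d), strictly = TRUE))
    stop("invalid config: phase calendar must be ordered and non-overlapping",
         call. = FALSE)
  if (cfg$ascent_sd < 0 || cfg$nonascent_sd < 0 ||
      cfg$light_noise_sd < 0 || cfg$pressure_noise_sd < 0 ||
      cfg$alt_wander_sd < 0 || cfg$day_alt_sd < 0)
    stop("invalid config: negative noise level", call. = FALSE)
  invisible(cfg)
}

# Run code with a derived seed, restoring the caller's RNG stream after.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed %% .Machine$integer.max)
  code
}

# Deterministic front catalogue for the synoptic field (shared by the
# gridded product and the continuous truth the tag-pressure encoder uses).
.weather_fronts <- function(config) {
  span_days <- as.numeric(config$end + 2 - (config$start - 2))
  .with_seed(config$seed + 1000L, {
    n <- stats::rpois(1, config$front_freq * span_days / 30)
    if (n == 0 || config$front_amp == 0)
      return(data.frame(t0 = numeric(0), life = numeric(0), lat0 = numeric(0),
                        lon0 = numeric(0), vlat = numeric(0), vlon = numeric(0),
                        sigma = numeric(0), amp = numeric(0)))
    t_origin <- as.numeric(as.POSIXct(paste(config$start - 2, "00:00:00"),
                                      tz = "UTC"))
    data.frame(
      t0 = t_origin + stats::runif(n, 0, span_days * 86400),
      life = stats::runif(n, 3, 6) * 86400,
      lat0 = stats::runif(n, 20, 55),
      lon0 = stats::runif(n, config$grid_lon[1] - 5, config$grid_lon[2] - 10),
      vlat = stats::rnorm(n, 0, 1.5) / 86400,   # deg per second
      vlon = stats::runif(n, 5, 10) / 86400,
      sigma = stats::runif(n, 5, 8),
      amp = config$front_amp * stats::runif(n, 0.6, 1.4))
  })
}

# Continuous weather field: analytic functions of (lat, lon, t-seconds).
.weather_field <- function(config, fronts = .weather_fronts(config)) {
  gauss <- function(lat, lon, t) {
    g <- rep(0, max(length(lat), length(lon), length(t)))
    if (nrow(fronts) == 0) return(g)
    for (i in seq_len(nrow(fronts))) {
      f <- fronts[i, ]
      dt <- t - f$t0
      env <- sin(pi * pmin(pmax(dt / f$life, 0), 1))
      clat <- f$lat0 + f$vlat * dt
      clon <- f$lon0 + f$vlon * dt
      d2 <- (lat - clat)^2 + (lon - clon)^2
      g <- g + env * exp(-d2 / (2 * f$sigma^2))
    }
    g
  }
  # each variable adds its own deterministic texture (distinct periods and
  # spatial phases) so the four fields are correlated through fronts but
  # never collinear
  day <- 86400
  list(
    fronts = fronts,
    mslp = function(lat, lon, t) config$base_mslp -
      .front_amp_sum(fronts, lat, lon, t) +
      0.125 * config$front_amp * sin(2 * pi * t / (4.3 * day) + lon / 15),
    t2m  = function(lat, lon, t) 299 - 0.15 * abs(lat - 5) -
      3 * gauss(lat, lon, t) + 1.2 * sin(2 * pi * t / day) +
      2.5 * sin(2 * pi * t / (5.3 * day) + lon / 8) +
      2 * sin(2 * pi * t / (365 * day) + lat / 20),
    rh   = function(lat, lon, t) pmin(100, pmax(5,
      55 + 30 * gauss(lat, lon, t) +
        8 * sin(2 * pi * t / (2.7 * day) + 0.3 * lon))),
    wind = function(lat, lon, t) pmax(0.2,
      4 + 8 * gauss(lat, lon, t) +
        1.5 * sin(2 * pi * t / (1.9 * day) + 0.5 * lat)))
}

# Pressure anomaly summed over fronts (amp-weighted version of gauss()).
.front_amp_sum <- function(fronts, lat, lon, t) {
  g <- rep(0, max(length(lat), length(lon), length(t)))
  if (nrow(fronts) == 0) return(g)
  for (i in seq_len(nrow(fronts))) {
    f <- fronts[i, ]
    dt <- t - f$t0
    env <- sin(pi * pmin(pmax(dt / f$life, 0), 1))
    clat <- f$lat0 + f$vlat * dt
    clon <- f$lon0 + f$vlon * dt
    d2 <- (lat - clat)^2 + (lon - clon)^2
    g <- g + f$amp * env * exp(-d2 / (2 * f$sigma^2))
  }
  g
}

#' Synthetic gridded weather product
#'
#' Samples the continuous synthetic synoptic field (background pressure
#' plus travelling Gaussian front anomalies with correlated temperature,
#' humidity and wind signatures) onto a regular 2.5-degree grid at 6-h
#' steps covering the configured bounding box, with a 30-h margin either
#' side of the deployment so 24-h change factors exist at the edges. The
#' front catalogue is attached as attribute `"fronts"` (ground truth for
#' tests).
#'
#' @param config A [sim_config()].
#' @return A [weather_grid()].
#' @export
simulate_weather_grid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  field <- .weather_field(config)
  lat <- seq(config$grid_lat[1], config$grid_lat[2], by = config$grid_res)
  lon <- seq(config$grid_lon[1], config$grid_lon[2], by = config$grid_res)
  t0 <- as.POSIXct(paste(config$start - 2, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$end + 2, "00:00:00"), tz = "UTC")
  tim <- seq(t0, t1, by = 21600)
  idx <- expand.grid(lat = lat, lon = lon, t = as.numeric(tim),
                     KEEP.OUT.ATTRS = FALSE)
  dims <- c(length(lat), length(lon), length(tim))
  g <- weather_grid(lat, lon, tim,
    mslp = array(field$mslp(idx$lat, idx$lon, idx$t), dims),
    t2m  = array(field$t2m(idx$lat, idx$lon, idx$t), dims),
    rh   = array(field$rh(idx$lat, idx$lon, idx$t), dims),
    wind = array(field$wind(idx$lat, idx$lon, idx$t), dims))
  attr(g, "fronts") <- field$fronts
  g
}

# Daily true positions: colony -> great-circle migration -> non-breeding
# site with a small bounded random walk -> return. One row per date.
.daily_positions <- function(config, dates) {
  n <- length(dates)
  lat <- rep(config$colony_lat, n); lon <- rep(config$colony_lon, n)
  mig_frac <- function(d, from, to)
    pmin(1, pmax(0, as.numeric(d - from) / as.numeric(to - from)))
  gc_path <- geosphere::gcIntermediate(
    c(config$colony_lon, config$colony_lat),
    c(config$nb_lon, config$nb_lat), n = 199, addStartEnd = TRUE)
  gc_point <- function(f) {
    p <- unname(gc_path[1 + round(pmin(pmax(f, 0), 1) * 200), ])
    c(lon = p[1], lat = p[2])
  }
  aut <- dates > config$autumn_start & dates < config$autumn_end
  spr <- dates > config$spring_start & dates < config$spring_end
  nb  <- dates >= config$autumn_end & dates <= config$spring_start
  for (i in which(aut)) {
    p <- gc_point(mig_frac(dates[i], config$autumn_start, config$autumn_end))
    lat[i] <- p["lat"] + stats::rnorm(1, 0, 0.3)
    lon[i] <- p["lon"] + stats::rnorm(1, 0, 0.3)
  }
  # bounded random walk around the residence site
  if (any(nb)) {
    wl <- wo <- 0
    for (i in which(nb)) {
      wl <- 0.8 * wl + stats::rnorm(1, 0, config$nb_jitter_sd)
      wo <- 0.8 * wo + stats::rnorm(1, 0, config$nb_jitter_sd)
      lat[i] <- config$nb_lat + wl; lon[i] <- config$nb_lon + wo
    }
  }
  for (i in which(spr)) {
    p <- gc_point(1 - mig_frac(dates[i], config$spring_start, config$spring_end))
    lat[i] <- p["lat"] + stats::rnorm(1, 0, 0.3)
    lon[i] <- p["lon"] + stats::rnorm(1, 0, 0.3)
  }
  data.frame(date = dates, lat = lat, lon = lon)
}

#' Simulate one annual cycle of tag data with ground truth
#'
#' Generates a full deployment for one individual: light follows solar
#' elevation at the true position through a logistic transfer function
#' (threshold `light_max / 2` crossed at solar elevation 0), truncated to
#' darkness when a breeding bird sits in its cavity through twilight;
#' pressure encodes the true altitude against the local synthetic sea-level
#' pressure via the inverse barometric formula; activity reflects the true
#' behaviour (flapping during migration bouts and twilight ascents, rest on
#' the colony at night, gliding otherwise). Twilight ascents are drawn per
#' event from the phase- and twilight-type-specific probabilities, with
#' heights from the configured distribution; each twilight also records its
#' truth (position, phase by the spatial rule, drawn height, ascent flag).
#'
#' Everything is deterministic given `config$seed`; `individual_id` offsets
#' the seed so a cohort shares one weather realisation but nothing else.
#'
#' @param config A [sim_config()].
#' @param individual_id,population_id Identifiers for the simulated bird.
#' @return A list with elements `series` (a [sensor_series()]) and `truth`
#'   (list: `twilights` data frame with true time/position/phase/height/
#'   flag/cavity per event, `behaviour` data frame of 5-min true labels,
#'   `track` daily true positions).
#' @export
simulate_annual_cycle <- function(config, individual_id = "SIM01",
                                  population_id = "simpop") {
  stopifnot(inherits(config, "sim_config"))
  # position-weighted id hash, widely spaced so per-bird streams cannot
  # collide across nearby master seeds
  key <- utf8ToInt(paste0(individual_id, ":", population_id))
  id_off <- sum(key * seq_along(key)) %% 190000L
  field <- .weather_field(config)   # seed-derived, shared across the cohort
  out <- .with_seed(config$seed + 10007 * id_off, {
    dates <- seq(config$start, config$end, by = "day")
    pos <- .daily_positions(config, dates)
    dnum <- as.numeric(as.POSIXct(paste(pos$date, "12:00:00"), tz = "UTC"))
    latf <- stats::approxfun(dnum, pos$lat, rule = 2)
    lonf <- stats::approxfun(dnum, pos$lon, rule = 2)

    # --- twilight truth ---------------------------------------------------
    tw <- do.call(rbind, lapply(seq_along(dates), function(i) {
      rbind(
        data.frame(date = dates[i], type = "dawn",
                   time = twilight_time(pos$lat[i], pos$lon[i], dates[i], "dawn")),
        data.frame(date = dates[i], type = "dusk",
                   time = twilight_time(pos$lat[i], pos$lon[i], dates[i], "dusk")))
    }))
    tw <- tw[!is.na(tw$time), ]
    tw <- tw[order(tw$time), ]
    tw$lat <- latf(as.numeric(tw$time)); tw$lon <- lonf(as.numeric(tw$time))
    tw$phase <- phase_of_position(tw$lat, tw$lon,
                                  colony = c(lat = config$colony_lat,
                                             lon = config$colony_lon))
    p_dawn <- config$p_dawn_ascent[tw$phase]
    odds <- p_dawn / (1 - p_dawn)
    p_ev <- ifelse(tw$type == "dawn", p_dawn,
                   (odds * config$dusk_odds) / (1 + odds * config$dusk_odds))
    p_ev[p_dawn == 1] <- 1
    tw$is_ascent <- stats::rbinom(nrow(tw), 1, p_ev) == 1
    bump <- ifelse(tw$is_ascent,
                   pmax(0, stats::rnorm(nrow(tw), config$ascent_mean,
                                        config$ascent_sd)),
                   stats::rnorm(nrow(tw),
                                config$nonascent_mean[tw$phase],
                                config$nonascent_sd))
    tw$cavity <- tw$phase == "breeding" & !tw$is_ascent &
      stats::runif(nrow(tw)) < config$cavity_p
    bump[tw$cavity] <- NA_real_   # bird sits on the colony: no flight offset
    tw$ascent_height <- bump

    # --- 5-min timeline ---------------------------------------------------
    t5 <- seq(as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC"),
              as.POSIXct(paste(config$end, "23:55:00"), tz = "UTC"),
              by = 300)
    n5 <- length(t5)
    lat5 <- latf(as.numeric(t5)); lon5 <- lonf(as.numeric(t5))
    # phase of each 5-min step: phase of the twilight event whose 12-h
    # neighbourhood it falls in
    near_tw <- pmax(1, pmin(nrow(tw),
      findInterval(as.numeric(t5), as.numeric(tw$time) - 21600)))
    phase5 <- tw$phase[near_tw]

    # colony ground intervals (breeding nights), cavity timing
    elev_colony <- solar_elevation(config$colony_lat, config$colony_lon, t5)
    ground <- logical(n5)
    cavity_dark <- logical(n5)
    breeding_tw <- which(tw$phase == "breeding")
    for (i in breeding_tw) {
      ti <- as.numeric(tw$time[i])
      if (tw$type[i] == "dusk") {
        enter <- if (tw$cavity[i]) ti - stats::runif(1, 20, 70) * 60
                 else ti + 45 * 60
        leave <- ti + 12 * 3600   # provisional; trimmed by next dawn below
        idx <- as.numeric(t5) >= enter & as.numeric(t5) <= leave &
          elev_colony < 10
        ground[idx] <- TRUE
        if (tw$cavity[i]) cavity_dark[as.numeric(t5) >= enter &
                                      as.numeric(t5) <= ti + 3 * 3600] <- TRUE
      } else {
        leave <- if (tw$cavity[i]) ti + stats::runif(1, 20, 70) * 60
                 else ti - 45 * 60
        idx <- as.numeric(t5) <= leave & as.numeric(t5) >= ti - 12 * 3600 &
          elev_colony < 10
        ground[idx] <- TRUE
        if (tw$cavity[i]) cavity_dark[as.numeric(t5) <= leave &
                                      as.numeric(t5) >= ti - 3 * 3600] <- TRUE
      }
    }
    ground <- ground & phase5 == "breeding"
    cavity_dark <- cavity_dark & phase5 == "breeding"

    # migration travel legs: multi-day continuous flapping flight at
    # cruising altitude, alternating with gliding rest days (two-state
    # Markov chain over days; travel runs last several days, as in
    # sustained migratory legs)
    bout <- logical(n5)
    mig_day <- dates > config$autumn_start & dates < config$autumn_end |
               dates > config$spring_start & dates < config$spring_end
    travel <- logical(length(dates))
    state <- TRUE
    for (i in which(mig_day)) {
      state <- if (state) stats::runif(1) < 0.8 else stats::runif(1) < 0.5
      travel[i] <- state
    }
    if (any(travel)) {
      dayidx <- findInterval(as.numeric(t5),
        as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")))
      bout <- travel[dayidx]
    }
    bout <- bout & phase5 == "migration"

    # altitude (m ASL): within-day wander plus a day-to-day cruising
    # offset (birds pick different altitude bands on different days)
    wander <- as.numeric(stats::filter(
      stats::rnorm(n5, 0, max(config$alt_wander_sd, 1e-12)), 0.95,
      method = "recursive"))
    if (config$alt_wander_sd == 0) wander <- numeric(n5)
    day_off <- as.numeric(stats::filter(
      stats::rnorm(length(dates), 0, max(config$day_alt_sd, 1e-12)), 0.5,
      method = "recursive"))
    if (config$day_alt_sd == 0) day_off <- numeric(length(dates))
    wander <- wander + day_off[findInterval(as.numeric(t5),
      as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")))]
    elev5 <- solar_elevation(lat5, lon5, t5)
    alt <- rep(config$cruise_alt[["breeding_day"]], n5)
    alt[phase5 == "migration"] <- config$cruise_alt[["migration_glide"]]
    alt[bout] <- config$cruise_alt[["migration_bout"]]
    nbm <- phase5 == "nonbreeding"
    alt[nbm] <- config$cruise_alt[["nonbreeding"]] +
      config$nb_diurnal_amp * stats::plogis(elev5[nbm] / 5)
    alt <- alt + wander
    # twilight altitude offsets (rectangular, +-30 min, inclusive)
    asc_flap <- logical(n5)
    air_tw <- logical(n5)   # airborne through the twilight (bump applies)
    for (i in seq_len(nrow(tw))) {
      if (is.na(tw$ascent_height[i])) next
      idx <- abs(as.numeric(t5) - as.numeric(tw$time[i])) <= 1800
      if (tw$phase[i] == "breeding") alt[idx] <- config$colony_elev + 200 +
          wander[idx]  # airborne around a non-cavity breeding twilight
      alt[idx] <- alt[idx] + tw$ascent_height[i]
      air_tw[idx] <- TRUE
      if (tw$is_ascent[i]) asc_flap[idx] <- TRUE
    }
    ground <- ground & !air_tw
    alt[ground] <- config$colony_elev

    # behaviour truth + activity
    label <- rep("gliding", n5)
    label[bout | asc_flap] <- "flapping"
    label[ground] <- "resting"
    a <- config$activity
    act <- numeric(n5)
    act[label == "flapping"] <- pmax(0, stats::rnorm(sum(label == "flapping"),
      a[["flap_mean"]], a[["flap_sd"]]))
    act[label == "gliding"] <- pmax(0, stats::rnorm(sum(label == "gliding"),
      a[["glide_mean"]], a[["glide_sd"]]))
    act[label == "resting"] <- pmax(0, stats::rnorm(sum(label == "resting"),
      a[["rest_mean"]], a[["rest_sd"]]))

    # light
    light <- config$light_max * stats::plogis(elev5 / config$light_k)
    if (config$light_noise_sd > 0)
      light <- light + stats::rnorm(n5, 0, config$light_noise_sd)
    light <- pmin(config$light_max, pmax(0, light))
    light[cavity_dark] <- 0

    # pressure + temperature at 30-min subset
    i30 <- seq(1, n5, by = 6)
    t30 <- t5[i30]
    p0 <- field$mslp(lat5[i30], lon5[i30], as.numeric(t30))
    pres <- altitude_to_pressure(alt[i30], p0)
    if (config$pressure_noise_sd > 0)
      pres <- pres + stats::rnorm(length(i30), 0, config$pressure_noise_sd)
    temp <- field$t2m(lat5[i30], lon5[i30], as.numeric(t30)) - 273.15 -
      0.0065 * alt[i30] + stats::rnorm(length(i30), 0, 0.3)

    series <- sensor_series(individual_id, population_id,
      light = data.frame(time = t5, value = light),
      activity = data.frame(time = t5, value = act),
      pressure = data.frame(time = t30, value = pres),
      temperature = data.frame(time = t30, value = temp))
    truth <- list(
      twilights = data.frame(time = tw$time, date = tw$date, type = tw$type,
                             lat = tw$lat, lon = tw$lon, phase = tw$phase,
                             ascent_height = tw$ascent_height,
                             is_ascent = tw$is_ascent, cavity = tw$cavity),
      behaviour = data.frame(time = t5, label = label, altitude = alt),
      track = pos)
    list(series = series, truth = truth)
  })
  out
}

#' Simulate a cohort of individuals
#'
#' Convenience wrapper: `n_per_pop` birds in each named population share the
#' configured colony and weather realisation but have independent draws.
#'
#' @param config A [sim_config()].
#' @param populations Character vector of population names.
#' @param n_per_pop Birds per population.
#' @return List of `simulate_annual_cycle()` results, named by individual.
#' @export
simulate_cohort <- function(config, populations = c("popA", "popB"),
                            n_per_pop = 5) {
  out <- list()
  for (p in populations)
    for (i in seq_len(n_per_pop)) {
      id <- sprintf("%s%02d", toupper(substr(p, nchar(p), nchar(p))), i)
      out[[paste0(p, "_", id)]] <-
        simulate_annual_cycle(config, individual_id = id, population_id = p)
    }
  out
}
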