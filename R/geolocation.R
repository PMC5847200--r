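#' Detect twilight events from the light channel (threshold method)
#'
#' Finds, per civil day (UTC), the dawn and dusk threshold crossings of the
#' light series. Crossing times are linearly interpolated between the two
#' bracketing 5-min samples; a sample lying exactly on the threshold starts
#' the crossing interval (tie rule). Within a day the main daylight block is
#' the longest above-threshold run, so the dawn reported is the last upward
#' crossing of the morning (spurious pre-dawn light spikes open and close
#' shorter blocks) and the dusk is the first downward crossing of the
#' evening.
#'
#' @param light Data frame with columns `time` (POSIXct UTC), `value`.
#' @param threshold Light threshold, sensor units.
#' @return Data frame of events: `time`, `type` (`dawn`/`dusk`), `natural`
#'   (all `NA` until [flag_unnatural()] runs). Days without a usable pair
#'   are absent. Constant or never-crossing light gives zero rows with a
#'   warning.
#' @export
detect_twilights <- function(light, threshold) {
  stopifnot(all(c("time", "value") %in% names(light)))
  v <- light$value; tt <- as.numeric(light$time)
  ok <- !is.na(v)
  v <- v[ok]; tt <- tt[ok]
  if (length(v) < 288)
    stop("need at least one day of light data", call. = FALSE)
  n <- length(v)
  rising  <- which(v[-n] <= threshold & v[-1] > threshold)
  falling <- which(v[-n] >= threshold & v[-1] < threshold)
  if (length(rising) == 0 && length(falling) == 0) {
    warning("light never crosses the threshold: no twilight events")
    return(data.frame(time = .POSIXct(numeric(0), tz = "UTC"),
                      type = character(0), natural = logical(0)))
  }
  cross_time <- function(i) {
    if (v[i + 1] == v[i]) return(tt[i])
    tt[i] + (tt[i + 1] - tt[i]) * (threshold - v[i]) / (v[i + 1] - v[i])
  }
  # above-threshold blocks: rising crossing paired with the next falling one
  ev <- rbind(
    if (length(rising)) data.frame(i = rising, dir = 1L),
    if (length(falling)) data.frame(i = falling, dir = -1L))
  ev <- ev[order(ev$i), ]
  out <- list()
  k <- 1
  while (k <= nrow(ev)) {
    if (ev$dir[k] == 1L) {
      j <- k + 1
      while (j <= nrow(ev) && ev$dir[j] != -1L) j <- j + 1
      if (j <= nrow(ev)) {
        out[[length(out) + 1]] <- c(start = cross_time(ev$i[k]),
                                    end = cross_time(ev$i[j]),
                                    len = tt[ev$i[j]] - tt[ev$i[k]])
        k <- j + 1
      } else break
    } else k <- k + 1
  }
  if (length(out) == 0) {
    warning("no complete daylight block found")
    return(data.frame(time = .POSIXct(numeric(0), tz = "UTC"),
                      type = character(0), natural = logical(0)))
  }
  blocks <- as.data.frame(do.call(rbind, out))
  blocks$date <- as.Date(.POSIXct(0.5 * (blocks$start + blocks$end),
                                  tz = "UTC"))
  # main block per civil day = the longest
  main <- do.call(rbind, lapply(split(blocks, blocks$date), function(b)
    b[which.max(b$len), ]))
  res <- rbind(
    data.frame(time = main$start, type = "dawn"),
    data.frame(time = main$end, type = "dusk"))
  res <- res[order(res$time), ]
  data.frame(time = .POSIXct(res$time, tz = "UTC"), type = res$type,
             natural = NA, row.names = NULL)
}

#' Flag unnatural sun events
#'
#' An event is unnatural when the light level jumps abruptly near it —
#' typically a bird entering or leaving a dark cavity rather than the sun
#' moving. Quantitatively: any single inter-sample light change within
#' `window` of the event that reaches `fraction` of the sensor's dynamic
#' range (boundary inclusive) marks the event unnatural.
#'
#' @param light Data frame `time`/`value` (5-min cadence).
#' @param events Output of [detect_twilights()].
#' @param fraction Fraction of the dynamic range (default 0.8).
#' @param window Half-width of the inspection window, seconds (default
#'   30 min).
#' @param dynamic_range Sensor range; defaults to the observed
#'   `max - min` of the channel.
#' @return `events` with the `natural` column filled in.
#' @export
flag_unnatural <- function(light, events, fraction = 0.8, window = 1800,
                           dynamic_range = NULL) {
  if (nrow(events) == 0) return(events)
  if (is.null(dynamic_range))
    dynamic_range <- diff(range(light$value, na.rm = TRUE))
  tt <- as.numeric(light$time)
  step <- abs(diff(light$value))
  step_mid <- (tt[-1] + tt[-length(tt)]) / 2
  events$natural <- vapply(as.numeric(events$time), function(et) {
    s <- step[abs(step_mid - et) <= window + 150]
    !any(s >= fraction * dynamic_range, na.rm = TRUE)
  }, logical(1))
  events
}

# ---------------------------------------------------------------------------
# Grid hidden Markov model

#' Forward-backward smoothing on a discrete state grid
#'
#' Generic forward-backward pass: `liks` is a list of per-event likelihood
#' vectors over the states, `transition` either a (symmetric) transition
#' matrix or a function applying it to a probability vector. Returns the
#' smoothed posterior for every event, each summing to one.
#'
#' @param liks List of numeric vectors (equal length).
#' @param transition Matrix `P` (rows: from, columns: to; may be
#'   asymmetric), or a symmetric linear operator given as a function
#'   `v -> v` (e.g. a separable Gaussian blur).
#' @param prior Initial state distribution (default uniform).
#' @return List of posterior vectors.
#' @export
hmm_smooth <- function(liks, transition, prior = NULL) {
  n <- length(liks)
  stopifnot(n >= 1)
  m <- length(liks[[1]])
  if (is.function(transition)) {
    fwd <- transition; bwd <- transition   # symmetric operator
  } else {
    fwd <- function(v) as.numeric(v %*% transition)
    bwd <- function(v) as.numeric(transition %*% v)
  }
  if (is.null(prior)) prior <- rep(1 / m, m)
  norm <- function(v) {
    s <- sum(v)
    if (s <= 0 || !is.finite(s)) rep(1 / length(v), length(v)) else v / s
  }
  alpha <- vector("list", n); beta <- vector("list", n)
  alpha[[1]] <- norm(prior * liks[[1]])
  if (n > 1) for (k in 2:n) alpha[[k]] <- norm(fwd(alpha[[k - 1]]) * liks[[k]])
  beta[[n]] <- rep(1, m)
  if (n > 1) for (k in (n - 1):1)
    beta[[k]] <- norm(bwd(beta[[k + 1]] * liks[[k + 1]]))
  lapply(seq_len(n), function(k) norm(alpha[[k]] * beta[[k]]))
}

# Regular lat/lon grid spec used by the positional posterior.
.make_grid <- function(lat_range, lon_range, res) {
  lat <- seq(lat_range[1] + res / 2, lat_range[2], by = res)
  lon <- seq(lon_range[1] + res / 2, lon_range[2], by = res)
  list(lat = lat, lon = lon, res = res, nlat = length(lat),
       nlon = length(lon))
}

# 1-D Gaussian random-walk kernel. Kept symmetric (no row normalisation)
# so the same operator serves the forward and backward passes; the
# per-step renormalisation in hmm_smooth absorbs the truncated tail mass
# at the grid edges.
.rw_kernel <- function(coords, sd) {
  outer(coords, coords, function(a, b) stats::dnorm(a - b, 0, sd))
}

#' Positional posterior for each twilight event
#'
#' A simplified grid hidden Markov model in the tradition of template-fit
#' geolocation: for each natural twilight, the likelihood of a grid cell is
#' how well the observed crossing time matches that cell's predicted
#' twilight — measured as the solar-elevation residual at the observed time
#' converted to minutes via the local elevation rate — under a Gaussian
#' twilight-error model. Between events a Gaussian random walk (separable in
#' latitude and longitude) models movement, and forward-backward smoothing
#' yields a normalised probability map per event, the contract downstream
#' bootstrapping relies on. Unnatural events carry no light information and
#' get no posterior (positions for them are later interpolated).
#'
#' @param events Data frame from [flag_unnatural()] (columns `time`, `type`,
#'   `natural`).
#' @param grid_lat,grid_lon Grid bounds, degrees.
#' @param grid_res Cell size, degrees (default 1).
#' @param movement_sd Random-walk standard deviation between consecutive
#'   twilights, degrees (default 1).
#' @param twilight_sd Twilight-time error standard deviation, minutes
#'   (default 8).
#' @param sun_elev Solar elevation defining the twilight (degrees; 0 when
#'   the light threshold is calibrated to sunrise/sunset).
#' @return Object of class `position_posterior`: list with `grid`, `events`
#'   (the natural events), and `post`, a matrix `[event, cell]` of
#'   probabilities (cells in lat-major order), each row summing to 1.
#' @export
estimate_positions <- function(events, grid_lat = c(-12.5, 60),
                               grid_lon = c(-20, 42.5), grid_res = 1,
                               movement_sd = 1, twilight_sd = 8,
                               sun_elev = 0) {
  nat <- events[!is.na(events$natural) & events$natural, ]
  if (nrow(nat) < 2)
    stop("need at least 2 natural events to estimate positions",
         call. = FALSE)
  g <- .make_grid(grid_lat, grid_lon, grid_res)
  cell_lat <- rep(g$lat, times = g$nlon)
  cell_lon <- rep(g$lon, each = g$nlat)
  liks <- lapply(seq_len(nrow(nat)), function(k) {
    t0 <- nat$time[k]
    e0 <- solar_elevation(cell_lat, cell_lon, t0)
    raw_rate <- (solar_elevation(cell_lat, cell_lon, t0 + 300) -
                 solar_elevation(cell_lat, cell_lon, t0 - 300)) / 10  # deg/min
    rate <- pmax(abs(raw_rate), 0.02)
    resid_min <- (e0 - sun_elev) / rate
    lik <- stats::dnorm(resid_min, 0, twilight_sd)
    # a dawn must be a rising sun, a dusk a setting one
    dirok <- if (nat$type[k] == "dawn") raw_rate > 0 else raw_rate < 0
    lik * ifelse(dirok, 1, 1e-6) + 1e-12
  })
  Klat <- .rw_kernel(g$lat, movement_sd)
  Klon <- .rw_kernel(g$lon, movement_sd)
  blur <- function(v) as.numeric(Klat %*% matrix(v, g$nlat, g$nlon) %*% t(Klon))
  post <- hmm_smooth(liks, blur)
  structure(list(grid = g, events = nat,
                 post = do.call(rbind, post)),
            class = "position_posterior")
}

#' @export
print.position_posterior <- function(x, ...) {
  cat(sprintf("<position_posterior> %d events on a %d x %d grid (%g deg)\n",
              nrow(x$post), x$grid$nlat, x$grid$nlon, x$grid$res))
  invisible(x)
}

# cell index -> lat/lon (lat-major order)
.cell_coords <- function(grid, idx) {
  list(lat = grid$lat[(idx - 1) %% grid$nlat + 1],
       lon = grid$lon[(idx - 1) %/% grid$nlat + 1])
}

#' Median track from positional posteriors
#'
#' Per-event marginal median latitude and longitude — the point estimate
#' weather annotation and sea-level-pressure lookup use.
#'
#' @param posterior A `position_posterior`.
#' @return Data frame `time`, `type`, `lat`, `lon`, `provenance = "median"`.
#' @export
median_track <- function(posterior) {
  g <- posterior$grid
  P <- posterior$post
  lat_idx <- rep(seq_len(g$nlat), times = g$nlon)
  lon_idx <- rep(seq_len(g$nlon), each = g$nlat)
  wmed <- function(vals, w) {
    o <- order(vals); cw <- cumsum(w[o])
    vals[o][which(cw >= 0.5 * sum(w))[1]]
  }
  lat <- apply(P, 1, function(w) wmed(g$lat[lat_idx], w))
  lon <- apply(P, 1, function(w) wmed(g$lon[lon_idx], w))
  data.frame(time = posterior$events$time, type = posterior$events$type,
             lat = lat, lon = lon, provenance = "median",
             stringsAsFactors = FALSE)
}

#' Bootstrap tracks from positional posteriors
#'
#' Draws `n` tracks; each track picks one grid cell per event independently
#' according to that event's probability mass — the resampling scheme the
#' ensemble regression uses to propagate positional uncertainty.
#'
#' @param posterior A `position_posterior`.
#' @param n Number of tracks (default 10000).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Integer matrix `[event, track]` of cell indices, with the
#'   posterior's grid attached as attribute `"grid"` and event times as
#'   `"events"`. Use [track_positions()] to materialise coordinates.
#' @export
sample_tracks <- function(posterior, n = 10000, seed = 1) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  P <- posterior$post
  idx <- matrix(0L, nrow(P), n)
  .with_seed(seed, {
    for (k in seq_len(nrow(P)))
      idx[k, ] <- sample.int(ncol(P), n, replace = TRUE, prob = P[k, ])
  })
  attr(idx, "grid") <- posterior$grid
  attr(idx, "events") <- posterior$events
  idx
}

#' Coordinates of one sampled track
#'
#' @param tracks Result of [sample_tracks()].
#' @param j Track number.
#' @return Data frame `time`, `type`, `lat`, `lon`, `provenance = "sampled"`.
#' @export
track_positions <- function(tracks, j) {
  g <- attr(tracks, "grid"); ev <- attr(tracks, "events")
  cc <- .cell_coords(g, tracks[, j])
  data.frame(time = ev$time, type = ev$type, lat = cc$lat, lon = cc$lon,
             provenance = "sampled", stringsAsFactors = FALSE)
}

#' Interpolate a track position at an arbitrary time
#'
#' Linear interpolation in latitude and longitude between the bracketing
#' twilight positions. Times before the first (after the last) event are
#' pinned to the colony when it is supplied — birds are assumed to reside
#' at the breeding colony between tag mounting and the first natural sun
#' event, and again after the last one.
#'
#' @param track Data frame `time`, `lat`, `lon` (ordered).
#' @param timestamp POSIXct time(s) to interpolate at.
#' @param colony Optional `c(lat = , lon = )` for the pinned edge windows.
#' @return Data frame `time`, `lat`, `lon`.
#' @export
interpolate_position <- function(track, timestamp, colony = NULL) {
  tt <- as.numeric(track$time); qt <- as.numeric(timestamp)
  inside <- qt >= tt[1] & qt <= tt[length(tt)]
  if (any(!inside) && is.null(colony))
    stop("timestamp outside track span and no colony to pin to",
         call. = FALSE)
  lat <- stats::approx(tt, track$lat, xout = qt, rule = 2)$y
  lon <- stats::approx(tt, track$lon, xout = qt, rule = 2)$y
  if (!is.null(colony)) {
    lat[!inside] <- colony[["lat"]]
    lon[!inside] <- colony[["lon"]]
  }
  data.frame(time = timestamp, lat = lat, lon = lon)
}
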