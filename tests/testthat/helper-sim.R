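# Shared small simulation fixtures, built once per test run.

# ~70-day deployment, mostly non-breeding residence: colony tail, a short
# autumn passage, then a stationary tropical residence.
tiny_cfg <- function(seed = 11, ...) {
  sim_config(start = "2014-10-01", end = "2014-12-09",
             autumn_start = "2014-10-03", autumn_end = "2014-10-18",
             spring_start = "2014-12-05", spring_end = "2014-12-07",
             seed = seed, ...)
}

# fully stationary tropical bird (non-breeding from day 3), noise-free
stationary_cfg <- function(seed = 5, ...) {
  sim_config(start = "2014-11-01", end = "2014-12-31",
             autumn_start = "2014-11-02", autumn_end = "2014-11-03",
             spring_start = "2014-12-29", spring_end = "2014-12-30",
             light_noise_sd = 0, pressure_noise_sd = 0, front_amp = 0,
             nb_jitter_sd = 0, cavity_p = 0,
             seed = seed, ...)
}

local_bird <- local({
  cache <- new.env()
  function(cfg_fun = tiny_cfg, key = "tiny", ...) {
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_annual_cycle(cfg_fun(...))
    cache[[key]]
  }
})

# quick synthetic position_posterior over a hand-made grid
fake_posterior <- function(post, lat = c(9.5, 10.5), lon = c(-11.5, -10.5),
                           times = NULL, types = NULL) {
  g <- list(lat = lat, lon = lon, res = diff(lat[1:2]),
            nlat = length(lat), nlon = length(lon))
  n <- nrow(post)
  if (is.null(times))
    times <- as.POSIXct("2014-11-01 06:00:00", tz = "UTC") + 43200 * (seq_len(n) - 1)
  if (is.null(types)) types <- rep(c("dawn", "dusk"), length.out = n)
  structure(list(grid = g,
                 events = data.frame(time = times, type = types,
                                     natural = TRUE),
                 post = post),
            class = "position_posterior")
}
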