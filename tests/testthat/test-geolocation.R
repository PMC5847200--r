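test_that("threshold crossings recover simulated twilights", {
  b <- local_bird(stationary_cfg, "stationary")
  cfg <- stationary_cfg()
  ev <- detect_twilights(b$series$light, cfg$light_threshold)
  expect_true(all(ev$type %in% c("dawn", "dusk")))
  tw <- b$truth$twilights
  m <- merge(data.frame(date = as.Date(ev$time), type = ev$type,
                        det = as.numeric(ev$time)),
             data.frame(date = tw$date, type = tw$type, phase = tw$phase,
                        tru = as.numeric(tw$time)))
  # judge against stationary days; on the (here one-day) passage the
  # daily-knot truth position lags the continuous one by design
  m <- m[m$phase == "nonbreeding", ]
  expect_gt(nrow(m), 100)
  expect_lt(max(abs(m$det - m$tru)), 5 * 60)
})

test_that("light that never crosses the threshold yields no events", {
  t5 <- seq(as.POSIXct("2014-07-01", tz = "UTC"), by = 300,
            length.out = 2 * 288)
  dark <- data.frame(time = t5, value = rep(1, length(t5)))
  expect_warning(ev <- detect_twilights(dark, 32), "never crosses")
  expect_equal(nrow(ev), 0)
  expect_error(detect_twilights(dark[1:100, ], 32), "one day")
})

test_that("a sample exactly on the threshold starts the crossing interval", {
  t5 <- seq(as.POSIXct("2014-07-01", tz = "UTC"), by = 300,
            length.out = 288 + 144)
  v <- rep(0, length(t5))
  # morning rise passes exactly through the threshold at sample 73 (06:00),
  # evening falls below it between samples
  v[73] <- 32; v[74:216] <- 64
  v[217] <- 10
  v[(288 + 73):(288 + 144)] <- 64
  light <- data.frame(time = t5, value = v)
  ev <- detect_twilights(light, 32)
  dawn1 <- ev$time[ev$type == "dawn"][1]
  expect_equal(as.numeric(dawn1), as.numeric(t5[73]))
})

test_that("abrupt cavity-style light steps mark events unnatural", {
  b <- local_bird(stationary_cfg, "stationary")
  cfg <- stationary_cfg()
  ev <- detect_twilights(b$series$light, cfg$light_threshold)
  ev <- flag_unnatural(b$series$light, ev, dynamic_range = cfg$light_max)
  # a smooth sigmoidal twilight at a stationary tropical site is natural
  expect_true(all(ev$natural))
  # a breeding bird that sits in the cavity through every twilight is not
  ccfg <- sim_config(start = "2014-07-20", end = "2014-08-30",
                     autumn_start = "2014-08-24", autumn_end = "2014-08-26",
                     spring_start = "2014-08-27", spring_end = "2014-08-28",
                     cavity_p = 1,
                     p_dawn_ascent = c(breeding = 0, migration = 0,
                                       nonbreeding = 0),
                     light_noise_sd = 0, seed = 8)
  cb <- simulate_annual_cycle(ccfg)
  cev <- detect_twilights(cb$series$light, ccfg$light_threshold)
  cev <- flag_unnatural(cb$series$light, cev, dynamic_range = ccfg$light_max)
  expect_gt(mean(!cev$natural), 0.9)
})

test_that("the unnatural-step boundary is inclusive", {
  t5 <- seq(as.POSIXct("2014-07-01", tz = "UTC"), by = 300,
            length.out = 2 * 288)
  # smooth day square wave plus one step of exactly 0.8 * range near dawn
  v <- rep(0, length(t5))
  v[74:216] <- 64; v[73] <- 12.8
  v[288 + (74:216)] <- 64
  light <- data.frame(time = t5, value = v)
  ev <- detect_twilights(light, 32)
  ev <- flag_unnatural(light, ev, fraction = 0.8, dynamic_range = 64)
  expect_false(ev$natural[1])   # 12.8 -> 64 is a step of 0.8 * 64
})

test_that("forward-backward posterior equals brute-force path enumeration", {
  set.seed(42)
  for (i in 1:5) {
    liks <- lapply(1:3, function(k) runif(4, 0.01, 1))
    K <- matrix(runif(16, 0.1, 1), 4)
    K <- (K + t(K)) / 2          # symmetric transition
    K <- K / rowSums(K)
    smooth <- hmm_smooth(liks, K)
    brute <- hmm_brute_force(liks, K)
    for (k in 1:3)
      expect_lt(max(abs(smooth[[k]] - brute[[k]])), 1e-9)
  }
})

test_that("flat likelihoods leave the smoothed prior unchanged", {
  liks <- lapply(1:4, function(k) rep(1, 9))
  K <- matrix(1 / 9, 9, 9)
  out <- hmm_smooth(liks, K)
  for (p in out) expect_equal(p, rep(1 / 9, 9), tolerance = 1e-12)
})

test_that("a stationary bird is located within a grid cell or two", {
  b <- local_bird(stationary_cfg, "stationary")
  cfg <- stationary_cfg()
  ev <- detect_twilights(b$series$light, cfg$light_threshold)
  ev <- flag_unnatural(b$series$light, ev, dynamic_range = cfg$light_max)
  post <- estimate_positions(ev, grid_lat = c(0, 25), grid_lon = c(-20, 5))
  expect_true(all(abs(rowSums(post$post) - 1) < 1e-9))
  med <- median_track(post)
  # residence site sits at (10.5 N, -11 E)
  expect_lt(median(abs(med$lat - 10.5)), 1.5)
  expect_lt(median(abs(med$lon + 11)), 1)
  # fewer than 2 natural events is a position failure
  expect_error(estimate_positions(ev[1, ]), "at least 2")
})

test_that("latitude is the weak coordinate around the equinox", {
  ecfg <- sim_config(start = "2014-09-13", end = "2014-10-02",
                     autumn_start = "2014-09-28", autumn_end = "2014-09-29",
                     spring_start = "2014-09-30", spring_end = "2014-10-01",
                     light_noise_sd = 0.5, nb_jitter_sd = 0, cavity_p = 0,
                     seed = 21)
  eb <- simulate_annual_cycle(ecfg)
  ev <- detect_twilights(eb$series$light, ecfg$light_threshold)
  ev <- flag_unnatural(eb$series$light, ev, dynamic_range = ecfg$light_max)
  post <- estimate_positions(ev, grid_lat = c(30, 60), grid_lon = c(-5, 20))
  g <- post$grid
  lat_c <- rep(g$lat, times = g$nlon); lon_c <- rep(g$lon, each = g$nlat)
  sds <- t(vapply(seq_len(nrow(post$post)), function(k) {
    w <- post$post[k, ]
    c(lat = sqrt(sum(w * (lat_c - sum(w * lat_c))^2)),
      lon = sqrt(sum(w * (lon_c - sum(w * lon_c))^2)))
  }, c(lat = 0, lon = 0)))
  expect_gt(median(sds[, "lat"]), median(sds[, "lon"]))
})

test_that("track sampling follows the posterior mass", {
  P <- matrix(c(0.6, 0, 0.4, 0,
                1, 0, 0, 0,
                0.25, 0.25, 0.25, 0.25), 3, 4, byrow = TRUE)
  post <- fake_posterior(P)
  tr <- sample_tracks(post, 10000, seed = 9)
  f1 <- mean(tr[1, ] == 1)
  expect_lt(abs(f1 - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))
  expect_true(all(tr[2, ] == 1))                       # degenerate posterior
  expect_identical(tr, sample_tracks(post, 10000, seed = 9))
  expect_false(identical(tr[3, ], sample_tracks(post, 10000, seed = 10)[3, ]))
  expect_error(sample_tracks(post, 0), "positive")
  tp <- track_positions(tr, 1)
  expect_equal(nrow(tp), 3)
  expect_true(all(tp$lat %in% post$grid$lat))
})

test_that("position interpolation is linear with colony-pinned edges", {
  tt <- as.POSIXct(c("2014-09-01 06:00", "2014-09-03 06:00"), tz = "UTC")
  track <- data.frame(time = tt, lat = c(0, 2), lon = c(0, 2))
  mid <- interpolate_position(track, tt[1] + 86400)
  expect_equal(c(mid$lat, mid$lon), c(1, 1))
  at <- interpolate_position(track, tt[2])
  expect_equal(c(at$lat, at$lon), c(2, 2))
  colony <- c(lat = 47.47, lon = 8.31)
  before <- interpolate_position(track, tt[1] - 86400, colony = colony)
  expect_equal(c(before$lat, before$lon), unname(colony))
  expect_error(interpolate_position(track, tt[1] - 86400), "colony")
})
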