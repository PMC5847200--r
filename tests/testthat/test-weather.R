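mini_grid <- function(nt = 12, lat = seq(0, 10, 2.5), lon = seq(0, 5, 2.5),
                      fill = 1000) {
  tim <- as.POSIXct("2014-11-01", tz = "UTC") + 21600 * (seq_len(nt) - 1)
  dims <- c(length(lat), length(lon), nt)
  weather_grid(lat, lon, tim,
               mslp = array(fill, dims), t2m = array(290, dims),
               rh = array(60, dims), wind = array(5, dims))
}

test_that("grid constructor enforces regular space-time structure", {
  g <- mini_grid()
  expect_s3_class(g, "weather_grid")
  tim <- g$time; tim[3] <- tim[3] + 60
  expect_error(weather_grid(g$lat, g$lon, tim, g$vars$mslp, g$vars$t2m,
                            g$vars$rh, g$vars$wind), "6 h")
})

test_that("a constant grid gives zero 24-h change factors", {
  g <- mini_grid(nt = 16)
  track <- data.frame(time = g$time[6] + c(3600, 7200), lat = c(2.5, 5),
                      lon = c(2.5, 2.5))
  w <- annotate_weather(track, g)
  expect_equal(w$mslp, c(1000, 1000))
  expect_equal(w$dmslp_before, c(0, 0))
  expect_equal(w$dtemp_after, c(0, 0))
  expect_equal(w$drh_before, c(0, 0))
  expect_true(all(w$in_domain))
})

test_that("an event on a window boundary reads the window starting there", {
  g <- mini_grid(nt = 12)
  g$vars$mslp[, , 6] <- 990   # window 6 differs from window 5
  ev <- data.frame(time = g$time[6], lat = 2.5, lon = 0)
  expect_equal(annotate_weather(ev, g)$mslp, 990)
})

test_that("positions or times off the grid are flagged out of domain", {
  g <- mini_grid(nt = 12)
  track <- data.frame(time = c(g$time[2], g$time[2], g$time[1] - 6e5),
                      lat = c(2.5, 60, 2.5), lon = c(2.5, 2.5, 2.5))
  w <- annotate_weather(track, g)
  expect_equal(w$in_domain, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(w$mslp[2:3])))
})

test_that("change factors are magnitudes; signed copies kept alongside", {
  g <- mini_grid(nt = 16)
  g$vars$mslp[, , ] <- rep(seq(1000, 985, length.out = 16),
                           each = 5 * 3)      # steadily falling pressure
  ev <- data.frame(time = g$time[8] + 3600, lat = 2.5, lon = 2.5)
  w <- annotate_weather(ev, g)
  expect_lt(w$dmslp_before_signed, 0)
  expect_equal(w$dmslp_before, abs(w$dmslp_before_signed))
  expect_gte(w$drh_after, 0)
})

test_that("a travelling front peaks the 24-h pressure change near its passage", {
  cfg <- sim_config(seed = 99, front_freq = 2)
  g <- simulate_weather_grid(cfg)
  fr <- attr(g, "fronts")
  expect_gt(nrow(fr), 0)
  f <- fr[which.max(fr$amp), ]
  t_mid <- f$t0 + f$life / 2
  c_lat <- f$lat0 + f$vlat * (t_mid - f$t0)
  c_lon <- f$lon0 + f$vlon * (t_mid - f$t0)
  # stay inside the grid
  c_lat <- min(max(c_lat, min(g$lat)), max(g$lat))
  c_lon <- min(max(c_lon, min(g$lon)), max(g$lon))
  tt <- g$time[g$time >= t_mid - 10 * 86400 & t_mid + 10 * 86400 >= g$time]
  w <- annotate_weather(data.frame(time = tt, lat = c_lat, lon = c_lon), g)
  peak_t <- as.numeric(tt[which.max(w$dmslp_before + w$dmslp_after)])
  expect_lt(abs(peak_t - t_mid), 2.5 * 86400)
  expect_gt(max(w$dmslp_before, na.rm = TRUE), 2)
})

test_that("annotation is deterministic", {
  cfg <- sim_config(seed = 31)
  g <- simulate_weather_grid(cfg)
  track <- data.frame(time = g$time[c(20, 40, 60)] + 1234,
                      lat = c(47, 30, 11), lon = c(8, 0, -10))
  expect_identical(annotate_weather(track, g), annotate_weather(track, g))
})

test_that("z-transform centres and scales with the n-1 convention", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(50, 7, 3)
  z <- z_transform(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(z_transform(rep(4, 10)), class = "degenerate_factor")
  expect_error(z_transform(3), "at least 2")
})

test_that("weather CSV round-trips the grid", {
  g <- mini_grid(nt = 4)
  g$vars$mslp[2, 1, 3] <- 987.5
  f <- tempfile(fileext = ".csv")
  write_weather_csv(g, f)
  h <- read_weather_csv(f)
  expect_equal(h$lat, g$lat)
  expect_equal(h$time, g$time)
  for (v in names(g$vars)) expect_equal(h$vars[[v]], g$vars[[v]])
})
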