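test_that("simulation is deterministic given the seed", {
  a <- simulate_annual_cycle(tiny_cfg(seed = 3))
  b <- simulate_annual_cycle(tiny_cfg(seed = 3))
  c <- simulate_annual_cycle(tiny_cfg(seed = 4))
  expect_identical(a$series$light$value, b$series$light$value)
  expect_identical(a$series$pressure$value, b$series$pressure$value)
  expect_identical(a$truth$twilights$ascent_height,
                   b$truth$twilights$ascent_height)
  expect_false(identical(a$series$light$value, c$series$light$value))
})

test_that("zero ascent probabilities produce zero true ascents", {
  cfg <- tiny_cfg(seed = 9,
                  p_dawn_ascent = c(breeding = 0, migration = 0,
                                    nonbreeding = 0))
  s <- simulate_annual_cycle(cfg)
  expect_false(any(s$truth$twilights$is_ascent))
})

test_that("a degenerate height distribution is reproduced exactly", {
  cfg <- tiny_cfg(seed = 10,
                  p_dawn_ascent = c(breeding = 0, migration = 0,
                                    nonbreeding = 1),
                  ascent_mean = 400, ascent_sd = 0)
  s <- simulate_annual_cycle(cfg)
  tw <- s$truth$twilights
  nb_dawn <- tw$phase == "nonbreeding" & tw$type == "dawn"
  expect_gt(sum(nb_dawn), 30)
  expect_true(all(tw$is_ascent[nb_dawn]))
  expect_true(all(tw$ascent_height[nb_dawn] == 400))
})

test_that("tag pressure inverts to the true altitude without noise", {
  b <- local_bird(stationary_cfg, "stationary")
  p <- b$series$pressure
  truth <- b$truth$behaviour
  alt <- pressure_to_altitude(p$value, 1013.25)  # front_amp 0: uniform MSLP
  m <- merge(data.frame(time = p$time, alt = alt),
             truth[, c("time", "altitude")], by = "time")
  expect_gt(nrow(m), 1000)
  expect_lt(max(abs(m$alt - m$altitude)), 1)
})

test_that("noise-free light is monotone in solar elevation", {
  b <- local_bird(stationary_cfg, "stationary")
  cfg <- stationary_cfg()
  idx <- 3000:6000
  lt <- b$series$light[idx, ]
  elev <- solar_elevation(10.5, -11, lt$time)   # residence site
  o <- order(elev)
  dl <- diff(lt$value[o])
  expect_true(all(dl > -1e-6))
  expect_true(all(lt$value >= 0 & lt$value <= cfg$light_max))
})

test_that("true ascent rates match the configured probabilities", {
  cfg <- sim_config(start = "2014-10-01", end = "2015-03-10",
                    autumn_start = "2014-10-02", autumn_end = "2014-10-17",
                    spring_start = "2015-03-06", spring_end = "2015-03-08",
                    seed = 17)
  s <- simulate_annual_cycle(cfg)
  tw <- s$truth$twilights
  nb <- tw[tw$phase == "nonbreeding", ]
  p_dawn <- mean(nb$is_ascent[nb$type == "dawn"])
  p_dusk <- mean(nb$is_ascent[nb$type == "dusk"])
  n <- sum(nb$type == "dawn")
  expect_lt(abs(p_dawn - 0.5), 4 * sqrt(0.5 * 0.5 / n))
  expect_lt(abs(p_dusk - 1 / 3), 4 * sqrt(2 / 9 / n))
})

test_that("the weather grid covers the box at 2.5-degree, 6-h resolution", {
  cfg <- sim_config(seed = 12)
  g <- simulate_weather_grid(cfg)
  expect_equal(unique(diff(g$lat)), 2.5)
  expect_equal(unique(diff(g$lon)), 2.5)
  expect_equal(range(g$lat), cfg$grid_lat)
  expect_equal(range(g$lon), cfg$grid_lon)
  expect_equal(unique(diff(as.numeric(g$time))), 21600)
})

test_that("zero front amplitude freezes the pressure field", {
  cfg <- tiny_cfg(seed = 13, front_amp = 0)
  g <- simulate_weather_grid(cfg)
  expect_true(all(g$vars$mslp == cfg$base_mslp))
  track <- data.frame(time = g$time[c(10, 30)], lat = c(10, 30),
                      lon = c(0, 5))
  w <- annotate_weather(track, g)
  expect_true(all(w$dmslp_before == 0) && all(w$dmslp_after == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(tiny_cfg(p_dawn_ascent = c(breeding = -0.1, migration = 0.2,
                                          nonbreeding = 0.5)), "invalid")
  expect_error(tiny_cfg(cavity_p = 1.4), "invalid")
  expect_error(sim_config(start = "2014-10-01", end = "2014-09-01"),
               "invalid")
  expect_error(tiny_cfg(pressure_noise_sd = -1), "invalid")
})

test_that("a simulated cohort shares the weather but not the draws", {
  cfg <- tiny_cfg(seed = 19)
  co <- simulate_cohort(cfg, populations = c("pA", "pB"), n_per_pop = 1)
  expect_length(co, 2)
  l1 <- co[[1]]$series$light$value
  l2 <- co[[2]]$series$light$value
  expect_false(identical(l1, l2))
  # same synoptic truth: ascent flags differ but the weather field is the
  # config's single realisation
  expect_identical(attr(simulate_weather_grid(cfg), "fronts"),
                   attr(simulate_weather_grid(cfg), "fronts"))
})
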