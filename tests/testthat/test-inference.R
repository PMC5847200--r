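# Build a synthetic record table directly (no pipeline), with known
# fixed effects, AR(1) response correlation, and noise covariates.
make_synth_records <- function(n_ind = 6, n_tw = 200, beta_phase = 0,
                               beta_type = 0, ar = 0, base_p = 0.35,
                               seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_ind)) {
    phase <- sample(c("migration", "nonbreeding"), n_tw, replace = TRUE)
    type <- rep(c("dawn", "dusk"), length.out = n_tw)
    eta <- qlogis(base_p) + beta_phase * (phase == "nonbreeding") +
      beta_type * (type == "dusk")
    p <- plogis(eta)
    # binary Markov chain with lag-1 correlation `ar` around p_t
    y <- integer(n_tw)
    y[1] <- rbinom(1, 1, p[1])
    for (k in 2:n_tw) {
      pk <- p[k] + ar * (y[k - 1] - p[k - 1]) *
        sqrt(p[k] * (1 - p[k]) / (p[k - 1] * (1 - p[k - 1])))
      y[k] <- rbinom(1, 1, min(max(pk, 0.01), 0.99))
    }
    rows[[i]] <- data.frame(
      individual = sprintf("I%02d", i),
      population = if (i <= n_ind / 2) "pA" else "pB",
      seq = seq_len(n_tw), phase = phase, type = type, is_ascent = y == 1,
      flight_alt = rnorm(n_tw, 1000, 200), t2m = rnorm(n_tw, 295, 3),
      mslp = rnorm(n_tw, 1013, 4), wind = rexp(n_tw, 0.2),
      rh = runif(n_tw, 30, 90),
      dmslp_before = abs(rnorm(n_tw, 0, 2)),
      dmslp_after = abs(rnorm(n_tw, 0, 2)),
      dtemp_before = abs(rnorm(n_tw, 0, 1)),
      dtemp_after = abs(rnorm(n_tw, 0, 1)),
      drh_before = abs(rnorm(n_tw, 0, 8)),
      drh_after = abs(rnorm(n_tw, 0, 8)))
  }
  do.call(rbind, rows)
}

test_that("exact signed-rank test reproduces the closed-form cases", {
  r <- wilcoxon_median_ascent(c(3, 1, 4, 2, 5))
  expect_equal(r$V, 15)
  expect_equal(r$p, 1 / 32)
  r <- wilcoxon_median_ascent(-c(3, 1, 4, 2, 5))
  expect_equal(r$V, 0)
  expect_equal(r$p, 1)
  r <- wilcoxon_median_ascent(c(-2, -1, 0, 1, 2))
  expect_equal(r$n_used, 4)
  expect_gt(r$p, 0.05)
  expect_error(wilcoxon_median_ascent(c(1, NA)), "missing")
})

test_that("signed-rank V and p match exhaustive enumeration up to n = 10", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n, 0.3, 1), sample(c(0, 1), 1))  # ties likely
    ref <- wilcoxon_enum(x)
    got <- wilcoxon_median_ascent(x)
    expect_equal(got$V, ref$V)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
  }
})

test_that("signed-rank p agrees with the stats implementation without ties", {
  set.seed(24)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    x <- rnorm(n, 0.4, 1)
    got <- wilcoxon_median_ascent(x)
    ref <- stats::wilcox.test(x, alternative = "greater", exact = TRUE)
    expect_equal(got$V, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("AR(1) parameter is recovered from correlated binary series", {
  rec <- make_synth_records(n_ind = 6, n_tw = 300, ar = 0.5, seed = 31)
  f <- fit_ascent_model(rec, niter = 4)
  expect_true(f$converged)
  expect_lt(abs(f$ar1 - 0.5), 0.15)
})

test_that("with independent responses the fit matches a plain GLM", {
  rec <- make_synth_records(n_ind = 8, n_tw = 400, beta_phase = 1,
                            beta_type = -0.5, ar = 0, seed = 32)
  f <- fit_ascent_model(rec, niter = 6)
  d <- rec
  d$y <- as.integer(d$is_ascent)
  d$phase <- factor(d$phase, levels = c("migration", "nonbreeding"))
  g <- glm(y ~ phase + type + flight_alt + t2m + mslp + wind + rh +
             dmslp_before + dmslp_after + dtemp_before + dtemp_after +
             drh_before + drh_after, family = binomial, data = d)
  co <- f$coefficients
  expect_lt(abs(co$estimate[co$factor == "phasenonbreeding"] -
                coef(g)[["phasenonbreeding"]]), 0.01)
  expect_lt(abs(co$estimate[co$factor == "typedusk"] -
                coef(g)[["typedusk"]]), 0.01)
  expect_lt(abs(f$ar1), 0.1)
})

test_that("known fixed effects are recovered with correct signs and CIs", {
  rec <- make_synth_records(n_ind = 8, n_tw = 300, beta_phase = 1,
                            beta_type = -0.7, ar = 0.3, seed = 33)
  f <- fit_ascent_model(rec, niter = 4)
  co <- f$coefficients
  pn <- co[co$factor == "phasenonbreeding", ]
  td <- co[co$factor == "typedusk", ]
  expect_gt(pn$lo, 0)
  expect_lt(td$hi, 0)
  expect_lt(abs(pn$estimate - 1), 3 * pn$se)
  expect_equal(co$hi - co$estimate, 2 * co$se, tolerance = 1e-10)
})

test_that("degenerate factors are dropped with a warning, not fatal", {
  rec <- make_synth_records(n_ind = 4, n_tw = 150, seed = 34)
  rec$wind <- 5
  expect_warning(f <- fit_ascent_model(rec, niter = 3), "degenerate.*wind")
  expect_true(f$converged)
  expect_false("wind_z" %in% f$coefficients$factor)
  expect_equal(f$dropped, "wind")
})

test_that("fewer than two individuals is an error", {
  rec <- make_synth_records(n_ind = 1, n_tw = 120)
  expect_error(fit_ascent_model(rec), "2 individuals")
})

test_that("the ensemble is deterministic and strict about zero crossings", {
  # records differ by run: a moderate phase effect that wobbles with the
  # run seed, so some runs' CIs cross zero
  mk <- function(seed) make_synth_records(
    n_ind = 4, n_tw = 150, beta_phase = 0.45 + 0.3 * (seed %% 2),
    seed = seed)
  ens <- run_ensemble(mk, n_runs = 4, seed = 100, niter = 3)
  ens2 <- run_ensemble(mk, n_runs = 4, seed = 100, niter = 3)
  expect_identical(ens$fits, ens2$fits)
  rel <- ens$relevance
  pn <- rel[rel$factor == "phasenonbreeding", ]
  # relevance demands zero excluded from every single run
  expect_equal(pn$relevant, pn$n_excluding_zero == pn$n_runs)
  expect_error(run_ensemble(mk, n_runs = 0), "positive")
  # degenerate resampling: identical data in every run -> identical fits
  mk1 <- function(seed) make_synth_records(n_ind = 4, n_tw = 120, seed = 7)
  ens3 <- run_ensemble(mk1, n_runs = 3, seed = 5, niter = 3)
  est <- ens3$fits$estimate[ens3$fits$factor == "typedusk"]
  expect_true(all(est == est[1]))
})

test_that("activity predicts altitude change only around twilight", {
  set.seed(41)
  n <- 600
  ind <- rep(c("A", "B", "C"), each = n / 3)
  twl <- rep(c(TRUE, FALSE), c(150, 450))[sample(n)]
  act <- abs(rnorm(n, 10, 6))
  dalt <- ifelse(twl, 15 * act + rnorm(n, 0, 30), rnorm(n, 0, 60))
  pairs <- data.frame(individual = ind, dalt = dalt, activity = act,
                      twilight = twl)
  s <- activity_altitude_slope(pairs)
  tw <- s[s$subset == "twilight", ]
  expect_gt(tw$lo, 0)
  # shuffling activity destroys the association
  sh <- pairs
  sh$activity <- sample(sh$activity)
  s2 <- activity_altitude_slope(sh)
  expect_true(s2$lo[1] < 0 & s2$hi[1] > 0)
})

test_that("altitude-change pairs use magnitudes, not levels", {
  b <- local_bird(stationary_cfg, "stationary")
  alt <- data.frame(time = b$series$pressure$time,
                    alt = pressure_to_altitude(b$series$pressure$value,
                                               1013.25))
  ev <- b$truth$twilights
  p1 <- altitude_change_pairs(b$series, alt, ev)
  p2 <- altitude_change_pairs(b$series, transform(alt, alt = alt + 500), ev)
  expect_equal(p1$dalt, p2$dalt, tolerance = 1e-9)
  expect_true(any(p1$twilight))
  s <- activity_altitude_slope(p1)
  expect_equal(nrow(s), 2)
  # simulated twilight ascents are flapped climbs: positive twilight slope
  expect_gt(s$slope[s$subset == "twilight"], 0)
})
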