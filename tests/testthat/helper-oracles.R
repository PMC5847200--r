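# Independent oracles, deliberately coded from different algorithms than
# the package implementations.

# Solar elevation after Michalsky (1988): ecliptic-coordinate almanac,
# independent of the package's fractional-year NOAA formulation.
michalsky_elevation <- function(lat, lon, time) {
  jd <- as.numeric(time) / 86400 + 2440587.5
  n <- jd - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 4e-7 * n) * pi / 180
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda))
  dec <- asin(sin(eps) * sin(lambda))
  ut_h <- (as.numeric(time) %% 86400) / 3600
  gmst <- (6.697375 + 0.0657098242 * n + ut_h) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- lmst * 15 * pi / 180 - ra
  asin(sin(dec) * sin(lat * pi / 180) +
         cos(dec) * cos(lat * pi / 180) * cos(ha)) * 180 / pi
}

# High-precision inversion oracle for the barometric formula: finds the
# altitude whose pressure ratio matches, by bisection on the analytic
# inverse, never evaluating the forward formula.
barometric_oracle <- function(p_h, p_0, T0 = 288.15, lapse = 0.0065,
                              kappa = 1.235) {
  e <- (kappa - 1) / kappa
  ratio <- p_h / p_0
  f <- function(h) (1 - h * lapse / T0)^(1 / e) - ratio
  stats::uniroot(f, lower = -5000, upper = 40000, tol = 1e-10)$root
}

# Brute-force smoothing posterior: enumerate every grid path.
hmm_brute_force <- function(liks, trans, prior = NULL) {
  n <- length(liks); m <- length(liks[[1]])
  if (is.null(prior)) prior <- rep(1 / m, m)
  paths <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  w <- apply(paths, 1, function(p) {
    v <- prior[p[1]] * liks[[1]][p[1]]
    if (n > 1) for (k in 2:n)
      v <- v * trans[p[k - 1], p[k]] * liks[[k]][p[k]]
    v
  })
  lapply(seq_len(n), function(k)
    vapply(seq_len(m), function(c) sum(w[paths[, k] == c]), 0) / sum(w))
}

# Exhaustive signed-rank test: every sign assignment enumerated.
wilcoxon_enum <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(list(V = 0, p = 1))  # nothing to test: never reject
  r <- rank(abs(x))
  V <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  list(V = V, p = mean(Vs >= V - 1e-9))
}
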