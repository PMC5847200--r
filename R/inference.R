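#' Fit the autocorrelated binomial ascent model
#'
#' Binomial (logit) mixed model for the per-twilight ascent flag, fitted by
#' penalized quasi-likelihood ([MASS::glmmPQL]) with a random intercept for
#' individual nested in population and a first-order autoregressive
#' correlation ([nlme::corAR1]) over the twilight sequence within
#' individual — consecutive twilights (dawn to dusk and dusk to dawn alike)
#' are lag-1 neighbours. Fixed factors: phase of the annual cycle
#' (reference level `migration`), twilight type (reference `dawn`), mean
#' 12-h flight altitude, the four weather state variables, and the six
#' absolute 24-h change factors for pressure, temperature and humidity.
#' All continuous factors are z-transformed first so effect sizes are
#' comparable; a factor with zero variance is dropped with a warning.
#' Confidence intervals are estimate plus/minus twice the standard error.
#'
#' @param records Data frame from [build_ascent_records()] (rows with
#'   missing response or factors are dropped).
#' @param weather_factors Character vector of continuous factor column
#'   names to include.
#' @param niter PQL iterations (default 5; the fixed effects stabilise
#'   within a few iterations).
#' @param verbose Passed to `glmmPQL`.
#' @return Object of class `ascent_model_fit`: list with `coefficients`
#'   (data frame: factor, estimate, se, lo, hi), `ar1`, `converged`, `n`,
#'   `dropped` (degenerate factors), `random` (grouping actually used),
#'   `separation` (factors with runaway standard errors).
#' @export
fit_ascent_model <- function(records,
                             weather_factors = c("flight_alt", "t2m", "mslp",
                                                 "wind", "rh",
                                                 "dmslp_before", "dmslp_after",
                                                 "dtemp_before", "dtemp_after",
                                                 "drh_before", "drh_after"),
                             niter = 5, verbose = FALSE) {
  need <- c("is_ascent", "phase", "type", "individual", "population", "seq",
            weather_factors)
  d <- records[stats::complete.cases(records[, need]), need]
  if (length(unique(d$individual)) < 2)
    stop("need at least 2 individuals", call. = FALSE)
  d$phase <- factor(d$phase, levels = c("migration", "breeding", "nonbreeding"))
  d$phase <- droplevels(d$phase)
  d$type <- factor(d$type, levels = c("dawn", "dusk"))
  d$y <- as.integer(d$is_ascent)
  dropped <- character(0)
  kept <- character(0)
  for (f in weather_factors) {
    z <- tryCatch(z_transform(d[[f]]), degenerate_factor = function(e) NULL)
    if (is.null(z)) {
      dropped <- c(dropped, f)
      warning("dropping degenerate factor: ", f, call. = FALSE)
    } else {
      d[[paste0(f, "_z")]] <- z
      kept <- c(kept, paste0(f, "_z"))
    }
  }
  terms <- c(if (nlevels(d$phase) > 1) "phase",
             if (nlevels(droplevels(d$type)) > 1) "type", kept)
  fml <- stats::reformulate(terms, response = "y")
  pql <- function(random) tryCatch(
    suppressWarnings(MASS::glmmPQL(fml, random = random,
      family = stats::binomial, data = d,
      correlation = nlme::corAR1(form = ~ seq),
      niter = niter, verbose = verbose)),
    error = function(e) e)
  # With a handful of populations the population-level variance sits on
  # the boundary and the nested PQL system can go numerically singular;
  # fall back to the individual-level intercept (AR(1) structure kept).
  random_used <- "population/individual"
  if (length(unique(d$population)) > 1) {
    fit <- pql(stats::as.formula("~ 1 | population/individual"))
    if (inherits(fit, "error")) {
      fit <- pql(stats::as.formula("~ 1 | individual"))
      random_used <- "individual"
    }
  } else {
    fit <- pql(stats::as.formula("~ 1 | individual"))
    random_used <- "individual"
  }
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, ar1 = NA_real_,
                          converged = FALSE, n = nrow(d), dropped = dropped,
                          message = conditionMessage(fit)),
                     class = "ascent_model_fit"))
  }
  tab <- summary(fit)$tTable
  est <- tab[, "Value"]; se <- tab[, "Std.Error"]
  co <- data.frame(factor = rownames(tab), estimate = est, se = se,
                   lo = est - 2 * se, hi = est + 2 * se,
                   row.names = NULL, stringsAsFactors = FALSE)
  ar1 <- tryCatch(as.numeric(stats::coef(fit$modelStruct$corStruct,
                                         unconstrained = FALSE)),
                  error = function(e) NA_real_)
  structure(list(coefficients = co, ar1 = ar1, converged = TRUE,
                 n = nrow(d), dropped = dropped, random = random_used,
                 # runaway SE signals (quasi-)complete separation in a level
                 separation = co$factor[co$se > 50]),
            class = "ascent_model_fit")
}

#' @export
print.ascent_model_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<ascent_model_fit> NOT converged:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<ascent_model_fit> n = %d twilights, AR(1) = %.3f\n",
              x$n, x$ar1))
  print(transform(x$coefficients, estimate = round(estimate, 3),
                  se = round(se, 3), lo = round(lo, 3), hi = round(hi, 3)))
  invisible(x)
}

#' Run the resampled-track model ensemble
#'
#' Repeats the ascent regression over independently redrawn bootstrap
#' tracks: each run rebuilds the record table (new phase labels and weather
#' annotations from the redrawn positions) and refits the model. A factor
#' is flagged statistically relevant only when zero lies outside every one
#' of the runs' confidence intervals — one excursion through zero in a
#' single run removes the flag. Non-converged runs are excluded; more than
#' 20 percent of them aborts the ensemble.
#'
#' @param make_records Function `seed -> records data frame`, drawing one
#'   track realisation per individual (deterministic given its seed).
#' @param n_runs Number of runs (default 100).
#' @param seed Master seed; run `r` uses `seed + r`.
#' @param ... Passed to [fit_ascent_model()].
#' @return Object of class `run_ensemble`: list with `fits` (long data
#'   frame: run, factor, estimate, se, lo, hi), `relevance` (factor,
#'   n_runs, n_excluding_zero, relevant, sign), `n_converged`, `ar1`
#'   (per-run vector).
#' @export
run_ensemble <- function(make_records, n_runs = 100, seed = 1, ...) {
  if (n_runs <= 0) stop("n_runs must be positive", call. = FALSE)
  fits <- list(); ar1 <- rep(NA_real_, n_runs); conv <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    rec <- make_records(seed + r)
    f <- fit_ascent_model(rec, ...)
    conv[r] <- f$converged
    if (f$converged) {
      ar1[r] <- f$ar1
      fits[[length(fits) + 1]] <- cbind(run = r, f$coefficients)
    }
  }
  if (mean(conv) < 0.8)
    stop("ensemble failure: more than 20% of runs did not converge",
         call. = FALSE)
  long <- do.call(rbind, fits)
  rel <- do.call(rbind, lapply(split(long, long$factor), function(g) {
    excl <- g$lo > 0 | g$hi < 0
    data.frame(factor = g$factor[1], n_runs = nrow(g),
               n_excluding_zero = sum(excl),
               relevant = all(excl),
               sign = sign(mean(g$estimate)),
               mean_estimate = mean(g$estimate),
               stringsAsFactors = FALSE)
  }))
  rownames(rel) <- NULL
  structure(list(fits = long, relevance = rel, n_converged = sum(conv),
                 ar1 = ar1), class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat(sprintf("<run_ensemble> %d converged runs\n", x$n_converged))
  print(x$relevance)
  invisible(x)
}

#' Ensemble estimate plot
#'
#' Per-factor blocks of run-wise estimates with their 2-SE confidence
#' bars, the graphical report of the ensemble.
#'
#' @param x A `run_ensemble`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ensemble <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(x$fits, ggplot2::aes(x = run, y = estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = lo, ymax = hi),
                            colour = "grey50") +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_wrap(~factor, scales = "free_y") +
    ggplot2::labs(x = "model run", y = "estimate (2-SE interval)")
}

#' Exact one-sided Wilcoxon signed-rank test
#'
#' Tests whether per-individual median ascent heights exceed zero. Zeros
#' are dropped (standard convention); absolute values are ranked with
#' average ranks on ties; V is the sum of ranks of the positive values.
#' The one-sided p-value P(V* >= V) under random signs is exact up to
#' n = 25 (closed form without ties, full sign-assignment distribution by
#' convolution with ties) and a normal approximation with tie correction
#' above.
#'
#' @param medians Numeric vector, one median ascent height per individual
#'   (NA not allowed).
#' @return List: `V`, `p` (one-sided, greater), `n_used`, `method`.
#' @export
wilcoxon_median_ascent <- function(medians) {
  if (anyNA(medians)) stop("missing medians not allowed", call. = FALSE)
  x <- medians[medians != 0]
  n <- length(x)
  if (n == 0) return(list(V = 0, p = 1, n_used = 0L, method = "degenerate"))
  r <- rank(abs(x))
  V <- sum(r[x > 0])
  ties <- any(duplicated(abs(x)))
  if (!ties && n <= 25) {
    p <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    method <- "exact"
  } else if (n <= 25) {
    # exact distribution over all 2^n sign assignments, by convolution on
    # doubled ranks (average ranks are integers or half-integers)
    r2 <- round(2 * r)
    f <- c(1)   # f[k+1] = #assignments with doubled statistic k
    for (ri in r2) {
      g <- c(f, numeric(ri))
      g[(ri + 1):(ri + length(f))] <- g[(ri + 1):(ri + length(f))] + f
      f <- g
    }
    p <- sum(f[seq(round(2 * V) + 1, length(f))]) / 2^n
    method <- "exact-ties"
  } else {
    mu <- sum(r) / 2
    sg <- sqrt(sum(r^2) / 4)
    p <- stats::pnorm((V - mu - 0.5) / sg, lower.tail = FALSE)
    method <- "normal"
  }
  list(V = V, p = p, n_used = n, method = method)
}

#' Activity versus 30-min altitude change
#'
#' For every 30-min interval of the altitude series, pairs the absolute
#' altitude change with the mean activity over the interval, splits the
#' intervals into those containing a twilight event and all others, and
#' fits to each subset a linear mixed model (individual as random
#' intercept) of z-scored altitude change on z-scored activity. A positive
#' twilight slope says twilight activity peaks are climbing flight, not
#' level flight.
#'
#' @param pairs Data frame with columns `individual`, `dalt` (m per
#'   30 min), `activity` (mean score), `twilight` (logical). Build it with
#'   [altitude_change_pairs()].
#' @return Data frame: `subset`, `slope`, `se`, `lo`, `hi`, `n`.
#' @export
activity_altitude_slope <- function(pairs) {
  d <- pairs[stats::complete.cases(pairs[, c("dalt", "activity")]), ]
  if (nrow(d) < 10) stop("insufficient altitude/activity pairs", call. = FALSE)
  one <- function(sub, name) {
    sub$da_z <- z_transform(abs(sub$dalt))
    sub$ac_z <- z_transform(sub$activity)
    m <- if (length(unique(sub$individual)) > 1)
      nlme::lme(da_z ~ ac_z, random = ~ 1 | individual, data = sub)
    else stats::lm(da_z ~ ac_z, data = sub)
    tab <- if (inherits(m, "lme")) summary(m)$tTable else summary(m)$coefficients
    est <- tab["ac_z", 1]; se <- tab["ac_z", 2]
    data.frame(subset = name, slope = est, se = se,
               lo = est - 2 * se, hi = est + 2 * se, n = nrow(sub),
               stringsAsFactors = FALSE)
  }
  rbind(one(d[d$twilight, ], "twilight"),
        one(d[!d$twilight, ], "other"))
}

#' Build 30-min altitude-change / activity pairs
#'
#' An interval counts as a twilight interval when it overlaps the hour
#' centred on a twilight event (`window` each side), so the climb into and
#' out of a twilight ascent is attributed to the twilight, not only the
#' instant of the crossing itself.
#'
#' @param series A [sensor_series()].
#' @param altitude Data frame `time`, `alt` (see [altitude_series()]).
#' @param events Data frame of twilight events (`time` column).
#' @param window Half-width of the twilight hour, seconds (default 30 min).
#' @return Data frame for [activity_altitude_slope()].
#' @export
altitude_change_pairs <- function(series, altitude, events, window = 1800) {
  ta <- as.numeric(series$activity$time)
  t0 <- as.numeric(altitude$time)
  n <- nrow(altitude) - 1
  if (n < 1) stop("altitude series too short", call. = FALSE)
  dalt <- diff(altitude$alt)
  act <- vapply(seq_len(n), function(i) {
    inwin <- ta >= t0[i] & ta < t0[i + 1]
    if (!any(inwin)) NA_real_ else mean(series$activity$value[inwin],
                                        na.rm = TRUE)
  }, numeric(1))
  et <- as.numeric(events$time)
  twl <- vapply(seq_len(n), function(i)
    any(et + window > t0[i] & et - window < t0[i + 1]), logical(1))
  data.frame(individual = series$individual_id,
             time = altitude$time[seq_len(n)],
             dalt = dalt, activity = act, twilight = twl,
             stringsAsFactors = FALSE)
}
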