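#' Classify 5-min intervals as flapping, gliding or resting
#'
#' Activity separates flapping from non-flapping flight; whether a
#' non-flapping bird is airborne at all is best told by the variance of the
#' pressure signal — a bird on the ground sits at constant barometric
#' altitude while a gliding bird drifts through pressure levels. Rule:
#' activity at or above `flap_threshold` is `flapping`; otherwise an
#' interval is `resting` when activity is below `rest_threshold` and the
#' rolling pressure variance (minimum over the centred and one-sided 3-h
#' windows with at least 3 samples each) at the nearest pressure sample is
#' below `ground_var`; all
#' remaining intervals are `gliding`. The variance criterion makes the
#' classification invariant to pressure offset. The numeric defaults are
#' calibrated against the synthetic generator's regimes (flap threshold
#' near the flapping regime's 5th percentile, rest threshold near the
#' resting regime's 95th percentile).
#'
#' @param activity Data frame `time`/`value`, 5-min cadence.
#' @param pressure Data frame `time`/`value` (hPa), 30-min cadence.
#' @param flap_threshold Activity score at or above which the bird flaps
#'   (default 25).
#' @param rest_threshold Activity score below which rest is possible
#'   (default 2).
#' @param ground_var Pressure variance (hPa^2) below which the bird is on
#'   the ground (default 0.5).
#' @param var_window Rolling-variance window, seconds (default 3 h).
#' @return Data frame `time`, `label`; one label per activity sample that
#'   overlaps the pressure record.
#' @export
classify_behaviour <- function(activity, pressure, flap_threshold = 25,
                               rest_threshold = 2, ground_var = 0.5,
                               var_window = 3 * 3600) {
  ta <- as.numeric(activity$time); tp <- as.numeric(pressure$time)
  keep <- ta >= min(tp) - 900 & ta <= max(tp) + 900
  if (!any(keep)) stop("activity and pressure do not overlap", call. = FALSE)
  ta <- ta[keep]; act <- activity$value[keep]
  # rolling pressure variance: minimum over the centred, left- and
  # right-aligned windows (>= 3 samples each), so a bird sitting on the
  # ground next to a take-off or landing still shows its constant side
  half <- var_window / 2
  winvar <- function(i, lo, hi) {
    w <- pressure$value[tp >= tp[i] + lo & tp <= tp[i] + hi]
    w <- w[!is.na(w)]
    if (length(w) < 3) NA_real_ else stats::var(w)
  }
  pvar <- vapply(seq_along(tp), function(i) {
    v <- c(winvar(i, -half, half), winvar(i, -var_window, 0),
           winvar(i, 0, var_window))
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }, numeric(1))
  nearest <- findInterval(ta, tp - 900) # nearest 30-min sample (grid-aligned)
  nearest <- pmax(1L, pmin(length(tp), nearest))
  pv <- pvar[nearest]
  label <- rep("gliding", length(ta))
  label[act >= flap_threshold] <- "flapping"
  rest <- act < rest_threshold & !is.na(pv) & pv < ground_var &
    act < flap_threshold
  label[rest] <- "resting"
  data.frame(time = .POSIXct(ta, tz = "UTC"), label = label,
             stringsAsFactors = FALSE)
}

#' Hourly behaviour frequency summary
#'
#' Aggregates labels into an hour-of-day by date frequency table per
#' behaviour — the raster underlying season-by-time-of-day behaviour
#' plots.
#'
#' @param labels Data frame from [classify_behaviour()] (possibly from
#'   several individuals, concatenated).
#' @return Data frame `date`, `hour`, `flapping`, `gliding`, `resting`
#'   (fractions summing to 1 per cell), and `n` samples.
#' @export
behaviour_frequency_summary <- function(labels) {
  date <- as.Date(labels$time)
  hour <- as.integer(format(labels$time, "%H", tz = "UTC"))
  key <- split(labels$label, list(date = date, hour = hour), drop = TRUE)
  rows <- lapply(names(key), function(k) {
    parts <- strsplit(k, "\\.")[[1]]
    lab <- key[[k]]
    data.frame(date = as.Date(parts[1]), hour = as.integer(parts[2]),
               flapping = mean(lab == "flapping"),
               gliding = mean(lab == "gliding"),
               resting = mean(lab == "resting"),
               n = length(lab))
  })
  out <- do.call(rbind, rows)
  out[order(out$date, out$hour), ]
}
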