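#' Annual-cycle phase of a position
#'
#' The spatial rule partitioning the globe into the three phases: within
#' 200 km (great-circle) of the breeding colony is `breeding`; at least
#' 200 km away and still at or north of the southern Sahara border
#' (latitude 15 N) is `migration`; south of 15 N is `nonbreeding`.
#' Boundaries are inclusive on the migration side (exactly 200 km, exactly
#' 15.0 N), and the colony-distance rule is applied first, so a
#' hypothetical position within 200 km of a colony south of 15 N would
#' still read `breeding`.
#'
#' @param lat,lon Position(s), decimal degrees.
#' @param colony Named vector `c(lat = , lon = )` of the colony.
#' @param breeding_radius_km Colony radius, km (default 200).
#' @param sahara_lat Southern Sahara border latitude, degrees (default 15).
#' @return Character vector in `{breeding, migration, nonbreeding}`.
#' @export
phase_of_position <- function(lat, lon, colony, breeding_radius_km = 200,
                              sahara_lat = 15) {
  stopifnot(all(abs(lat) <= 90))
  d_km <- geosphere::distGeo(cbind(lon, lat),
                             c(colony[["lon"]], colony[["lat"]])) / 1000
  ifelse(d_km < breeding_radius_km, "breeding",
         ifelse(lat >= sahara_lat, "migration", "nonbreeding"))
}

#' Phase membership probabilities from a positional posterior
#'
#' Sums each event's posterior mass over the three phase regions, giving
#' the probability with which the event belongs to each phase — the
#' quantity the track bootstrap propagates into the regression.
#'
#' @param posterior A `position_posterior` (see [estimate_positions()]).
#' @param colony Named vector `c(lat = , lon = )`.
#' @param ... Passed to [phase_of_position()].
#' @return Data frame, one row per event: `time`, `type`, `breeding`,
#'   `migration`, `nonbreeding` (each row sums to 1), plus `hard` (argmax).
#' @export
phase_probabilities <- function(posterior, colony, ...) {
  g <- posterior$grid
  cell_lat <- rep(g$lat, times = g$nlon)
  cell_lon <- rep(g$lon, each = g$nlat)
  ph <- phase_of_position(cell_lat, cell_lon, colony, ...)
  M <- cbind(breeding = as.numeric(ph == "breeding"),
             migration = as.numeric(ph == "migration"),
             nonbreeding = as.numeric(ph == "nonbreeding"))
  P <- posterior$post %*% M
  P <- P / rowSums(P)
  data.frame(time = posterior$events$time, type = posterior$events$type,
             breeding = P[, 1], migration = P[, 2], nonbreeding = P[, 3],
             hard = colnames(P)[max.col(P, ties.method = "first")],
             stringsAsFactors = FALSE)
}
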