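#' Pipeline run configuration
#'
#' Defaults follow the study design: ascent threshold 300 m, 10,000
#' bootstrap tracks, 100 model runs, abrupt-light fraction 0.8, a 1-degree
#' positional grid. Smaller values are useful for quick runs; the defaults
#' are the reference conditions.
#'
#' @param light_threshold Light threshold for twilight detection; `NULL`
#'   takes the simulation config's calibrated value.
#' @param ascent_threshold Ascent height threshold, m.
#' @param unnatural_fraction Dynamic-range fraction defining an abrupt
#'   light step.
#' @param grid_res Positional grid resolution, degrees.
#' @param movement_sd Random-walk sd between twilights, degrees.
#' @param twilight_sd Twilight-time error sd, minutes.
#' @param n_tracks Bootstrap tracks for phase-frequency summaries.
#' @param n_runs Model runs in the ensemble.
#' @param seed Master seed for every random stage.
#' @param output_dir Optional directory for CSV/JSON artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(light_threshold = NULL, ascent_threshold = 300,
                       unnatural_fraction = 0.8, grid_res = 1,
                       movement_sd = 1, twilight_sd = 8,
                       n_tracks = 10000, n_runs = 100, seed = 1,
                       output_dir = NULL) {
  structure(list(light_threshold = light_threshold,
                 ascent_threshold = ascent_threshold,
                 unnatural_fraction = unnatural_fraction,
                 grid_res = grid_res, movement_sd = movement_sd,
                 twilight_sd = twilight_sd, n_tracks = n_tracks,
                 n_runs = n_runs, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

.stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  log(name)
  res
}

#' Run the full ascent-analysis pipeline
#'
#' simulate (or accept) tag data -> detect and flag twilights -> grid-HMM
#' positional posteriors -> complete the twilight set astronomically ->
#' barometric altitude and ascent records along the median track ->
#' behaviour classification -> resampled-track model ensemble -> summary.
#' Deterministic given the seeds in `sim` and `config`. Per-stage counters
#' (events detected, events flagged unnatural, records dropped) are
#' collected in the returned `log`.
#'
#' @param sim A [sim_config()] describing the cohort's study conditions.
#' @param config A [run_config()].
#' @param populations Character vector of population names to simulate.
#' @param n_per_pop Birds per population.
#' @param cohort Optional pre-built list of `list(series, truth)` entries
#'   (as from [simulate_cohort()]); when supplied, `populations` and
#'   `n_per_pop` are ignored.
#' @param grid Optional [weather_grid()]; default simulates one from `sim`.
#' @param run_ensemble_stage Set `FALSE` to stop after the record tables
#'   (useful for partial runs).
#' @return List of class `pipeline_result`: `records` (median-track ascent
#'   records, all individuals), `ensemble`, `posteriors`, `phase_probs`,
#'   `behaviour`, `summary`, `log`, `config`, `sim`.
#' @export
run_pipeline <- function(sim = sim_config(), config = run_config(),
                         populations = c("popA", "popB"), n_per_pop = 5,
                         cohort = NULL, grid = NULL,
                         run_ensemble_stage = TRUE) {
  stopifnot(inherits(sim, "sim_config"), inherits(config, "run_config"))
  counters <- list()
  log <- function(name) counters[[name]] <<- TRUE
  note <- function(key, val) counters[[key]] <<- val

  if (is.null(grid))
    grid <- .stage("weather", log, simulate_weather_grid(sim))
  if (is.null(cohort))
    cohort <- .stage("simulate", log,
                     simulate_cohort(sim, populations, n_per_pop))
  colony <- c(lat = sim$colony_lat, lon = sim$colony_lon)
  thr <- if (is.null(config$light_threshold)) sim$light_threshold
         else config$light_threshold
  dates <- seq(sim$start + 1, sim$end - 1, by = "day")

  per_ind <- .stage("geolocate", log, lapply(cohort, function(b) {
    ev <- detect_twilights(b$series$light, thr)
    ev <- flag_unnatural(b$series$light, ev,
                         fraction = config$unnatural_fraction,
                         dynamic_range = sim$light_max)
    post <- estimate_positions(ev,
      grid_lat = sim$grid_lat, grid_lon = sim$grid_lon,
      grid_res = config$grid_res, movement_sd = config$movement_sd,
      twilight_sd = config$twilight_sd)
    med <- median_track(post)
    tws <- complete_twilights(ev, med, colony, dates)
    list(series = b$series, truth = b$truth, events = ev, post = post,
         median = med, twilights = tws)
  }))
  note("n_events_detected", sum(vapply(per_ind, function(x) nrow(x$events), 0)))
  note("n_events_unnatural",
       sum(vapply(per_ind, function(x) sum(!x$events$natural), 0)))

  records <- .stage("ascents", log, do.call(rbind, lapply(per_ind, function(x)
    build_ascent_records(x$series, x$twilights, x$median, grid, colony,
                         threshold = config$ascent_threshold))))
  rownames(records) <- NULL
  note("n_records", nrow(records))
  note("n_records_missing", sum(is.na(records$ascent_height)))

  behaviour <- .stage("behaviour", log, do.call(rbind, lapply(per_ind,
    function(x) cbind(individual = x$series$individual_id,
                      classify_behaviour(x$series$activity,
                                         x$series$pressure)))))

  phase_probs <- .stage("phases", log, do.call(rbind, lapply(per_ind,
    function(x) cbind(individual = x$series$individual_id,
                      phase_probabilities(x$post, colony)))))

  ens <- NULL
  if (run_ensemble_stage) {
    make_records <- function(run_seed) {
      do.call(rbind, lapply(seq_along(per_ind), function(i) {
        x <- per_ind[[i]]
        tr <- sample_tracks(x$post, 1, seed = run_seed * 1000L + i)
        build_ascent_records(x$series, x$twilights, track_positions(tr, 1),
                             grid, colony,
                             threshold = config$ascent_threshold)
      }))
    }
    ens <- .stage("model", log,
                  run_ensemble(make_records, n_runs = config$n_runs,
                               seed = config$seed))
  }

  summary <- .stage("summary", log,
                    .pipeline_summary(records, ens, config))

  out <- structure(list(records = records, ensemble = ens,
                        posteriors = lapply(per_ind, `[[`, "post"),
                        phase_probs = phase_probs, behaviour = behaviour,
                        per_individual = per_ind,
                        summary = summary, log = counters,
                        config = config, sim = sim),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) .write_artifacts(out, grid)
  out
}

.pipeline_summary <- function(records, ens, config) {
  ok <- !is.na(records$is_ascent)
  r <- records[ok, ]
  freq <- stats::aggregate(is_ascent ~ phase + type, data = r, FUN = mean)
  med <- stats::aggregate(ascent_height ~ phase, data = r, FUN = stats::median)
  dawn <- mean(r$is_ascent[r$type == "dawn"])
  dusk <- mean(r$is_ascent[r$type == "dusk"])
  ind_med <- stats::aggregate(
    ascent_height ~ individual,
    data = r[r$phase == "nonbreeding", ], FUN = stats::median)
  wil <- if (nrow(ind_med) >= 5)
    wilcoxon_median_ascent(ind_med$ascent_height) else NULL
  list(ascent_freq = freq,
       median_ascent_height = med,
       dawn_dusk_ratio = dawn / dusk,
       individual_medians_nonbreeding = ind_med,
       wilcoxon_nonbreeding = wil,
       relevance = if (!is.null(ens)) ens$relevance else NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  twilight records:", nrow(x$records), "\n")
  cat("  dawn:dusk ascent ratio:",
      round(x$summary$dawn_dusk_ratio, 2), "\n")
  cat("  ascent frequency by phase and type:\n")
  print(x$summary$ascent_freq)
  if (!is.null(x$summary$relevance)) {
    cat("  ensemble relevance:\n")
    print(x$summary$relevance[, c("factor", "relevant", "sign")])
  }
  invisible(x)
}

.write_artifacts <- function(res, grid) {
  dir <- res$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfgfile <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(unclass(res$config), cfgfile)
  hash <- substr(unname(tools::md5sum(cfgfile)), 1, 8)
  tag <- sprintf("%s_seed%d", hash, res$config$seed)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, sprintf("%s_%s.csv", name, tag)),
                     row.names = FALSE)
  w(res$records, "ascent_records")
  w(res$phase_probs, "phase_probabilities")
  w(res$behaviour, "behaviour_labels")
  if (!is.null(res$ensemble)) {
    w(res$ensemble$fits, "ensemble_fits")
    jsonlite::write_json(res$ensemble$relevance,
                         file.path(dir, sprintf("relevance_%s.json", tag)),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  write_weather_csv(grid, file.path(dir, sprintf("weather_%s.csv", tag)))
  invisible(dir)
}
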