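#' Configuration for synthetic cell-displacement tracks
#'
#' Tracks emulate a time-lapse of epidermal cells imaged along the meristem:
#' each cell's distance from the QC is recorded at fixed intervals while the
#' cell moves through the linear velocity field
#' `v(x) = relative_rate * (velocity_intercept + velocity_slope * x)`.
#'
#' @param velocity_intercept Velocity at the QC, um/h.
#' @param velocity_slope Increase of velocity per um of distance, 1/h.
#' @param relative_rate_per_condition Named numeric vector of unitless
#'   fold-changes of the whole velocity field per condition (reference = 1).
#' @param sampling_interval Imaging interval, h.
#' @param duration Total imaging duration, h. Must yield at least 3
#'   observations per track.
#' @param track_noise_sd Observation noise on each recorded distance, um.
#' @param n_cells Cells tracked per condition.
#' @param start_range Length-2 numeric, uniform range of starting distances
#'   from the QC (um).
#' @param seed Integer seed.
#' @return An object of class `synth_track_config`.
#' @export
synth_track_config <- function(velocity_intercept = 0.5,
                               velocity_slope = 0.04,
                               relative_rate_per_condition = c(WT = 1),
                               sampling_interval = 0.5,
                               duration = 6,
                               track_noise_sd = 0.2,
                               n_cells = 30,
                               start_range = c(8, 80),
                               seed = 1L) {
  cfg <- structure(list(
    velocity_intercept = velocity_intercept,
    velocity_slope = velocity_slope,
    relative_rate_per_condition = relative_rate_per_condition,
    sampling_interval = sampling_interval,
    duration = duration,
    track_noise_sd = track_noise_sd,
    n_cells = n_cells,
    start_range = start_range,
    seed = as.integer(seed)
  ), class = "synth_track_config")
  validate_track_config(cfg)
  cfg
}

validate_track_config <- function(cfg) {
  check_positive(cfg$sampling_interval, "sampling_interval")
  check_positive(cfg$duration, "duration")
  if (cfg$duration / cfg$sampling_interval < 2) {
    stop_config("configuration error: duration/interval must yield >= 3 observations")
  }
  if (cfg$n_cells < 1) stop_config("configuration error: n_cells must be >= 1")
  if (cfg$track_noise_sd < 0) {
    stop_config("configuration error: track_noise_sd must be >= 0")
  }
  if (is.null(names(cfg$relative_rate_per_condition))) {
    stop_config("configuration error: relative rates must be named by condition")
  }
  a <- cfg$velocity_intercept
  b <- cfg$velocity_slope
  for (r in cfg$relative_rate_per_condition) {
    if (r < 0) stop_config("configuration error: relative rates must be >= 0")
    if (min(r * (a + b * 0), r * (a + b * 100)) < 0) {
      stop_config("configuration error: velocity negative on [0, 100] um")
    }
  }
  invisible(cfg)
}

# Exact position after time t under dx/dt = r (a + b x).
advect <- function(x0, t, a, b, r) {
  if (r == 0) return(rep(x0, length(t)))
  if (b == 0) return(x0 + r * a * t)
  (x0 + a / b) * exp(r * b * t) - a / b
}

#' Generate synthetic displacement tracks
#'
#' Integrates the configured velocity field exactly over each sampling
#' interval and adds independent observation noise to every recorded
#' distance.
#'
#' @param config A [synth_track_config()].
#' @return A data frame with columns `cell_id`, `condition`, `time` (h) and
#'   `distance` (um from the QC), one row per observation.
#' @export
generate_tracks <- function(config) {
  stopifnot(inherits(config, "synth_track_config"))
  validate_track_config(config)
  cfg <- config
  times <- seq(0, cfg$duration, by = cfg$sampling_interval)
  with_seed(cfg$seed, {
    out <- list()
    for (cond in names(cfg$relative_rate_per_condition)) {
      r <- cfg$relative_rate_per_condition[[cond]]
      x0 <- runif(cfg$n_cells, cfg$start_range[1], cfg$start_range[2])
      for (i in seq_len(cfg$n_cells)) {
        x <- advect(x0[i], times, cfg$velocity_intercept,
                    cfg$velocity_slope, r)
        obs <- x + rnorm(length(times), 0, cfg$track_noise_sd)
        out[[length(out) + 1L]] <- data.frame(
          cell_id = sprintf("%s_cell%03d", cond, i),
          condition = cond,
          time = times,
          distance = pmax(0, obs),
          stringsAsFactors = FALSE
        )
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
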