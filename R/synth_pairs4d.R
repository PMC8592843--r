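#' Configuration for synthetic lineage-tracked (4D) cell pairs
#'
#' Emulates two-time-point lineage-tracked geometry of epidermal cells: each
#' parent cell at time t0 is re-identified (possibly as two daughters) at
#' time t1 = t0 + `dt`. Growth is linear in time per axis; daughters of a
#' divided cell partition the grown length and volume and scatter around the
#' grown depth and width with their means preserved.
#'
#' @param conditions Character vector of condition labels.
#' @param n_cells Number of lineages per condition.
#' @param rates Named list (per condition) of true growth rates
#'   `c(length=, width=, depth=)` in um/h.
#' @param dt Time between the two imaging points, h.
#' @param division_prob Probability that a lineage divides during `dt`.
#' @param noise_sd Named numeric `c(length=, width=, depth=)`, observation
#'   noise on the grown geometry (um).
#' @param d0_range Uniform range of t0 distance from the QC (um).
#' @param displacement_rate Fractional advection per hour used to place the
#'   t1 distance (`d1 = d0 * exp(displacement_rate * dt)`).
#' @param shape_factor Cuboid volume proxy factor in (0, 1].
#' @param seed Integer seed.
#' @return An object of class `synth_pairs4d_config`.
#' @export
synth_pairs4d_config <- function(conditions = c("WT", "bri1", "BL"),
                                 n_cells = 120,
                                 rates = NULL,
                                 dt = 12,
                                 division_prob = 0.25,
                                 noise_sd = c(length = 0.15, width = 0.08,
                                              depth = 0.08),
                                 d0_range = c(4, 60),
                                 displacement_rate = 0.03,
                                 shape_factor = 0.85,
                                 seed = 1L) {
  if (is.null(rates)) {
    rates <- list(WT = c(length = 0.6, width = 0.05, depth = 0.05),
                  bri1 = c(length = 0.35, width = 0.03, depth = 0.08),
                  BL = c(length = 1.4, width = 0.03, depth = 0.05))
    rates <- rates[intersect(conditions, names(rates))]
    for (cond in setdiff(conditions, names(rates))) {
      rates[[cond]] <- c(length = 0.6, width = 0.05, depth = 0.05)
    }
  }
  cfg <- structure(list(
    conditions = conditions, n_cells = n_cells, rates = rates, dt = dt,
    division_prob = division_prob, noise_sd = noise_sd, d0_range = d0_range,
    displacement_rate = displacement_rate, shape_factor = shape_factor,
    seed = as.integer(seed)
  ), class = "synth_pairs4d_config")
  validate_pairs4d_config(cfg)
  cfg
}

validate_pairs4d_config <- function(cfg) {
  check_positive(cfg$dt, "dt")
  if (cfg$n_cells < 1) stop_config("configuration error: n_cells must be >= 1")
  if (cfg$division_prob < 0 || cfg$division_prob > 1) {
    stop_config("configuration error: division_prob must lie in [0, 1]")
  }
  if (any(cfg$noise_sd < 0)) {
    stop_config("configuration error: noise_sd must be >= 0")
  }
  miss <- setdiff(cfg$conditions, names(cfg$rates))
  if (length(miss)) {
    stop_config("configuration error: no rates for %s",
                paste(miss, collapse = ", "))
  }
  invisible(cfg)
}

#' Generate a raw lineage-tracked two-time-point geometry table
#'
#' One row per daughter cell at t1, carrying its parent's t0 geometry. Feed
#' the result to [merge_and_rate()] to apply the division-merging rule and
#' compute per-hour growth rates.
#'
#' @param config A [synth_pairs4d_config()].
#' @return A data frame with columns `pair_id`, `condition`, `tissue`,
#'   `distance_qc_t0`, `distance_qc_t1`, `dt`, t0 geometry
#'   (`length_t0`, `width_t0`, `depth_t0`, `volume_t0`), `daughter_id` and
#'   daughter t1 geometry (`length_t1`, `width_t1`, `depth_t1`,
#'   `volume_t1`).
#' @export
generate_pairs_4d <- function(config) {
  stopifnot(inherits(config, "synth_pairs4d_config"))
  validate_pairs4d_config(config)
  cfg <- config
  sf <- cfg$shape_factor
  with_seed(cfg$seed, {
    out <- list()
    for (cond in cfg$conditions) {
      rt <- cfg$rates[[cond]]
      n <- cfg$n_cells
      d0 <- runif(n, cfg$d0_range[1], cfg$d0_range[2])
      d1 <- d0 * exp(cfg$displacement_rate * cfg$dt)
      L0 <- exp(rnorm(n, log(7.5), 0.2))
      W0 <- exp(rnorm(n, log(9), 0.15))
      D0 <- exp(rnorm(n, log(12), 0.15))
      L1 <- pmax(0.5, L0 + rt[["length"]] * cfg$dt +
                   rnorm(n, 0, cfg$noise_sd[["length"]]))
      W1 <- pmax(0.5, W0 + rt[["width"]] * cfg$dt +
                   rnorm(n, 0, cfg$noise_sd[["width"]]))
      D1 <- pmax(0.5, D0 + rt[["depth"]] * cfg$dt +
                   rnorm(n, 0, cfg$noise_sd[["depth"]]))
      divided <- rbinom(n, 1, cfg$division_prob) == 1
      for (i in seq_len(n)) {
        pid <- sprintf("%s_pair%04d", cond, i)
        base <- data.frame(
          pair_id = pid, condition = cond, tissue = "epidermis_nonhair",
          distance_qc_t0 = d0[i], distance_qc_t1 = d1[i], dt = cfg$dt,
          length_t0 = L0[i], width_t0 = W0[i], depth_t0 = D0[i],
          volume_t0 = sf * L0[i] * W0[i] * D0[i],
          stringsAsFactors = FALSE
        )
        if (divided[i]) {
          u <- runif(1, 0.4, 0.6)
          dd <- rnorm(1, 0, 0.2)
          dw <- rnorm(1, 0, 0.2)
          v1 <- sf * L1[i] * W1[i] * D1[i]
          d_rows <- rbind(
            cbind(base, data.frame(daughter_id = paste0(pid, "_a"),
                                   length_t1 = u * L1[i],
                                   width_t1 = W1[i] + dw,
                                   depth_t1 = D1[i] + dd,
                                   volume_t1 = u * v1)),
            cbind(base, data.frame(daughter_id = paste0(pid, "_b"),
                                   length_t1 = (1 - u) * L1[i],
                                   width_t1 = W1[i] - dw,
                                   depth_t1 = D1[i] - dd,
                                   volume_t1 = (1 - u) * v1))
          )
        } else {
          d_rows <- cbind(base, data.frame(daughter_id = paste0(pid, "_a"),
                                           length_t1 = L1[i],
                                           width_t1 = W1[i],
                                           depth_t1 = D1[i],
                                           volume_t1 = sf * L1[i] * W1[i] *
                                             D1[i]))
        }
        out[[length(out) + 1L]] <- d_rows
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
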