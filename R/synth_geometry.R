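#' Configuration for the synthetic 3D cell-geometry generator
#'
#' Builds the configuration consumed by [generate_geometry_table()]. The
#' generator emulates MorphoGraphX/3D Cell Atlas-style per-cell exports for a
#' root meristem experiment: five concentric tissues, several roots per
#' condition, and per-cell length, width, depth, surface area and volume as a
#' function of distance from the quiescent centre (QC).
#'
#' The statistical structure is the one the downstream analysis assumes:
#'
#' * cell length follows a two-component mixture on the log scale (a short
#'   "meristem" component and a long "elongation-zone" component), with the
#'   probability of the short component decreasing with distance from the QC
#'   (logistic in distance, calibrated so its marginal over the sampled
#'   distances equals `weight_short`);
#' * log-depth and width have per-tissue baselines with linear trends in
#'   `sqrt(distance)`;
#' * conditions act as additive shifts on the transformed scales. Sign
#'   conventions follow the biology: raising brassinosteroid (BR) signalling
#'   (BL treatment) lengthens and thins cells, losing it (`bri1`) shortens
#'   and widens them;
#' * each root contributes a random intercept on each transformed scale
#'   (`root_sd`), on top of per-cell residual noise (`residual_sd`).
#'
#' Volume and surface area are derived from the three axis lengths through a
#' cuboid proxy: `volume = shape_factor * L * W * D` and
#' `surface_area = shape_factor^(2/3) * 2 * (LW + LD + WD)`, with
#' `shape_factor` in (0, 1].
#'
#' @param treatments Character vector of condition labels. The first is the
#'   reference (wild type).
#' @param roots_per_treatment Number of roots (biological replicates) per
#'   condition.
#' @param cells_per_root_per_tissue Number of cells generated per root and
#'   tissue.
#' @param tissues Character vector of the five tissue labels.
#' @param baseline_geometry Data frame with one row per tissue and columns
#'   `tissue`, `len_short`, `len_long` (median lengths of the two mixture
#'   components, um), `depth0`, `width0` (median depth / mean width at the QC,
#'   um), and `len_slope`, `depth_slope`, `width_slope` (trends per
#'   sqrt(um) of distance, on the log scale for length and depth and the raw
#'   scale for width).
#' @param treatment_effects Named list (one entry per treatment) of additive
#'   shifts `list(length=, depth=, width=)` on the transformed scales.
#' @param root_sd Named list of root-level random-intercept standard
#'   deviations for `length`, `depth` (log scale) and `width` (um).
#' @param residual_sd Named list of per-cell residual standard deviations for
#'   `depth` (log scale) and `width` (um); the length residual is the
#'   mixture-component `sd_short`/`sd_long`.
#' @param zone_mixture List with `weight_short` (marginal probability of the
#'   short component, in (0,1)), `sd_short`, `sd_long` (component standard
#'   deviations on the log scale), and `logistic_scale` (um, steepness of the
#'   distance dependence of the short-component probability).
#' @param distance_range Length-2 numeric, the uniform sampling range of
#'   distance from the QC (um).
#' @param shape_factor Cuboid proxy factor in (0, 1].
#' @param seed Integer seed; all draws flow from one seeded generator.
#'
#' @return An object of class `synth_geometry_config`.
#' @seealso [generate_geometry_table()]
#' @export
synth_geometry_config <- function(treatments = c("WT", "bri1", "BL"),
                                  roots_per_treatment = 4,
                                  cells_per_root_per_tissue = 120,
                                  tissues = c("epidermis_nonhair",
                                              "epidermis_hair",
                                              "cortex", "endodermis",
                                              "pericycle"),
                                  baseline_geometry = NULL,
                                  treatment_effects = NULL,
                                  root_sd = list(length = 0.08, depth = 0.08,
                                                 width = 0.6),
                                  residual_sd = list(depth = 0.12,
                                                     width = 0.9),
                                  zone_mixture = list(weight_short = 0.85,
                                                      sd_short = 0.22,
                                                      sd_long = 0.30,
                                                      logistic_scale = 12),
                                  distance_range = c(4, 200),
                                  shape_factor = 0.85,
                                  seed = 1L) {
  if (is.null(baseline_geometry)) {
    baseline_geometry <- data.frame(
      tissue = tissues,
      len_short = c(7.5, 7.0, 8.0, 7.5, 6.0),
      len_long = c(32, 30, 34, 30, 26),
      depth0 = c(12, 11, 14, 10, 7),
      width0 = c(9, 8, 11, 9, 6),
      len_slope = c(0.010, 0.010, 0.010, 0.008, 0.008),
      depth_slope = c(0.020, 0.020, 0.022, 0.015, 0.015),
      width_slope = c(0.15, 0.15, 0.18, 0.12, 0.10)
    )[seq_along(tissues), , drop = FALSE]
    baseline_geometry$tissue <- tissues
  }
  if (is.null(treatment_effects)) {
    eff0 <- list(length = 0, depth = 0, width = 0)
    treatment_effects <- setNames(rep(list(eff0), length(treatments)),
                                  treatments)
    if ("bri1" %in% treatments) {
      treatment_effects[["bri1"]] <- list(length = -0.25, depth = 0.12,
                                          width = 1.5)
    }
    if ("BL" %in% treatments) {
      treatment_effects[["BL"]] <- list(length = 0.30, depth = -0.12,
                                        width = -1.2)
    }
  }
  cfg <- structure(list(
    treatments = treatments,
    roots_per_treatment = roots_per_treatment,
    cells_per_root_per_tissue = cells_per_root_per_tissue,
    tissues = tissues,
    baseline_geometry = baseline_geometry,
    treatment_effects = treatment_effects,
    root_sd = root_sd,
    residual_sd = residual_sd,
    zone_mixture = zone_mixture,
    distance_range = distance_range,
    shape_factor = shape_factor,
    seed = as.integer(seed)
  ), class = "synth_geometry_config")
  validate_geometry_config(cfg)
  cfg
}

validate_geometry_config <- function(cfg) {
  if (cfg$roots_per_treatment < 1 || cfg$cells_per_root_per_tissue < 1) {
    stop_config("configuration error: counts must be positive")
  }
  zm <- cfg$zone_mixture
  if (zm$weight_short <= 0 || zm$weight_short >= 1) {
    stop_config("configuration error: weight_short must lie in (0, 1)")
  }
  check_positive(zm$logistic_scale, "zone_mixture logistic_scale")
  if (any(c(zm$sd_short, zm$sd_long, unlist(cfg$root_sd),
            unlist(cfg$residual_sd)) < 0)) {
    stop_config("configuration error: standard deviations must be >= 0")
  }
  if (cfg$shape_factor <= 0 || cfg$shape_factor > 1) {
    stop_config("configuration error: shape_factor must lie in (0, 1]")
  }
  bg <- cfg$baseline_geometry
  if (!all(cfg$tissues %in% bg$tissue)) {
    stop_config("configuration error: baseline_geometry missing tissues")
  }
  check_positive(unlist(bg[c("len_short", "len_long", "depth0", "width0")]),
                 "baseline medians")
  if (any(bg$len_short >= bg$len_long)) {
    stop_config("configuration error: short component must be shorter than long")
  }
  miss <- setdiff(cfg$treatments, names(cfg$treatment_effects))
  if (length(miss)) {
    stop_config("configuration error: no treatment effect for %s",
                paste(miss, collapse = ", "))
  }
  invisible(cfg)
}

# Midpoint of the logistic P(short | distance) solved so that the marginal
# short-component weight over distance ~ U(distance_range) equals w.
logistic_mid_for_weight <- function(w, scale, range) {
  marg <- function(m) {
    f <- function(d) plogis((m - d) / scale)
    stats::integrate(f, range[1], range[2])$value / diff(range) - w
  }
  lo <- range[1] - 20 * scale
  hi <- range[2] + 20 * scale
  uniroot(marg, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic per-cell 3D geometry table
#'
#' Draws one row per segmented cell according to a
#' [synth_geometry_config()]. Deterministic for a fixed config and seed. The
#' hidden column `true_zone` records the mixture component each cell's length
#' was drawn from, for validating the zone classifier.
#'
#' @param config A [synth_geometry_config()].
#' @return A data frame with columns `cell_id`, `root_id`, `treatment`,
#'   `tissue`, `distance_qc`, `length`, `width`, `depth`, `surface_area`,
#'   `volume` and `true_zone` (`"meristem"` or `"elongation"`).
#' @export
generate_geometry_table <- function(config) {
  stopifnot(inherits(config, "synth_geometry_config"))
  validate_geometry_config(config)
  cfg <- config
  zm <- cfg$zone_mixture
  mid <- logistic_mid_for_weight(zm$weight_short, zm$logistic_scale,
                                 cfg$distance_range)
  bg <- cfg$baseline_geometry
  rownames(bg) <- bg$tissue

  with_seed(cfg$seed, {
    out <- vector("list",
                  length(cfg$treatments) * cfg$roots_per_treatment *
                    length(cfg$tissues))
    i <- 0L
    cell0 <- 0L
    for (tr in cfg$treatments) {
      eff <- cfg$treatment_effects[[tr]]
      for (r in seq_len(cfg$roots_per_treatment)) {
        root_id <- sprintf("%s_root%02d", tr, r)
        u_len <- rnorm(1, 0, cfg$root_sd$length)
        u_dep <- rnorm(1, 0, cfg$root_sd$depth)
        u_wid <- rnorm(1, 0, cfg$root_sd$width)
        for (ti in cfg$tissues) {
          n <- cfg$cells_per_root_per_tissue
          b <- bg[ti, ]
          d <- runif(n, cfg$distance_range[1], cfg$distance_range[2])
          sq <- sqrt(d)
          p_short <- plogis((mid - d) / zm$logistic_scale)
          short <- rbinom(n, 1, p_short) == 1
          mu_len <- ifelse(short, log(b$len_short), log(b$len_long)) +
            b$len_slope * sq + eff$length + u_len
          sd_len <- ifelse(short, zm$sd_short, zm$sd_long)
          len <- exp(rnorm(n, mu_len, sd_len))
          dep <- exp(rnorm(n, log(b$depth0) + b$depth_slope * sq +
                             eff$depth + u_dep, cfg$residual_sd$depth))
          wid <- pmax(0.5, rnorm(n, b$width0 + b$width_slope * sq +
                                   eff$width + u_wid, cfg$residual_sd$width))
          vol <- cfg$shape_factor * len * wid * dep
          sa <- cfg$shape_factor^(2 / 3) *
            2 * (len * wid + len * dep + wid * dep)
          i <- i + 1L
          out[[i]] <- data.frame(
            cell_id = sprintf("cell%06d", cell0 + seq_len(n)),
            root_id = root_id,
            treatment = tr,
            tissue = ti,
            distance_qc = d,
            length = len,
            width = wid,
            depth = dep,
            surface_area = sa,
            volume = vol,
            true_zone = ifelse(short, "meristem", "elongation"),
            stringsAsFactors = FALSE
          )
          cell0 <- cell0 + n
        }
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
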