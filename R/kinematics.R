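#' Fit displacement-rate regressions from time-lapse tracks
#'
#' For every condition, computes each cell's displacement rate by endpoint
#' differencing over the full imaging window,
#' `rate = (x(T) - x(0)) / T`, and regresses the rate on the starting
#' distance from the QC. Because cells accelerate while moving through a
#' velocity field `v(x) = a + b x`, the endpoint-rate slope `s`
#' overestimates `b`; the fit converts it back exactly via
#' `b = log(1 + T s) / T` (and `a = b * intercept / s`), so the reported
#' `slope` and `intercept` describe the instantaneous velocity field.
#' Relative rates versus the reference condition are ratios of the fitted
#' slopes (the fold applies to the whole field, so slope ratios estimate
#' it directly).
#'
#' @param tracks Data frame with `cell_id`, `condition`, `time` (h) and
#'   `distance` (um) columns, e.g. from [generate_tracks()].
#' @param reference Condition used as the denominator of relative rates
#'   (default `"WT"` when present).
#' @param min_r2 R-squared below which a warning is issued (the field
#'   convention requires a good linear fit, R^2 > 0.9).
#' @return A named list of `kinematics_fit` objects (one per condition),
#'   each with `intercept` (um/h), `slope` (1/h), `endpoint_intercept`,
#'   `endpoint_slope`, `r_squared`, `window` (h), `n`, `condition` and
#'   `relative_rate` (fold vs the reference; `NA` if no reference).
#' @export
fit_displacement <- function(tracks, reference = "WT", min_r2 = 0.9) {
  need <- c("cell_id", "condition", "time", "distance")
  if (!all(need %in% names(tracks))) {
    stop("tracks must have cell_id, condition, time, distance columns",
         call. = FALSE)
  }
  fits <- list()
  for (cond in unique(tracks$condition)) {
    tr <- tracks[tracks$condition == cond, , drop = FALSE]
    spl <- split(tr, tr$cell_id)
    if (length(spl) < 3) {
      stop(sprintf("condition %s: need at least 3 cells", cond),
           call. = FALSE)
    }
    ends <- t(vapply(spl, function(d) {
      d <- d[order(d$time), ]
      c(x0 = d$distance[1], x1 = d$distance[nrow(d)],
        T = d$time[nrow(d)] - d$time[1])
    }, numeric(3)))
    if (any(ends[, "T"] <= 0)) {
      stop("each track needs a positive time span", call. = FALSE)
    }
    if (length(unique(round(ends[, "x0"], 6))) < 2) {
      stop(sprintf("condition %s: need at least 2 distinct start positions",
                   cond), call. = FALSE)
    }
    if (diff(range(ends[, "x0"])) < 30) {
      warning(sprintf("condition %s: start positions span < 30 um", cond),
              call. = FALSE)
    }
    rate <- (ends[, "x1"] - ends[, "x0"]) / ends[, "T"]
    reg <- lm(rate ~ ends[, "x0"])
    s <- as.numeric(coef(reg)[2])
    c0 <- as.numeric(coef(reg)[1])
    r2 <- summary(reg)$r.squared
    T <- mean(ends[, "T"])
    if (1 + T * s <= 0) {
      stop(sprintf("condition %s: endpoint slope implies negative velocity",
                   cond), call. = FALSE)
    }
    b <- log(1 + T * s) / T
    a <- if (abs(s) < 1e-12) c0 else b * c0 / s
    if (is.finite(r2) && r2 <= min_r2) {
      warning(sprintf("condition %s: displacement regression R^2 = %.3f <= %.2f",
                      cond, r2, min_r2), call. = FALSE)
    }
    fits[[cond]] <- structure(list(
      condition = cond, intercept = a, slope = b,
      endpoint_intercept = c0, endpoint_slope = s,
      r_squared = r2, window = T, n = length(spl),
      relative_rate = NA_real_
    ), class = "kinematics_fit")
  }
  if (reference %in% names(fits)) {
    ref <- fits[[reference]]
    for (cond in names(fits)) {
      f <- fits[[cond]]
      fits[[cond]]$relative_rate <- if (abs(ref$slope) > 1e-12) {
        f$slope / ref$slope
      } else if (abs(ref$intercept) > 1e-12) {
        f$intercept / ref$intercept
      } else NA_real_
    }
  }
  fits
}

#' @export
print.kinematics_fit <- function(x, ...) {
  cat(sprintf("Kinematics fit [%s]: v(x) = %.4f + %.5f x um/h (R^2 = %.3f, n = %d)\n",
              x$condition, x$intercept, x$slope, x$r_squared, x$n))
  if (!is.na(x$relative_rate)) {
    cat(sprintf("  relative displacement rate vs reference: %.3f-fold\n",
                x$relative_rate))
  }
  invisible(x)
}

#' Meristem residence time from a fitted velocity field
#'
#' Time for a cell to travel from `x0` to `x1` through
#' `v(x) = a + b x`: `(1/b) log((a + b x1)/(a + b x0))`, with the limits
#' `log(x1/x0)/b` as `a -> 0` and `(x1 - x0)/a` as `b -> 0`. By default the
#' velocity line is forced through the origin (`a = 0`), i.e. the linear
#' displacement-rate increase is anchored at the QC.
#'
#' @param fit A `kinematics_fit`, or a numeric slope `b` (1/h).
#' @param x0,x1 Interval of distances from the QC (um); defaults 8 and 100
#'   um (the working definition of the meristem span).
#' @param zero_intercept Force `a = 0` (default `TRUE`).
#' @return Residence time in hours.
#' @export
residence_time <- function(fit, x0 = 8, x1 = 100, zero_intercept = TRUE) {
  if (inherits(fit, "kinematics_fit")) {
    a <- if (zero_intercept) 0 else fit$intercept
    b <- fit$slope
  } else {
    b <- as.numeric(fit)
    a <- if (zero_intercept) 0 else attr(fit, "intercept")
    if (is.null(a)) a <- 0
  }
  if (x1 <= x0) stop("value error: x1 must exceed x0", call. = FALSE)
  if (min(a + b * x0, a + b * x1) <= 0) {
    stop("value error: velocity must be positive on [x0, x1]",
         call. = FALSE)
  }
  if (abs(b) < 1e-14) return((x1 - x0) / a)
  log((a + b * x1) / (a + b * x0)) / b
}

#' Relative displacement rate from cell-production bookkeeping
#'
#' For genotypes without live imaging, the relative change in cell
#' displacement rate is derived from whole-root bookkeeping: the cell
#' production rate is the daily root elongation divided by the mature cell
#' length; the length flux leaving the meristem per day is that rate times
#' the mean meristematic cell length; the meristem residence time is the
#' meristem length (cell number x mean cell length) divided by the flux;
#' and the relative rate is the reference residence time divided by the
#' genotype's.
#'
#' @param genotype,reference Lists/named vectors with fields
#'   `root_elongation_day` (um/day), `mature_cell_length` (um),
#'   `mean_meristem_cell_length` (um) and `meristem_cell_number`.
#' @return Unitless fold-change of displacement rate versus the reference.
#' @export
relative_rate_from_production <- function(genotype, reference) {
  res_time <- function(p) {
    p <- as.list(p)
    check_positive(unlist(p[c("root_elongation_day", "mature_cell_length",
                              "mean_meristem_cell_length",
                              "meristem_cell_number")]),
                   "production inputs")
    cells_day <- p$root_elongation_day / p$mature_cell_length
    flux <- cells_day * p$mean_meristem_cell_length
    if (flux <= 0) stop("value error: zero flux", call. = FALSE)
    meristem_len <- p$meristem_cell_number * p$mean_meristem_cell_length
    meristem_len / flux
  }
  res_time(reference) / res_time(genotype)
}
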