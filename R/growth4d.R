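#' Merge daughters and compute per-hour growth rates for 4D pairs
#'
#' Applies the division-merging rule to a raw lineage-tracked table (one
#' row per daughter): for a divided cell the daughters' lengths and volumes
#' are summed while their depths and widths are averaged. Per-hour rates
#' are the merged t1 geometry minus the t0 geometry divided by the imaging
#' duration. A 4D anisotropy rate is also reported as the per-hour change
#' of the shape anisotropy index (`length^2/(depth*width)`) between t0 and
#' the merged t1.
#'
#' @param raw Data frame from [generate_pairs_4d()] (or equivalent) with
#'   one row per daughter.
#' @return Data frame with one row per lineage: `pair_id`, `condition`,
#'   `tissue`, `distance_qc_t0`, `distance_qc_t1`, `dt`, `n_daughters`, the
#'   t0 and merged t1 geometry, per-hour rates `rate_length`, `rate_width`,
#'   `rate_depth` (um/h), `rate_volume` (um^3/h) and `rate_anisotropy`
#'   (1/h). Rows with missing daughter geometry are rejected and reported
#'   in the `rejected` attribute.
#' @export
merge_and_rate <- function(raw) {
  need <- c("pair_id", "condition", "dt", "length_t0", "width_t0",
            "depth_t0", "volume_t0", "length_t1", "width_t1", "depth_t1",
            "volume_t1")
  if (!all(need %in% names(raw))) {
    stop(sprintf("missing columns: %s",
                 paste(setdiff(need, names(raw)), collapse = ", ")),
         call. = FALSE)
  }
  bad <- !stats::complete.cases(raw[, c("length_t1", "width_t1",
                                        "depth_t1", "volume_t1")])
  rejected <- raw[bad, , drop = FALSE]
  if (nrow(rejected)) {
    warning(sprintf("%d daughter rows with unresolved geometry rejected",
                    nrow(rejected)), call. = FALSE)
  }
  raw <- raw[!bad, , drop = FALSE]
  spl <- split(raw, raw$pair_id)
  out <- lapply(spl, function(d) {
    if (any(d$dt <= 0)) stop("value error: dt must be positive",
                             call. = FALSE)
    dt <- d$dt[1]
    L1 <- sum(d$length_t1); V1 <- sum(d$volume_t1)
    W1 <- mean(d$width_t1); D1 <- mean(d$depth_t1)
    a0 <- anisotropy_index(d$length_t0[1], d$depth_t0[1], d$width_t0[1])
    a1 <- anisotropy_index(L1, D1, W1)
    data.frame(
      pair_id = d$pair_id[1], condition = d$condition[1],
      tissue = if ("tissue" %in% names(d)) d$tissue[1] else NA_character_,
      distance_qc_t0 = if ("distance_qc_t0" %in% names(d))
        d$distance_qc_t0[1] else NA_real_,
      distance_qc_t1 = if ("distance_qc_t1" %in% names(d))
        d$distance_qc_t1[1] else NA_real_,
      dt = dt, n_daughters = nrow(d),
      length_t0 = d$length_t0[1], width_t0 = d$width_t0[1],
      depth_t0 = d$depth_t0[1], volume_t0 = d$volume_t0[1],
      length_t1 = L1, width_t1 = W1, depth_t1 = D1, volume_t1 = V1,
      rate_length = (L1 - d$length_t0[1]) / dt,
      rate_width = (W1 - d$width_t0[1]) / dt,
      rate_depth = (D1 - d$depth_t0[1]) / dt,
      rate_volume = (V1 - d$volume_t0[1]) / dt,
      rate_anisotropy = (a1 - a0) / dt,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rejected") <- rejected
  res
}

#' Restrict 4D pairs to the meristem observation window
#'
#' Keeps lineages located within `d0_max` um of the QC at the first time
#' point and within `d1_max` um at the second, ensuring cells stayed in the
#' meristem throughout the experiment.
#'
#' @param pairs Data frame from [merge_and_rate()].
#' @param d0_max,d1_max Window bounds (um); defaults 60 and 100.
#' @return Filtered data frame; the number of removed rows is reported in
#'   the `n_removed` attribute.
#' @export
filter_meristem_window <- function(pairs, d0_max = 60, d1_max = 100) {
  need <- c("distance_qc_t0", "distance_qc_t1")
  if (!all(need %in% names(pairs))) {
    stop("pairs must carry distances at both time points", call. = FALSE)
  }
  keep <- pairs$distance_qc_t0 <= d0_max & pairs$distance_qc_t1 <= d1_max
  res <- pairs[keep, , drop = FALSE]
  attr(res, "n_removed") <- sum(!keep)
  res
}

#' ANCOVA of 4D growth rates with position as covariate
#'
#' Models a per-hour growth rate as a function of condition and t0 distance
#' from the QC. The fit starts from the interaction model
#' `rate ~ condition * distance`; when the interaction is removable (its
#' F-test p-value is at or above `alpha_interaction`) the additive model is
#' used. Pairwise condition contrasts are evaluated at the mean distance
#' with Benjamini-Hochberg adjustment across the contrast family.
#'
#' @param pairs Data frame from [merge_and_rate()] (usually windowed by
#'   [filter_meristem_window()]).
#' @param parameter One of `"length"`, `"width"`, `"depth"`, `"volume"`,
#'   `"anisotropy"`.
#' @param alpha_interaction Threshold for removing the interaction.
#' @return Object of class `ancova_result`: list with `parameter`, `form`
#'   (`"interaction"` or `"additive"`), `fit`, `interaction_p`,
#'   `coefficients` and `contrasts` (data frame with `pair`, `estimate`,
#'   `se`, `p_raw`, `p_adjusted`).
#' @export
ancova_rates <- function(pairs, parameter,
                         alpha_interaction = 0.05) {
  col <- paste0("rate_", parameter)
  if (!col %in% names(pairs)) {
    stop(sprintf("no column %s in pairs", col), call. = FALSE)
  }
  dat <- data.frame(rate = pairs[[col]],
                    condition = factor(pairs$condition),
                    distance = pairs$distance_qc_t0)
  if (sd(dat$distance) < 1e-12) {
    stop("model error: distance covariate does not vary", call. = FALSE)
  }
  if (nlevels(dat$condition) < 2) {
    fit <- lm(rate ~ distance, data = dat)
    return(structure(list(parameter = parameter, form = "single-condition",
                          fit = fit, interaction_p = NA_real_,
                          coefficients = coef(fit), contrasts = NULL),
                     class = "ancova_result"))
  }
  fit_int <- lm(rate ~ condition * distance, data = dat)
  fit_add <- lm(rate ~ condition + distance, data = dat)
  if (any(!is.finite(coef(fit_add)))) {
    stop("model error: collinear design", call. = FALSE)
  }
  cmp <- anova(fit_add, fit_int)
  p_int <- cmp[["Pr(>F)"]][2]
  if (is.na(p_int)) p_int <- 1
  keep_interaction <- p_int < alpha_interaction
  fit <- if (keep_interaction) fit_int else fit_add
  emm <- emmeans::emmeans(fit, "condition",
                          at = list(distance = mean(dat$distance)))
  ctr_raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                             adjust = "none"))
  ctr_adj <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                             adjust = "BH"))
  contrasts <- data.frame(
    pair = as.character(ctr_raw$contrast),
    estimate = ctr_raw$estimate,
    se = ctr_raw$SE,
    p_raw = ctr_raw$p.value,
    p_adjusted = ctr_adj$p.value,
    stringsAsFactors = FALSE
  )
  structure(list(parameter = parameter,
                 form = if (keep_interaction) "interaction" else "additive",
                 fit = fit, interaction_p = p_int,
                 coefficients = coef(fit), contrasts = contrasts),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA of rate_%s: %s model (interaction p = %.3g)\n",
              x$parameter, x$form, x$interaction_p))
  if (!is.null(x$contrasts)) {
    print(x$contrasts, digits = 3)
  }
  invisible(x)
}

#' Count cell divisions per distance bin
#'
#' A lineage divided when it resolves to two or more daughters. Counts are
#' binned by t0 distance from the QC.
#'
#' @param pairs Data frame from [merge_and_rate()].
#' @param breaks Numeric bin boundaries (um) passed to `cut`; default
#'   20-um bins covering the observed range.
#' @return Table of division counts per bin; total in attribute `total`.
#' @export
count_divisions <- function(pairs, breaks = NULL) {
  if (!"n_daughters" %in% names(pairs)) {
    stop("pairs must carry n_daughters", call. = FALSE)
  }
  div <- pairs$n_daughters >= 2
  if (is.null(breaks)) {
    top <- max(pairs$distance_qc_t0, 20)
    breaks <- seq(0, ceiling(top / 20) * 20, by = 20)
  }
  bins <- cut(pairs$distance_qc_t0, breaks = breaks, include.lowest = TRUE)
  counts <- table(bin = bins[div])
  attr(counts, "total") <- sum(div)
  counts
}
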