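#' Transformation specification for geometry parameters
#'
#' Names the variance-stabilizing transform applied to each geometric
#' parameter before modelling, and the transform of distance from the QC.
#' Defaults: log for depth and length, identity for width, square root for
#' surface area, cube root for volume, square root for distance.
#'
#' @param length,depth,width,surface_area,volume One of `"log"`, `"sqrt"`,
#'   `"cbrt"`, `"identity"`.
#' @param distance Transform for `distance_qc` (default `"sqrt"`).
#' @return Named list of class `transform_spec`.
#' @export
transform_spec <- function(length = "log", depth = "log",
                           width = "identity", surface_area = "sqrt",
                           volume = "cbrt", distance = "sqrt") {
  spec <- list(length = length, depth = depth, width = width,
               surface_area = surface_area, volume = volume,
               distance = distance)
  ok <- c("log", "sqrt", "cbrt", "identity")
  bad <- !vapply(spec, function(s) s %in% ok, logical(1))
  if (any(bad)) {
    stop_config("unknown transform: %s",
                paste(unlist(spec[bad]), collapse = ", "))
  }
  structure(spec, class = "transform_spec")
}

transform_fun <- function(name) {
  switch(name,
         log = log,
         sqrt = sqrt,
         cbrt = function(x) x^(1 / 3),
         identity = identity)
}

inverse_fun <- function(name) {
  switch(name,
         log = exp,
         sqrt = function(x) x^2,
         cbrt = function(x) x^3,
         identity = identity)
}

#' Apply variance-stabilizing transforms to a geometry table
#'
#' Adds a `<parameter>_t` column for every parameter the transform spec
#' names that is present in the table, and `distance_qc_t` for distance.
#' All transforms are invertible on the positive reals; non-positive values
#' under `log`/`sqrt`/`cbrt` raise an error naming the offending rows.
#'
#' @param cells Data frame of cell records.
#' @param spec A [transform_spec()].
#' @return `cells` with transformed columns added.
#' @export
apply_transform <- function(cells, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"))
  for (p in setdiff(names(spec), "distance")) {
    if (!p %in% names(cells)) next
    x <- cells[[p]]
    if (spec[[p]] != "identity" && any(x <= 0)) {
      bad <- which(x <= 0)
      stop(sprintf("value error: non-positive %s in rows %s", p,
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    cells[[paste0(p, "_t")]] <- transform_fun(spec[[p]])(x)
  }
  if ("distance_qc" %in% names(cells)) {
    if (any(cells$distance_qc < 0)) {
      stop("value error: negative distance_qc", call. = FALSE)
    }
    cells$distance_qc_t <- transform_fun(spec$distance)(cells$distance_qc)
  }
  cells
}

#' Shape anisotropy index
#'
#' `length^2 / (depth * width)`; values above 1 indicate
#' elongation-dominated shape, below 1 radially dominated shape.
#'
#' @param length,depth,width Cell axis sizes (um); depth and width must be
#'   positive.
#' @return Unitless numeric.
#' @export
anisotropy_index <- function(length, depth, width) {
  if (any(depth * width <= 0)) {
    stop("value error: depth and width must be positive", call. = FALSE)
  }
  length^2 / (depth * width)
}

#' Fit the random-intercept mixed model for one geometry parameter
#'
#' REML fit of `transformed parameter ~ treatment + transformed distance`
#' with a random intercept per root, within one tissue, on meristem cells.
#' This is the per-tissue, per-parameter model underlying the treatment
#' comparisons: treatment and distance from the QC are fixed effects and
#' the individual root is the random (replicate) effect.
#'
#' When every observation is its own root the random intercept is not
#' identifiable; the fit then falls back to ordinary least squares with the
#' random variance reported as zero (with a warning). A singular REML fit
#' (random variance estimated at zero) is retained, with a warning.
#'
#' @param cells Data frame with `treatment`, `root_id`, `distance_qc` and
#'   the geometry columns; typically already zone-classified.
#' @param parameter One of `"length"`, `"depth"`, `"width"`,
#'   `"surface_area"`, `"volume"`.
#' @param tissue Optional tissue label to subset to.
#' @param spec A [transform_spec()].
#' @param meristem_only If `TRUE` (default) and a `zone` column is present,
#'   restrict to `zone == "meristem"` before fitting.
#' @param reference Treatment level used as the reference (default the
#'   wild type, `"WT"`, when present).
#' @return An object of class `geometry_mixed_fit`: list with the fitted
#'   model (`fit`), `coefficients`, `varcomp` (fixed / random / residual
#'   variances), `anova` (per-term sums of squares and Satterthwaite
#'   F-tests), `term_p`, `model_p` (the treatment-term p-value),
#'   `parameter`, `tissue`, `n`, `n_roots` and `ols_fallback`.
#' @export
fit_mixed_model <- function(cells, parameter, tissue = NULL,
                            spec = transform_spec(),
                            meristem_only = TRUE, reference = "WT") {
  stopifnot(parameter %in% setdiff(names(spec), "distance"))
  dat <- cells
  if (!is.null(tissue)) dat <- dat[dat$tissue == tissue, , drop = FALSE]
  if (meristem_only && "zone" %in% names(dat)) {
    dat <- dat[!is.na(dat$zone) & dat$zone == "meristem", , drop = FALSE]
  }
  dat <- apply_transform(dat, spec)
  dat$.y <- dat[[paste0(parameter, "_t")]]
  dat$treatment <- factor(dat$treatment)
  if (reference %in% levels(dat$treatment)) {
    dat$treatment <- stats::relevel(dat$treatment, ref = reference)
  }
  dat$root_id <- factor(dat$root_id)
  per_root <- table(dat$treatment, dat$root_id)
  n_roots <- nlevels(dat$root_id)
  if (any(rowSums(per_root > 0) < 2)) {
    warning("fewer than 2 roots in some treatment", call. = FALSE)
  }

  ols_fallback <- n_roots >= nrow(dat)
  if (ols_fallback) {
    warning("one observation per root: random intercept not identifiable; ",
            "falling back to OLS with zero random variance", call. = FALSE)
    fit <- lm(.y ~ treatment + distance_qc_t, data = dat)
    an <- anova(fit)
    pv <- an[c("treatment", "distance_qc_t"), "Pr(>F)"]
    var_rand <- 0
    var_res <- sigma(fit)^2
    beta <- coef(fit)
    X <- model.matrix(fit)
  } else {
    fit <- lmerTest::lmer(.y ~ treatment + distance_qc_t + (1 | root_id),
                          data = dat, REML = TRUE)
    if (lme4::isSingular(fit, tol = 1e-6)) {
      warning("singular fit: random-intercept variance estimated at zero",
              call. = FALSE)
    }
    an <- stats::anova(fit, type = 2)
    pv <- an[c("treatment", "distance_qc_t"), "Pr(>F)"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_rand <- vc$vcov[vc$grp == "root_id"]
    var_res <- vc$vcov[vc$grp == "Residual"]
    beta <- lme4::fixef(fit)
    X <- model.matrix(fit)
  }
  eta <- as.numeric(X %*% beta)
  var_fixed <- sum((eta - mean(eta))^2) / length(eta)
  # term-wise share of the fixed-effect variance, from the centred
  # components of the fixed linear predictor (treatment and distance are
  # orthogonal by design, so these sums of squares partition the fixed SS)
  term_ss <- function(cols) {
    if (!length(cols)) return(0)
    comp <- as.numeric(X[, cols, drop = FALSE] %*% beta[cols])
    sum((comp - mean(comp))^2)
  }
  ss <- c(term_ss(grep("^treatment", colnames(X))),
          term_ss(which(colnames(X) == "distance_qc_t")))
  structure(list(
    fit = fit,
    coefficients = beta,
    varcomp = c(fixed = var_fixed, random = as.numeric(var_rand),
                residual = as.numeric(var_res)),
    anova = an,
    ss = setNames(as.numeric(ss), c("treatment", "distance")),
    term_p = setNames(as.numeric(pv), c("treatment", "distance")),
    model_p = as.numeric(pv[1]),
    parameter = parameter, tissue = tissue,
    n = nrow(dat), n_roots = n_roots,
    ols_fallback = ols_fallback,
    data = dat
  ), class = "geometry_mixed_fit")
}

#' @export
print.geometry_mixed_fit <- function(x, ...) {
  cat(sprintf("Mixed model: %s%s, n = %d cells / %d roots%s\n",
              x$parameter,
              if (is.null(x$tissue)) "" else paste0(" in ", x$tissue),
              x$n, x$n_roots,
              if (x$ols_fallback) " (OLS fallback)" else ""))
  cat(sprintf("  variance: fixed %.4g, random(root) %.4g, residual %.4g\n",
              x$varcomp["fixed"], x$varcomp["random"],
              x$varcomp["residual"]))
  cat(sprintf("  treatment p = %.3g, distance p = %.3g\n",
              x$term_p["treatment"], x$term_p["distance"]))
  invisible(x)
}

#' Tukey-type pairwise treatment comparisons for a mixed fit
#'
#' All pairwise treatment contrasts from the fitted covariance, with
#' single-step (max-|t|) adjusted p-values as in the Tukey procedure,
#' computed with `multcomp::glht`. Contrasts are evaluated with distance
#' held at its covariate value (the model is additive, so the contrast does
#' not depend on it).
#'
#' @param fit A [fit_mixed_model()] result.
#' @return Data frame of class `geometry_posthoc` with columns `tissue`,
#'   `parameter`, `pair`, `estimate` (transformed scale), `se`, `p_raw`,
#'   `p_single_step` and `pct_variance_br`.
#' @export
posthoc_pairwise <- function(fit) {
  stopifnot(inherits(fit, "geometry_mixed_fit"))
  model <- fit$fit
  glht_fit <- multcomp::glht(model,
                             linfct = multcomp::mcp(treatment = "Tukey"))
  ss <- summary(glht_fit, test = multcomp::adjusted("single-step"))
  raw <- summary(glht_fit, test = multcomp::adjusted("none"))
  est <- as.numeric(ss$test$coefficients)
  res <- data.frame(
    tissue = if (is.null(fit$tissue)) NA_character_ else fit$tissue,
    parameter = fit$parameter,
    pair = unname(names(ss$test$coefficients)),
    estimate = unname(est),
    se = unname(as.numeric(ss$test$sigma)),
    p_raw = as.numeric(raw$test$pvalues),
    p_single_step = as.numeric(ss$test$pvalues),
    pct_variance_br = pct_variance_br(fit),
    stringsAsFactors = FALSE
  )
  class(res) <- c("geometry_posthoc", "data.frame")
  res
}

#' Benjamini-Hochberg rejections at a given level
#'
#' Step-up BH procedure expressed through `p.adjust`; returns the logical
#' rejection flags at level `alpha`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return Logical vector, `TRUE` where rejected.
#' @export
bh_reject <- function(p, alpha) {
  if (length(p) == 0) return(logical(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH") <= alpha
}

#' Two-step adaptive FDR correction across models and post-hoc tests
#'
#' Stage 1 applies Benjamini-Hochberg at level `alpha` to the M model
#' p-values (one per tissue x parameter model). With m1 stage-1 discoveries,
#' stage 2 applies Benjamini-Hochberg at the adaptive level
#' `alpha * m1 / M` to the pooled post-hoc p-values of the surviving
#' models. The procedure keeps the overall false discovery rate at `alpha`.
#'
#' @param model_pvalues Numeric vector of M model p-values.
#' @param posthoc_pvalues List of length M; element i holds the post-hoc
#'   p-values of model i (may be `NULL`).
#' @param alpha Overall FDR level (default 0.05).
#' @return List with `stage1_significant` (logical, length M),
#'   `stage2_significant` (list parallel to `posthoc_pvalues`; `NULL` for
#'   non-surviving models), `m1`, `M` and `stage2_alpha`
#'   (`alpha * m1 / M`; 0 when nothing survives stage 1).
#' @export
two_step_adaptive_fdr <- function(model_pvalues, posthoc_pvalues = NULL,
                                  alpha = 0.05) {
  p <- as.numeric(model_pvalues)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  M <- length(p)
  stage1 <- bh_reject(p, alpha)
  m1 <- sum(stage1)
  stage2_alpha <- if (m1 == 0) 0 else alpha * m1 / M
  stage2 <- NULL
  if (!is.null(posthoc_pvalues)) {
    stopifnot(length(posthoc_pvalues) == M)
    stage2 <- vector("list", M)
    if (m1 > 0) {
      surv <- which(stage1)
      pooled <- unlist(posthoc_pvalues[surv], use.names = FALSE)
      if (length(pooled)) {
        flags <- bh_reject(pooled, stage2_alpha)
        off <- 0L
        for (i in surv) {
          k <- length(posthoc_pvalues[[i]])
          if (k > 0) stage2[[i]] <- flags[off + seq_len(k)]
          off <- off + k
        }
      }
    }
  }
  list(stage1_significant = stage1, stage2_significant = stage2,
       m1 = m1, M = M, stage2_alpha = stage2_alpha)
}

#' Percent of variance explained by the BR conditions
#'
#' Decomposes the model variance into fixed, random (root) and residual
#' components; the fixed share (variance of the fixed-effect linear
#' predictor over the observations divided by the total) is then multiplied
#' by the treatment's proportion of the fixed-term sums of squares,
#' `SS_treatment / (SS_treatment + SS_distance)`, and expressed in percent.
#'
#' @param fit A [fit_mixed_model()] result.
#' @return Percent in `[0, 100]`.
#' @export
pct_variance_br <- function(fit) {
  stopifnot(inherits(fit, "geometry_mixed_fit"))
  vc <- fit$varcomp
  total <- sum(vc)
  if (total <= 0) stop("value error: zero total variance", call. = FALSE)
  ss <- fit$ss
  denom <- sum(ss)
  if (denom <= 0) return(0)
  as.numeric(100 * (vc[["fixed"]] / total) * (ss[["treatment"]] / denom))
}

#' Run the full 3D geometry statistics stage over tissues and parameters
#'
#' Fits the mixed model per tissue x parameter, runs Tukey post-hoc
#' comparisons, applies the two-step adaptive FDR across all models and
#' attaches the percent variance explained by treatment.
#'
#' @param cells Zone-classified geometry table.
#' @param parameters Geometry parameters to analyse.
#' @param tissues Tissues to analyse (default: all in the table).
#' @param spec A [transform_spec()].
#' @param alpha Overall FDR level.
#' @return List with `models` (per-stratum fits), `comparisons` (combined
#'   post-hoc data frame with `significant` flags), `fdr` (the two-step
#'   correction result) and `stage2_alpha`.
#' @export
geometry_stats_pipeline <- function(cells,
                                    parameters = c("length", "depth",
                                                   "width", "surface_area",
                                                   "volume"),
                                    tissues = NULL,
                                    spec = transform_spec(),
                                    alpha = 0.05) {
  if (is.null(tissues)) tissues <- unique(cells$tissue)
  models <- list()
  comparisons <- list()
  for (ti in tissues) {
    for (p in parameters) {
      key <- paste(ti, p, sep = ":")
      fit <- fit_mixed_model(cells, p, tissue = ti, spec = spec)
      models[[key]] <- fit
      comparisons[[key]] <- posthoc_pairwise(fit)
    }
  }
  model_p <- vapply(models, function(m) m$model_p, numeric(1))
  posthoc_p <- lapply(comparisons, function(cmp) cmp$p_single_step)
  fdr <- two_step_adaptive_fdr(model_p, posthoc_p, alpha = alpha)
  for (i in seq_along(comparisons)) {
    flags <- fdr$stage2_significant[[i]]
    comparisons[[i]]$significant <-
      if (is.null(flags)) rep(FALSE, nrow(comparisons[[i]])) else flags
  }
  out <- do.call(rbind, comparisons)
  rownames(out) <- NULL
  list(models = models, comparisons = out, fdr = fdr,
       stage2_alpha = fdr$stage2_alpha)
}
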