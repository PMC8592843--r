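test_that("transforms are exact and invertible", {
  tab <- data.frame(volume = 27, surface_area = 49, length = exp(2),
                    depth = 3, width = 2, distance_qc = 16)
  out <- apply_transform(tab)
  expect_equal(out$volume_t, 3)
  expect_equal(out$surface_area_t, 7)
  expect_equal(out$length_t, 2)
  expect_equal(out$distance_qc_t, 4)
  # round trip
  expect_equal(out$volume_t^3, tab$volume, tolerance = 1e-10)
  expect_equal(out$surface_area_t^2, tab$surface_area, tolerance = 1e-10)
  expect_equal(exp(out$length_t), tab$length, tolerance = 1e-10)
  bad <- data.frame(volume = c(8, -1), distance_qc = c(1, 2))
  expect_error(apply_transform(bad), "non-positive volume")
})

test_that("anisotropy index is length^2 over depth x width", {
  expect_equal(anisotropy_index(1, 1, 1), 1)
  expect_equal(anisotropy_index(2, 1, 1), 4)
  expect_equal(anisotropy_index(3, 2, 1.5), 3)
  expect_error(anisotropy_index(1, 0, 1), "value error")
})

stats_config <- function(shift = 0.3, root_sd = 0.1, resid = 0.2,
                         roots = 6, cells = 50, len_slope = 0.01,
                         seed = 1) {
  synth_geometry_config(
    treatments = c("WT", "mut"), roots_per_treatment = roots,
    cells_per_root_per_tissue = cells, tissues = "cortex",
    treatment_effects = list(WT = list(length = 0, depth = 0, width = 0),
                             mut = list(length = shift, depth = 0,
                                        width = 0)),
    baseline_geometry = data.frame(
      tissue = "cortex", len_short = 8, len_long = 34, depth0 = 14,
      width0 = 11, len_slope = len_slope, depth_slope = 0.02,
      width_slope = 0.18),
    root_sd = list(length = root_sd, depth = 0.08, width = 0.6),
    zone_mixture = list(weight_short = 0.999, sd_short = resid,
                        sd_long = resid, logistic_scale = 12),
    seed = seed)
}

test_that("mixed model recovers a known treatment shift", {
  tab <- generate_geometry_table(stats_config(seed = 5))  # 600 cells, 12 roots
  fit <- fit_mixed_model(tab, "length", tissue = "cortex")
  i <- grep("^treatment", names(fit$coefficients))
  est <- fit$coefficients[i]
  se <- sqrt(diag(as.matrix(vcov(fit$fit))))[i]
  expect_lt(abs(est - 0.3), 3 * se)
  expect_gt(fit$varcomp["random"], 0)
  expect_false(fit$ols_fallback)
})

test_that("zero root variance is detected as a (near) null component", {
  tab <- generate_geometry_table(stats_config(root_sd = 0, seed = 8))
  fit <- suppressWarnings(fit_mixed_model(tab, "length",
                                          tissue = "cortex"))
  expect_lt(fit$varcomp["random"], 1e-4 * fit$varcomp["residual"] + 1e-6)
})

test_that("mixed fit reduces to OLS when every observation is its own root", {
  tab <- generate_geometry_table(stats_config(roots = 2, cells = 40,
                                              seed = 3))
  tab$root_id <- paste0("r", seq_len(nrow(tab)))  # one obs per root
  expect_warning(fit <- fit_mixed_model(tab, "length", tissue = "cortex"),
                 "OLS")
  expect_true(fit$ols_fallback)
  dat <- apply_transform(tab)
  dat$treatment <- stats::relevel(factor(dat$treatment), ref = "WT")
  ols <- lm(log(length) ~ treatment + distance_qc_t, data = dat)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("posthoc pairwise comparisons behave across effect sizes", {
  # three treatments, one with a huge shift
  cfg <- synth_geometry_config(
    treatments = c("WT", "null", "big"), roots_per_treatment = 4,
    cells_per_root_per_tissue = 40, tissues = "cortex",
    treatment_effects = list(WT = list(length = 0, depth = 0, width = 0),
                             null = list(length = 0, depth = 0, width = 0),
                             big = list(length = 2, depth = 0, width = 0)),
    root_sd = list(length = 0.02, depth = 0.05, width = 0.3),
    zone_mixture = list(weight_short = 0.999, sd_short = 0.2,
                        sd_long = 0.2, logistic_scale = 12),
    seed = 11)
  tab <- generate_geometry_table(cfg)
  fit <- fit_mixed_model(tab, "length", tissue = "cortex")
  cmp <- posthoc_pairwise(fit)
  expect_equal(nrow(cmp), 3)  # 3 treatments -> 3 pairwise contrasts
  expect_true(all(cmp$p_single_step >= cmp$p_raw - 1e-12))
  big_wt <- cmp[cmp$pair %in% c("big - WT", "WT - big"), ]
  expect_lt(big_wt$p_single_step, 1e-6)
  null_wt <- cmp[cmp$pair %in% c("null - WT", "WT - null"), ]
  expect_gt(null_wt$p_single_step, 0.05)
})

test_that("BH rejections agree with the brute-force step-up rule", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    p <- round(runif(n), 3)
    alpha <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_identical(bh_reject(p, alpha), bh_brute_force(p, alpha))
  }
  # ties and boundary values
  expect_identical(bh_reject(c(0, 0, 1, 1), 0.05),
                   bh_brute_force(c(0, 0, 1, 1), 0.05))
})

test_that("two-step adaptive correction computes the adaptive level", {
  # 17 of 25 models significant at stage 1
  p_model <- c(rep(1e-6, 17), rep(0.9, 8))
  post <- replicate(25, runif(3), simplify = FALSE)
  res <- two_step_adaptive_fdr(p_model, post, alpha = 0.05)
  expect_equal(res$m1, 17)
  expect_equal(res$stage2_alpha, 0.05 * 17 / 25)
  expect_equal(res$stage2_alpha, 0.034)
  expect_null(res$stage2_significant[[18]])
  # all null models: stage 2 skipped
  res0 <- two_step_adaptive_fdr(rep(1, 10), replicate(10, runif(2),
                                                      simplify = FALSE))
  expect_equal(res0$m1, 0)
  expect_equal(res0$stage2_alpha, 0)
  expect_true(all(vapply(res0$stage2_significant, is.null, logical(1))))
  # all significant: stage-2 level equals alpha
  res1 <- two_step_adaptive_fdr(rep(0, 10), replicate(10, runif(2),
                                                      simplify = FALSE))
  expect_equal(res1$stage2_alpha, 0.05)
})

test_that("percent variance explained matches the generating decomposition", {
  # single-source limit: pure treatment effect, tiny noise
  cfg <- stats_config(shift = 1, root_sd = 1e-3, resid = 1e-3,
                      len_slope = 0, roots = 3, cells = 40, seed = 2)
  tab <- generate_geometry_table(cfg)
  fit <- suppressWarnings(fit_mixed_model(tab, "length",
                                          tissue = "cortex"))
  expect_gt(pct_variance_br(fit), 99)
  # null limit
  cfg0 <- stats_config(shift = 0, root_sd = 0.05, resid = 0.2,
                       roots = 6, cells = 80, seed = 4)
  fit0 <- suppressWarnings(fit_mixed_model(
    generate_geometry_table(cfg0), "length", tissue = "cortex"))
  expect_lt(pct_variance_br(fit0), 5)
})

test_that("percent variance matches the analytic share at ratio 2:1:1:1", {
  # treatment variance 0.06 (effects -0.3, 0, +0.3 balanced),
  # distance 0.03, root 0.03, residual 0.03 on the log-length scale
  v_sqrtd <- 102 - ((2 / 3) * (200^1.5 - 4^1.5) / 196)^2
  beta <- sqrt(0.03 / v_sqrtd)
  analytic <- 100 * (0.09 / 0.15) * (0.06 / 0.09)
  recovered <- vapply(1:4, function(s) {
    cfg <- synth_geometry_config(
      treatments = c("a", "b", "c"), roots_per_treatment = 10,
      cells_per_root_per_tissue = 60, tissues = "cortex",
      treatment_effects = list(a = list(length = -0.3, depth = 0, width = 0),
                               b = list(length = 0, depth = 0, width = 0),
                               c = list(length = 0.3, depth = 0, width = 0)),
      baseline_geometry = data.frame(
        tissue = "cortex", len_short = 8, len_long = 34, depth0 = 14,
        width0 = 11, len_slope = beta, depth_slope = 0.02,
        width_slope = 0.18),
      root_sd = list(length = sqrt(0.03), depth = 0.08, width = 0.6),
      zone_mixture = list(weight_short = 0.9995, sd_short = sqrt(0.03),
                          sd_long = sqrt(0.03), logistic_scale = 12),
      seed = 100 + s)
    fit <- fit_mixed_model(generate_geometry_table(cfg), "length",
                           tissue = "cortex", reference = "b")
    pct_variance_br(fit)
  }, numeric(1))
  mc_se <- sd(recovered) / sqrt(length(recovered))
  expect_lt(abs(mean(recovered) - analytic), 3 * mc_se + 1.5)
})

test_that("pipeline type-I error on null data stays at the nominal level", {
  n_rep <- 300
  rej <- vapply(seq_len(n_rep), function(s) {
    cfg <- stats_config(shift = 0, root_sd = 0.05, resid = 0.2,
                        roots = 3, cells = 20, seed = 5000 + s)
    fit <- suppressWarnings(fit_mixed_model(
      generate_geometry_table(cfg), "length", tissue = "cortex"))
    fit$model_p < 0.05
  }, logical(1))
  rate <- mean(rej)
  bound <- 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rate, bound)
})
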