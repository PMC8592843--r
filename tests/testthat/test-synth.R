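cell_areas_of <- function(mesh) rootmeristem:::cell_areas(mesh)

test_that("geometry generator is deterministic and validates its config", {
  cfg <- synth_geometry_config(seed = 7, roots_per_treatment = 2,
                               cells_per_root_per_tissue = 20)
  t1 <- generate_geometry_table(cfg)
  t2 <- generate_geometry_table(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 3 * 2 * 5 * 20)
  expect_true(all(c("cell_id", "root_id", "treatment", "tissue",
                    "distance_qc", "length", "width", "depth",
                    "surface_area", "volume", "true_zone") %in% names(t1)))
  expect_error(synth_geometry_config(roots_per_treatment = 0),
               "configuration error")
  expect_error(synth_geometry_config(
    zone_mixture = list(weight_short = 1.2, sd_short = 0.2, sd_long = 0.3,
                        logistic_scale = 12)),
    "configuration error")
})

test_that("zero-noise geometry is a deterministic function of position", {
  cfg <- synth_geometry_config(
    treatments = "WT", roots_per_treatment = 2,
    cells_per_root_per_tissue = 40,
    root_sd = list(length = 0, depth = 0, width = 0),
    residual_sd = list(depth = 0, width = 0),
    zone_mixture = list(weight_short = 0.9, sd_short = 0, sd_long = 0,
                        logistic_scale = 12),
    seed = 3)
  tab <- generate_geometry_table(cfg)
  # geometry must be an exact function of (tissue, component, distance):
  # recompute from the configured baselines
  bg <- cfg$baseline_geometry
  for (ti in unique(tab$tissue)) {
    b <- bg[bg$tissue == ti, ]
    sub <- tab[tab$tissue == ti, ]
    mu <- ifelse(sub$true_zone == "meristem", log(b$len_short),
                 log(b$len_long)) + b$len_slope * sqrt(sub$distance_qc)
    expect_equal(sub$length, exp(mu), tolerance = 1e-12)
    expect_equal(sub$depth,
                 exp(log(b$depth0) + b$depth_slope * sqrt(sub$distance_qc)),
                 tolerance = 1e-12)
  }
})

test_that("volume and surface area follow the cuboid proxy", {
  cfg <- synth_geometry_config(seed = 11, roots_per_treatment = 1,
                               cells_per_root_per_tissue = 25)
  tab <- generate_geometry_table(cfg)
  sf <- cfg$shape_factor
  expect_equal(tab$volume, sf * tab$length * tab$width * tab$depth,
               tolerance = 1e-12)
  expect_equal(tab$surface_area,
               sf^(2 / 3) * 2 * (tab$length * tab$width +
                                   tab$length * tab$depth +
                                   tab$width * tab$depth),
               tolerance = 1e-12)
})

test_that("configured treatment effect is recovered from sample moments", {
  shift <- 0.3
  cfg <- synth_geometry_config(
    treatments = c("WT", "hiBR"), roots_per_treatment = 10,
    cells_per_root_per_tissue = 100, tissues = "cortex",
    treatment_effects = list(
      WT = list(length = 0, depth = 0, width = 0),
      hiBR = list(length = shift, depth = 0, width = 0)),
    root_sd = list(length = 0, depth = 0, width = 0),
    seed = 21)
  tab <- generate_geometry_table(cfg)  # 10^3 cells per arm
  d <- tapply(log(tab$length), tab$treatment, mean)
  n <- min(table(tab$treatment))
  se <- sqrt(2) * sd(log(tab$length[tab$treatment == "WT"])) / sqrt(n)
  expect_lt(abs((d[["hiBR"]] - d[["WT"]]) - shift), 3 * se)
})

test_that("track integration matches the closed-form velocity field", {
  # pure exponential field v = b x from x0 = 8
  cfg <- synth_track_config(velocity_intercept = 0, velocity_slope = 0.04,
                            track_noise_sd = 0, n_cells = 1,
                            start_range = c(8, 8), seed = 1)
  tr <- generate_tracks(cfg)
  expect_equal(tr$distance, 8 * exp(0.04 * tr$time), tolerance = 1e-12)
  # uniform motion
  cfg2 <- synth_track_config(velocity_intercept = 2, velocity_slope = 0,
                             track_noise_sd = 0, n_cells = 1,
                             start_range = c(10, 10), seed = 1)
  tr2 <- generate_tracks(cfg2)
  expect_equal(tr2$distance, 10 + 2 * tr2$time, tolerance = 1e-12)
  # zero relative rate: stationary
  cfg3 <- synth_track_config(relative_rate_per_condition = c(mut = 0),
                             track_noise_sd = 0, n_cells = 2, seed = 1)
  tr3 <- generate_tracks(cfg3)
  expect_true(all(tapply(tr3$distance, tr3$cell_id,
                         function(x) diff(range(x))) == 0))
  # configuration errors
  expect_error(synth_track_config(velocity_intercept = -1,
                                  velocity_slope = 0),
               "velocity negative")
  expect_error(synth_track_config(duration = 1, sampling_interval = 1),
               ">= 3 observations")
})

test_that("4D pair generator satisfies its construction invariants", {
  # certain division, no noise: daughters partition grown length/volume
  cfg <- synth_pairs4d_config(conditions = "WT", n_cells = 40,
                              division_prob = 1,
                              noise_sd = c(length = 0, width = 0,
                                           depth = 0), seed = 5)
  raw <- generate_pairs_4d(cfg)
  expect_true(all(table(raw$pair_id) == 2))
  merged <- merge_and_rate(raw)
  rate <- cfg$rates$WT
  expect_equal(merged$length_t1, merged$length_t0 + rate[["length"]] * 12,
               tolerance = 1e-10)
  expect_equal(merged$depth_t1, merged$depth_t0 + rate[["depth"]] * 12,
               tolerance = 1e-10)
  # zero rates + zero noise: t1 equals t0
  cfg0 <- synth_pairs4d_config(
    conditions = "WT", n_cells = 20, division_prob = 0,
    rates = list(WT = c(length = 0, width = 0, depth = 0)),
    noise_sd = c(length = 0, width = 0, depth = 0), seed = 6)
  m0 <- merge_and_rate(generate_pairs_4d(cfg0))
  expect_equal(m0$length_t1, m0$length_t0, tolerance = 1e-12)
  expect_true(all(abs(m0$rate_volume) < 1e-10))
})

test_that("per-hour rates are recovered from generated 4D pairs", {
  rates <- list(X = c(length = 1.0, width = 0.05, depth = 0.05))
  cfg <- synth_pairs4d_config(conditions = "X", n_cells = 400,
                              rates = rates, dt = 12,
                              division_prob = 0.3, seed = 9)
  merged <- merge_and_rate(generate_pairs_4d(cfg))
  for (p in c("length", "width", "depth")) {
    est <- mean(merged[[paste0("rate_", p)]])
    se <- sd(merged[[paste0("rate_", p)]]) / sqrt(nrow(merged))
    expect_lt(abs(est - rates$X[[p]]), 3 * se + 1e-9)
  }
})

test_that("generated meshes are watertight with correctly shared walls", {
  mesh <- generate_mesh(synth_mesh_config(seed = 2))
  expect_true(validate_mesh(mesh))
  shared <- ifelse(is.na(mesh$walls$cell2), 1L, 2L)
  # boundary walls are exactly the outer-epidermal ones
  expect_true(all(shared[mesh$walls$class == "outer-epidermal"] == 1))
  expect_true(all(shared[mesh$walls$class != "outer-epidermal"] == 2))
  expect_setequal(unique(mesh$tissue),
                  c("stele", "pericycle", "endodermis", "cortex",
                    "epidermis"))
})

test_that("unjittered 8-fold symmetric mesh is invariant under 45-degree rotation", {
  mesh <- generate_mesh(synth_mesh_config(n_epidermis = 16, n_cortex = 8,
                                          n_endodermis = 8,
                                          n_pericycle = 8, n_stele = 8,
                                          jitter_sd = 0, seed = 1))
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- mesh$vertices %*% t(R)
  # every rotated vertex coincides with an original vertex
  d <- apply(rot, 1, function(p) {
    min(sqrt(rowSums(sweep(mesh$vertices, 2, p)^2)))
  })
  expect_lt(max(d), 1e-9)
})

test_that("ring areas match the analytic annulus at 16+ cells per ring", {
  radii <- c(10, 12, 14, 17, 20)
  mesh <- generate_mesh(synth_mesh_config(n_epidermis = 24, n_cortex = 16,
                                          n_endodermis = 16,
                                          n_pericycle = 16, n_stele = 16,
                                          radii = radii, jitter_sd = 0,
                                          seed = 1))
  per <- tissue_areas(mesh)
  analytic <- c(stele = pi * radii[1]^2,
                pericycle = pi * (radii[2]^2 - radii[1]^2),
                endodermis = pi * (radii[3]^2 - radii[2]^2),
                cortex = pi * (radii[4]^2 - radii[3]^2),
                epidermis = pi * (radii[5]^2 - radii[4]^2))
  for (ti in names(analytic)) {
    expect_lt(abs(per[[ti]] / analytic[[ti]] - 1), 0.02)
  }
})

test_that("mesh JSON serialization round-trips", {
  mesh <- generate_mesh(synth_mesh_config(n_epidermis = 10, n_cortex = 6,
                                          n_endodermis = 6,
                                          n_pericycle = 6, n_stele = 6,
                                          radii = c(6, 8, 10, 13, 16),
                                          jitter_sd = 0.1, seed = 4))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_mesh_json(mesh, path)
  back <- read_mesh_json(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-12)
  expect_identical(back$tissue, mesh$tissue)
  expect_equal(sort(cell_areas_of(back)), sort(cell_areas_of(mesh)),
               tolerance = 1e-10)
  key <- function(m) paste(pmin(m$walls$v1, m$walls$v2),
                           pmax(m$walls$v1, m$walls$v2))
  expect_setequal(key(back), key(mesh))
  m <- match(key(mesh), key(back))
  expect_identical(back$walls$class[m], mesh$walls$class)
  expect_equal(back$walls$rest_length[m], mesh$walls$rest_length,
               tolerance = 1e-12)
})
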