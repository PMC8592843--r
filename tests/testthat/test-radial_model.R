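test_that("a mesh at rest under zero pressure does not move", {
  mesh <- small_template(seed = 1)
  p <- hexagon_params(k = 100, P = 0)
  out <- relax(mesh, p)
  expect_equal(out$vertices, mesh$vertices, tolerance = 1e-12)
  expect_equal(attr(out, "relax_iterations"), 0)
})

test_that("pressurized hexagon equilibrium matches a generic energy minimizer", {
  mesh <- hexagon_mesh(side = 2)
  p <- hexagon_params(k = 10, P = 1)
  relaxed <- relax(mesh, p)
  # independent oracle: quasi-Newton minimization of the total potential
  energy_of <- function(v) {
    m <- mesh
    m$vertices <- matrix(v, ncol = 2)
    mesh_energy(m, p)
  }
  opt <- optim(as.numeric(mesh$vertices), energy_of, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  oracle <- matrix(opt$par, ncol = 2)
  expect_lt(max(abs(relaxed$vertices - oracle)), 1e-4)
  expect_lt(mesh_energy(relaxed, p), mesh_energy(mesh, p))
})

test_that("relaxation preserves rotational symmetry", {
  mesh <- generate_mesh(synth_mesh_config(n_epidermis = 16, n_cortex = 8,
                                          n_endodermis = 8,
                                          n_pericycle = 8, n_stele = 8,
                                          jitter_sd = 0, seed = 1))
  relaxed <- relax(mesh, sim_params())
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- relaxed$vertices %*% t(R)
  d <- apply(rot, 1, function(pt) {
    min(sqrt(rowSums(sweep(relaxed$vertices, 2, pt)^2)))
  })
  expect_lt(max(d), 1e-6)
})

test_that("plain descent relaxation is an energy descent", {
  mesh <- hexagon_mesh(side = 2)
  mesh$vertices <- mesh$vertices * 1.15  # deformed start
  p <- hexagon_params(k = 10, P = 1, relax_method = "descent")
  relaxed <- relax(mesh, p, record_energy = TRUE)
  trace <- attr(relaxed, "energy_trace")
  expect_gt(length(trace), 10)
  expect_true(all(diff(trace) <= 1e-10 * (1 + abs(trace[-length(trace)]))))
})

test_that("growth respects threshold and zero-extensibility limits", {
  mesh <- relax(small_template(seed = 2), sim_params())
  # zero extensibility: area constant over many steps
  p0 <- sim_params(extensibility = 0)
  res <- simulate_to_area(mesh, p0, step_budget = 50)
  expect_lt(abs(res$total_extension - 1), 1e-6)
  expect_equal(res$mesh$walls$rest_length, mesh$walls$rest_length)
  # strain below threshold everywhere: rest lengths unchanged
  pth <- sim_params(threshold = 10)
  grown <- grow_step(mesh, pth, n_steps = 5)
  expect_equal(grown$walls$rest_length, mesh$walls$rest_length)
  # stalling before an area target raises the stall error
  expect_error(simulate_to_area(mesh, p0,
                                target_area = 1.1 * attr(tissue_areas(mesh),
                                                         "total")),
               "stall")
})

test_that("a growing pressurized cell has monotone non-decreasing area", {
  mesh <- hexagon_mesh(side = 2)
  p <- hexagon_params(k = 50, P = 1, ext = 0.02)
  res <- rootmeristem:::run_engine(relax(mesh, p), p, 60L)
  expect_true(res$converged)
  expect_true(all(diff(res$area_trace) > -1e-9))
  expect_gt(tail(res$area_trace, 1), res$area_trace[1])
})

test_that("doubling stiffness and pressure together changes nothing", {
  mesh <- relax(small_template(seed = 3), sim_params())
  p1 <- sim_params()
  p2 <- sim_params(stiffness = 2 * p1$stiffness,
                   pressure = 2 * p1$pressure)
  r1 <- simulate_to_area(mesh, p1, step_budget = 40)
  r2 <- simulate_to_area(mesh, p2, step_budget = 40)
  expect_equal(r1$area_trace, r2$area_trace, tolerance = 1e-10)
  expect_equal(r1$mesh$vertices, r2$mesh$vertices, tolerance = 1e-10)
})

test_that("target equal to the initial area performs zero growth", {
  mesh <- relax(small_template(seed = 4), sim_params())
  a0 <- attr(tissue_areas(mesh), "total")
  res <- simulate_to_area(mesh, sim_params(), target_area = a0)
  expect_equal(res$steps, 0)
  expect_true(all(abs(res$extension - 1) < 1e-12))
})

test_that("tissue areas follow the shoelace formula and normalization", {
  sq <- rootmeristem:::build_mesh(
    rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4), "epidermis")
  a <- tissue_areas(sq)
  expect_equal(as.numeric(a), 1)
  expect_equal(normalize_profile(c(5, 10, 20)), c(1, 2, 4))
  expect_equal(normalize_profile(c(3, 3, 3)), c(1, 1, 1))
})

test_that("raising the inner multiplier strictly decreases inner extension", {
  mesh <- relax(small_template(seed = 5), sim_params())
  # leverage of the inner-wall stiffness accumulates over growth steps;
  # probe at a budget long enough for the effect to clear solver noise
  ext_in <- vapply(c(0.5, 1, 2), function(m) {
    simulate_to_area(mesh,
                     apply_stiffness_multipliers(sim_params(), m, 1),
                     step_budget = 150)$inner_extension
  }, numeric(1))
  expect_true(all(diff(ext_in) < 0))
})

test_that("uniform parameters overgrow the outer and undergrow the inner group", {
  mesh <- small_template(seed = 6)
  cal <- sim_params()
  uni <- uniform_params()
  m_cal <- relax(mesh, cal)
  m_uni <- relax(mesh, uni)
  target <- 1.6
  r_cal <- simulate_to_area(m_cal, cal,
                            target_area = target *
                              attr(tissue_areas(m_cal), "total"))
  r_uni <- simulate_to_area(m_uni, uni,
                            target_area = target *
                              attr(tissue_areas(m_uni), "total"))
  expect_gt(r_uni$outer_extension, r_cal$outer_extension)
  expect_lt(r_uni$inner_extension, r_cal$inner_extension)
})
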