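#' Mechanical parameters for the cross-section mass-spring model
#'
#' Collects wall stiffness per wall class, extensibility per tissue, turgor
#' pressure per tissue, the growth strain threshold and the numerical
#' controls of the relaxation.
#'
#' Walls are linear-strain springs (tension `k * (l - l0)/l0`, `k` in units
#' of force per unit strain); each cell pushes outward on its walls with
#' force `pressure * wall_length` (force/length units); vertices follow the
#' net force in an overdamped explicit update, preconditioned per vertex
#' by the incident spring stiffness (so stiff and soft regions relax at a
#' comparable pace), until the maximum vertex force is below `force_tol`. During a growth step every wall whose strain
#' exceeds `threshold` gains rest length at rate `ext * (strain -
#' threshold)` per step, where `ext` averages the two adjacent cells'
#' extensibility (boundary walls use their single cell).
#'
#' The defaults are the reference (wild-type) calibration and express the
#' dual-ring arrangement: a stiff outer epidermal wall and stiff
#' outer/inner endodermal walls dominate mechanically, the innermost
#' pericycle/stele walls are softest, and the inner tissues compensate
#' with higher extensibility. Turgor pressure declines modestly from the
#' stele outwards; besides being physiologically plausible, the inward
#' pressure step is what loads the endodermal ring in a force-controlled
#' way and thereby gives inner-wall stiffness real leverage over
#' inner-tissue growth (with strictly uniform pressure the interior is
#' displacement-loaded and inner stiffness is nearly unidentifiable).
#'
#' @param stiffness Named numeric over the six wall classes
#'   (force/strain).
#' @param extensibility Named numeric per tissue, or a scalar applied to
#'   all tissues (1/step).
#' @param pressure Named numeric per tissue or scalar (force/length).
#' @param threshold Growth strain threshold (unitless, default 0: any
#'   positive strain grows).
#' @param dt Dimensionless relaxation step (fraction of the local stable
#'   step); `NULL` (default) uses 0.3.
#' @param force_tol Convergence tolerance on the maximum vertex force;
#'   `NULL` scales it to the pressure loading
#'   (`1e-4 * max(pressure) * mean(rest length)`).
#' @param relax_max_iter Iteration cap per relaxation (simulation error if
#'   exceeded).
#' @param relax_method `"fire"` (default): fast inertial relaxation engine
#'   on the preconditioned forces; `"descent"`: plain preconditioned
#'   gradient descent, which descends the potential strictly and is used
#'   for energy audits.
#' @param max_growth_steps Hard cap on growth steps in area mode.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(stiffness = c("outer-epidermal" = 2000,
                                     "epidermal-other" = 800,
                                     "cortex" = 500,
                                     "outer-endodermal" = 1600,
                                     "inner-endodermal" = 1600,
                                     "pericycle-stele" = 300),
                       extensibility = c(stele = 0.4, pericycle = 0.4,
                                         endodermis = 0.24, cortex = 0.12,
                                         epidermis = 0.10),
                       pressure = c(stele = 1.6, pericycle = 1.6,
                                    endodermis = 1.3, cortex = 1,
                                    epidermis = 1),
                       threshold = 0,
                       dt = NULL,
                       force_tol = NULL,
                       relax_max_iter = 500000,
                       relax_method = c("fire", "descent"),
                       max_growth_steps = 5000) {
  relax_method <- match.arg(relax_method)
  if (is.null(names(stiffness)) || !all(wall_classes() %in% names(stiffness))) {
    stop_config("stiffness must be named over all six wall classes")
  }
  check_positive(stiffness, "stiffness")
  if (threshold < 0) stop_config("threshold must be >= 0")
  if (any(extensibility < 0)) stop_config("extensibility must be >= 0")
  if (any(pressure < 0)) stop_config("pressure must be >= 0")
  structure(list(stiffness = stiffness, extensibility = extensibility,
                 pressure = pressure, threshold = threshold, dt = dt,
                 force_tol = force_tol, relax_max_iter = relax_max_iter,
                 relax_method = relax_method,
                 max_growth_steps = max_growth_steps),
            class = "sim_params")
}

#' Uniform-parameter variant of [sim_params()]
#'
#' The minimal-assumption baseline: one stiffness for every wall class and
#' one extensibility for every tissue. Pressure keeps the template default
#' (the inward turgor gradient is a property of the tissue, not of the
#' calibration being tested).
#'
#' @param stiffness,extensibility Scalars.
#' @param pressure As in [sim_params()].
#' @param ... Passed to [sim_params()].
#' @return Object of class `sim_params`.
#' @export
uniform_params <- function(stiffness = 800, extensibility = 0.08,
                           pressure = c(stele = 1.6, pericycle = 1.6,
                                        endodermis = 1.3, cortex = 1,
                                        epidermis = 1), ...) {
  sim_params(stiffness = setNames(rep(stiffness, 6), wall_classes()),
             extensibility = extensibility, pressure = pressure, ...)
}

per_tissue <- function(x, tissues, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), length(tissues)), tissues))
  }
  miss <- setdiff(tissues, names(x))
  if (length(miss)) {
    stop_config("%s missing for tissue(s): %s", what,
                paste(miss, collapse = ", "))
  }
  setNames(as.numeric(x[tissues]), tissues)
}

# Assemble the flat arrays the C++ engine consumes.
engine_args <- function(mesh, params) {
  tissues <- unique(mesh$tissue)
  ext_t <- per_tissue(params$extensibility, tissues, "extensibility")
  prs_t <- per_tissue(params$pressure, tissues, "pressure")
  w <- mesh$walls
  k <- params$stiffness[w$class]
  if (any(is.na(k))) stop_config("unknown wall class in mesh")
  e1 <- ext_t[mesh$tissue[w$cell1]]
  e2 <- ifelse(is.na(w$cell2), e1, ext_t[mesh$tissue[w$cell2]])
  wall_ext <- (e1 + e2) / 2
  loops <- mesh$cells
  cell_off <- cumsum(c(0L, vapply(loops, length, integer(1))))
  cell_loop <- unlist(loops) - 1L
  pressure <- prs_t[mesh$tissue]
  dt <- params$dt
  if (is.null(dt)) dt <- 0.3
  tol <- params$force_tol
  if (is.null(tol)) {
    tol <- 1e-4 * max(prs_t) * mean(w$rest_length)
    if (tol <= 0) tol <- 1e-9 * max(k)
  }
  list(verts = mesh$vertices, wall_a = as.integer(w$v1 - 1L),
       wall_b = as.integer(w$v2 - 1L), wall_k = as.numeric(k),
       wall_l0 = as.numeric(w$rest_length),
       wall_ext = as.numeric(wall_ext),
       cell_off = as.integer(cell_off), cell_loop = as.integer(cell_loop),
       pressure = as.numeric(pressure), threshold = params$threshold,
       dt = dt, tol = tol, relax_max_iter = params$relax_max_iter,
       method = if (identical(params$relax_method, "descent")) 0L else 1L)
}

run_engine <- function(mesh, params, n_growth_steps = 0L,
                       target_area = NA_real_, record_energy = FALSE) {
  a <- engine_args(mesh, params)
  cpp_simulate(a$verts, a$wall_a, a$wall_b, a$wall_k, a$wall_l0,
               a$wall_ext, a$cell_off, a$cell_loop, a$pressure,
               a$threshold, a$dt, a$tol, a$relax_max_iter,
               as.integer(n_growth_steps),
               if (is.na(target_area)) -1 else target_area,
               record_energy, a$method)
}

#' Relax a mesh to mechanical quasi-equilibrium
#'
#' Overdamped explicit relaxation of vertex positions under wall spring
#' tension and cell pressure until the maximum vertex force falls below
#' the tolerance.
#'
#' @param mesh A `cross_section_mesh`.
#' @param params A [sim_params()].
#' @param record_energy Record total potential energy (spring energy minus
#'   pressure-area work) at every iteration into the `energy_trace`
#'   attribute.
#' @return The relaxed mesh with attributes `relax_iterations`,
#'   `converged` and (optionally) `energy_trace`.
#' @export
relax <- function(mesh, params, record_energy = FALSE) {
  res <- run_engine(mesh, params, 0L, NA_real_, record_energy)
  if (!res$converged) {
    stop(sprintf("simulation error: relaxation did not converge within %d iterations",
                 params$relax_max_iter), call. = FALSE)
  }
  mesh$vertices <- res$vertices
  attr(mesh, "relax_iterations") <- res$relax_iterations
  attr(mesh, "converged") <- res$converged
  if (record_energy) attr(mesh, "energy_trace") <- res$energy_trace
  mesh
}

#' Apply growth steps to a relaxed mesh
#'
#' Each step adds irreversible rest length to every wall with strain above
#' the threshold and re-relaxes the mesh.
#'
#' @param mesh A `cross_section_mesh` (relax first for a clean strain
#'   state).
#' @param params A [sim_params()].
#' @param n_steps Number of growth steps.
#' @return The grown, re-relaxed mesh (updated vertices and
#'   `walls$rest_length`).
#' @export
grow_step <- function(mesh, params, n_steps = 1L) {
  res <- run_engine(mesh, params, as.integer(n_steps), NA_real_)
  if (!res$converged) {
    stop("simulation error: relaxation did not converge during growth",
         call. = FALSE)
  }
  mesh$vertices <- res$vertices
  mesh$walls$rest_length <- res$rest_length
  mesh
}

#' Simulate growth to a target area or for a fixed step budget
#'
#' Alternates relaxation and growth until the total cross-section area
#' reaches `target_area` (area mode) or exactly `step_budget` growth steps
#' have been applied (time mode), and reports per-tissue area extensions.
#'
#' @param mesh A `cross_section_mesh` (the initial template).
#' @param params A [sim_params()].
#' @param target_area Total area to reach (um^2); must exceed the initial
#'   area.
#' @param step_budget Number of growth steps (time mode); exactly one of
#'   `target_area` and `step_budget` must be given.
#' @return Object of class `sim_result`: list with `initial_areas`,
#'   `final_areas` (per tissue, um^2), `extension` (per-tissue fold),
#'   `inner_extension`, `outer_extension` (fold; inner = endodermis +
#'   pericycle + stele, outer = epidermis + cortex), `total_extension`,
#'   `steps`, `area_trace` and the final `mesh`.
#' @export
simulate_to_area <- function(mesh, params, target_area = NULL,
                             step_budget = NULL) {
  if (is.null(target_area) == is.null(step_budget)) {
    stop("give exactly one of target_area and step_budget", call. = FALSE)
  }
  init <- tissue_areas(mesh)
  if (!is.null(target_area)) {
    if (target_area < attr(init, "total")) {
      stop("target_area must be at least the initial area", call. = FALSE)
    }
    res <- run_engine(mesh, params, params$max_growth_steps, target_area)
    if (res$stalled) {
      stop("stall error: area increase below 1e-9 per step before target",
           call. = FALSE)
    }
    if (res$converged && res$total_area < target_area) {
      stop("simulation error: growth-step cap reached before target area",
           call. = FALSE)
    }
  } else {
    res <- run_engine(mesh, params, as.integer(step_budget), NA_real_)
  }
  if (!res$converged) {
    stop("simulation error: relaxation did not converge during growth",
         call. = FALSE)
  }
  mesh$vertices <- res$vertices
  mesh$walls$rest_length <- res$rest_length
  fin <- tissue_areas(mesh)
  structure(list(
    initial_areas = init, final_areas = fin,
    extension = setNames(as.numeric(fin) / as.numeric(init[names(fin)]),
                         names(fin)),
    inner_extension = attr(fin, "inner") / attr(init, "inner"),
    outer_extension = attr(fin, "outer") / attr(init, "outer"),
    total_extension = attr(fin, "total") / attr(init, "total"),
    steps = res$steps, area_trace = res$area_trace, mesh = mesh
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d growth steps, total area %.1f -> %.1f um^2 (x%.3f)\n",
              x$steps, attr(x$initial_areas, "total"),
              attr(x$final_areas, "total"), x$total_extension))
  cat(sprintf("  inner (endodermis+pericycle+stele) extension: %.3f\n",
              x$inner_extension))
  cat(sprintf("  outer (epidermis+cortex) extension:           %.3f\n",
              x$outer_extension))
  invisible(x)
}

inner_wall_classes <- function() c("inner-endodermal", "pericycle-stele")
outer_wall_classes <- function() {
  c("outer-epidermal", "epidermal-other", "cortex", "outer-endodermal")
}

#' Scale inner- and outer-group wall stiffness
#'
#' Multiplies the stiffness of the inner wall group (inner-endodermal and
#' pericycle-stele walls) by `inner` and the outer group (outer-epidermal,
#' epidermal-other, cortex and outer-endodermal walls) by `outer`.
#'
#' @param params A [sim_params()].
#' @param inner,outer Positive multipliers.
#' @return Modified `sim_params`.
#' @export
apply_stiffness_multipliers <- function(params, inner, outer) {
  check_positive(c(inner, outer), "multipliers")
  st <- params$stiffness
  st[inner_wall_classes()] <- st[inner_wall_classes()] * inner
  st[outer_wall_classes()] <- st[outer_wall_classes()] * outer
  params$stiffness <- st
  params
}

#' Fit inner/outer stiffness multipliers to target area extensions
#'
#' Derivative-free (Nelder-Mead, in log-multiplier space) search for the
#' two stiffness multipliers that make the simulated inner- and
#' outer-group area extensions match the targets under a fixed growth-step
#' budget. The budget is `round(relative_time * wt_steps)`: a genotype
#' that spends (say) 1.76 times longer traversing the meristem is
#' simulated for 1.76 times the reference step count. The objective is the
#' maximum relative extension error; the fit is converged when it drops
#' below `residual_tol` (default 0.1%).
#'
#' @param mesh The reference (unsimulated) template mesh.
#' @param params Reference-calibrated [sim_params()].
#' @param targets Named numeric `c(inner = , outer = )` target area
#'   extensions (fold).
#' @param wt_steps Growth steps used by the reference simulation.
#' @param relative_time Time budget of the genotype relative to the
#'   reference (fold).
#' @param start Initial multipliers.
#' @param max_eval Cap on simulator evaluations.
#' @param residual_tol Convergence threshold on the residual.
#' @return Object of class `stiffness_fit`: list with `inner`, `outer`
#'   (multipliers), `inner_pct_change`, `outer_pct_change` (percent change
#'   of group stiffness), `residual`, `step_budget`, `evaluations`,
#'   `converged` and the final `sim` result.
#' @export
fit_stiffness_multipliers <- function(mesh, params, targets,
                                      wt_steps, relative_time = 1,
                                      start = c(1, 1), max_eval = 200,
                                      residual_tol = 1e-3) {
  stopifnot(all(c("inner", "outer") %in% names(targets)))
  check_positive(unlist(targets[c("inner", "outer")]), "targets")
  budget <- max(1L, as.integer(round(relative_time * wt_steps)))
  evals <- 0L
  best <- list(par = log(start), value = Inf)
  stop_tol <- residual_tol / 2
  objective <- function(logm) {
    evals <<- evals + 1L
    p <- apply_stiffness_multipliers(params, exp(logm[1]), exp(logm[2]))
    sim <- tryCatch(simulate_to_area(mesh, p, step_budget = budget),
                    error = function(e) NULL)
    if (is.null(sim)) return(10)
    val <- max(abs(sim$inner_extension / targets[["inner"]] - 1),
               abs(sim$outer_extension / targets[["outer"]] - 1))
    if (val < best$value) best <<- list(par = logm, value = val)
    if (val < stop_tol) stop("..early-stop..", call. = FALSE)
    val
  }
  tryCatch(
    optim(log(start), objective, method = "Nelder-Mead",
          control = list(maxit = max_eval, abstol = 1e-9, reltol = 1e-9)),
    error = function(e) {
      if (!grepl("..early-stop..", conditionMessage(e), fixed = TRUE)) {
        stop(e)
      }
      NULL
    })
  inner <- exp(best$par[1]); outer <- exp(best$par[2])
  final_sim <- simulate_to_area(
    mesh, apply_stiffness_multipliers(params, inner, outer),
    step_budget = budget)
  residual <- max(abs(final_sim$inner_extension / targets[["inner"]] - 1),
                  abs(final_sim$outer_extension / targets[["outer"]] - 1))
  if (residual > 0.05) {
    warning(sprintf("fit failure: residual %.3f above 0.05; landscape near optimum may be flat",
                    residual), call. = FALSE)
  }
  structure(list(inner = inner, outer = outer,
                 inner_pct_change = 100 * (inner - 1),
                 outer_pct_change = 100 * (outer - 1),
                 residual = residual, step_budget = budget,
                 evaluations = evals,
                 converged = residual < residual_tol,
                 sim = final_sim),
            class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("stiffness_fit: inner x%.3f (%+.1f%%), outer x%.3f (%+.1f%%)\n",
              x$inner, x$inner_pct_change, x$outer, x$outer_pct_change))
  cat(sprintf("  residual %.2e over %d-step budget (%d evaluations, %s)\n",
              x$residual, x$step_budget, x$evaluations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Total potential energy of a mesh under given parameters
#'
#' Spring energy `sum 0.5 k strain^2 l0` minus the pressure-area work
#' `sum P * A`. Relaxation descends this potential.
#'
#' @param mesh A `cross_section_mesh`.
#' @param params A [sim_params()].
#' @return Scalar energy.
#' @export
mesh_energy <- function(mesh, params) {
  tissues <- unique(mesh$tissue)
  prs <- per_tissue(params$pressure, tissues, "pressure")
  k <- params$stiffness[mesh$walls$class]
  l <- wall_lengths(mesh)
  l0 <- mesh$walls$rest_length
  eps <- (l - l0) / l0
  sum(0.5 * k * eps^2 * l0) -
    sum(prs[mesh$tissue] * cell_areas(mesh))
}
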