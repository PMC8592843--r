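# Shared fixtures, built in code at test time.

# Single hexagonal cell mesh with side length `side`, centred at origin.
hexagon_mesh <- function(side = 2, tissue = "epidermis") {
  th <- 2 * pi * (0:5) / 6
  verts <- cbind(side * cos(th), side * sin(th))
  rootmeristem:::build_mesh(verts, list(1:6), tissue)
}

hexagon_params <- function(k = 10, P = 1, ext = 0, ...) {
  uniform_params(stiffness = k, extensibility = ext, pressure = P, ...)
}

# Small cross-section template for fast simulator tests.
small_template <- function(seed = 1, jitter_sd = 0.1) {
  generate_mesh(synth_mesh_config(n_epidermis = 12, n_cortex = 6,
                                  n_endodermis = 6, n_pericycle = 8,
                                  n_stele = 8,
                                  radii = c(8, 10.5, 13.5, 18, 22.5),
                                  jitter_sd = jitter_sd, seed = seed))
}

# Memoized wild-type reference experiment on the full-size template:
# relaxed mesh, calibrated parameters and the growth run to 1.8x area.
.wt_cache <- new.env(parent = emptyenv())
wt_experiment <- function() {
  if (is.null(.wt_cache$sim)) {
    mesh <- generate_mesh(synth_mesh_config(seed = 1))
    params <- sim_params()
    relaxed <- relax(mesh, params)
    a0 <- attr(tissue_areas(relaxed), "total")
    .wt_cache$mesh <- relaxed
    .wt_cache$params <- params
    .wt_cache$sim <- simulate_to_area(relaxed, params,
                                      target_area = 1.8 * a0)
  }
  list(mesh = .wt_cache$mesh, params = .wt_cache$params,
       sim = .wt_cache$sim)
}

# Independent brute-force Benjamini-Hochberg step-up rule.
bh_brute_force <- function(p, alpha) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(n)) {
    if (ps[i] <= alpha * i / n) k <- i
  }
  rej <- logical(n)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}
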