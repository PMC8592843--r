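#' Configuration for a synthetic root cross-section mesh
#'
#' Describes a concentric polygonal tessellation of a root cross section at
#' the top of the meristem (nominally the 8 um section): a pie of stele
#' cells surrounded by rings of pericycle, endodermis, cortex and epidermis.
#' Cell counts default to canonical Arabidopsis root anatomy and are
#' configurable.
#'
#' @param n_epidermis,n_cortex,n_endodermis,n_pericycle,n_stele Cells per
#'   ring.
#' @param radii Strictly increasing numeric of length 5: outer boundary
#'   radius (um) of the stele, pericycle, endodermis, cortex and epidermis.
#' @param jitter_sd Standard deviation (um) of Gaussian perturbation applied
#'   to every vertex.
#' @param seed Integer seed (used for the jitter).
#' @return An object of class `synth_mesh_config`.
#' @export
synth_mesh_config <- function(n_epidermis = 20, n_cortex = 8,
                              n_endodermis = 8, n_pericycle = 12,
                              n_stele = 18,
                              radii = c(12, 15, 19, 25, 31),
                              jitter_sd = 0.15, seed = 1L) {
  cfg <- structure(list(
    counts = c(stele = n_stele, pericycle = n_pericycle,
               endodermis = n_endodermis, cortex = n_cortex,
               epidermis = n_epidermis),
    radii = radii, jitter_sd = jitter_sd, seed = as.integer(seed)
  ), class = "synth_mesh_config")
  if (any(cfg$counts < 3)) {
    stop_config("configuration error: at least 3 cells per ring")
  }
  if (length(radii) != 5 || any(diff(radii) <= 0) || radii[1] <= 0) {
    stop_config("configuration error: radii must be 5 strictly increasing positive values")
  }
  if (jitter_sd < 0) stop_config("configuration error: jitter_sd must be >= 0")
  cfg
}

ring_angles <- function(n, offset) {
  (2 * pi * (seq_len(n) - 1 + offset) / n) %% (2 * pi)
}

#' Generate a concentric root cross-section mesh
#'
#' Builds a watertight 2D polygonal tessellation: stele cells are pie wedges
#' meeting at the centre; each outer tissue is a ring of annular-sector
#' cells. Vertices on a ring interface are shared between the two rings, so
#' every internal wall has exactly two incident cells. Walls are classified
#' by the tissues they separate into the six wall classes used by the
#' mechanical model: `outer-epidermal` (the organ surface),
#' `epidermal-other` (all other walls touching an epidermal cell),
#' `outer-endodermal` (cortex/endodermis interface), `inner-endodermal`
#' (endodermis/pericycle interface), `cortex` (walls between cortex cells)
#' and `pericycle-stele` (all remaining inner walls).
#'
#' @param config A [synth_mesh_config()].
#' @return An object of class `cross_section_mesh`: a list with `vertices`
#'   (n x 2 matrix, um), `cells` (list of counter-clockwise vertex-index
#'   loops), `tissue` (character per cell) and `walls` (data frame with
#'   `v1`, `v2`, `class`, `cell1`, `cell2`, `rest_length`).
#' @export
generate_mesh <- function(config) {
  stopifnot(inherits(config, "synth_mesh_config"))
  cfg <- config
  tissues <- names(cfg$counts)
  # half-spacing stagger: neighbouring rings with equal counts bisect each
  # other's arcs, which keeps ring areas close to the analytic annulus and
  # anchors every interface vertex to a radial wall
  offsets <- c(stele = 0, pericycle = 0.5, endodermis = 0,
               cortex = 0.5, epidermis = 0)
  angles <- mapply(ring_angles, cfg$counts, offsets[tissues],
                   SIMPLIFY = FALSE)

  # interface i sits at radii[i]; its vertex angles are the union of the
  # division angles of the rings on either side
  iface_angles <- vector("list", 5)
  for (i in 1:5) {
    a <- angles[[i]]
    if (i < 5) {
      a <- c(a, angles[[i + 1]])
    } else {
      # nothing subdivides the organ surface from outside: bisect its arcs
      # once so the outer wall tracks the circle as well as the interfaces
      a <- c(a, a + pi / cfg$counts[i])
    }
    a <- sort(unique(round(a %% (2 * pi), 12)))
    iface_angles[[i]] <- a
  }

  verts <- matrix(0, nrow = 0, ncol = 2)
  key_id <- new.env(parent = emptyenv())
  add_vertex <- function(x, y) {
    verts <<- rbind(verts, c(x, y))
    nrow(verts)
  }
  centre_id <- add_vertex(0, 0)
  iface_ids <- vector("list", 5)
  for (i in 1:5) {
    iface_ids[[i]] <- vapply(iface_angles[[i]], function(th) {
      add_vertex(cfg$radii[i] * cos(th), cfg$radii[i] * sin(th))
    }, integer(1))
  }

  # vertices (ids + angles) of interface i lying in the sector [th0, th1],
  # ascending; th1 may exceed 2*pi (wrap)
  sector_vertices <- function(i, th0, th1) {
    a <- iface_angles[[i]]
    ids <- iface_ids[[i]]
    eps <- 1e-7
    a_ext <- c(a, a + 2 * pi)
    ids_ext <- c(ids, ids)
    sel <- a_ext >= th0 - eps & a_ext <= th1 + eps
    ord <- order(a_ext[sel])
    unique_ids <- ids_ext[sel][ord]
    unique_ids[!duplicated(unique_ids)]
  }

  cells <- list()
  tissue <- character(0)
  for (t in seq_along(tissues)) {
    n <- cfg$counts[t]
    th <- sort(angles[[t]])
    for (j in seq_len(n)) {
      th0 <- th[j]
      th1 <- if (j < n) th[j + 1] else th[1] + 2 * pi
      if (t == 1) {
        arc <- sector_vertices(1, th0, th1)
        loop <- c(centre_id, arc)
      } else {
        inner <- sector_vertices(t - 1, th0, th1)
        outer <- sector_vertices(t, th0, th1)
        loop <- c(outer, rev(inner))
      }
      cells[[length(cells) + 1L]] <- loop
      tissue <- c(tissue, tissues[t])
    }
  }

  if (cfg$jitter_sd > 0) {
    verts <- with_seed(cfg$seed, {
      verts + matrix(rnorm(length(verts), 0, cfg$jitter_sd), ncol = 2)
    })
  }

  mesh <- build_mesh(verts, cells, tissue)
  validate_mesh(mesh)
  mesh
}

# Assemble a cross_section_mesh from vertex coordinates, CCW vertex loops
# and per-cell tissue labels; walls and their classes are derived.
build_mesh <- function(vertices, cells, tissue) {
  edges <- list()
  ekey <- character(0)
  e_cells <- list()
  for (ci in seq_along(cells)) {
    loop <- cells[[ci]]
    nb <- c(loop[-1], loop[1])
    for (k in seq_along(loop)) {
      a <- loop[k]; b <- nb[k]
      if (a == b) stop("generation error: degenerate wall (repeated vertex)")
      key <- paste(min(a, b), max(a, b))
      idx <- match(key, ekey)
      if (is.na(idx)) {
        ekey <- c(ekey, key)
        edges[[length(edges) + 1L]] <- c(min(a, b), max(a, b))
        e_cells[[length(e_cells) + 1L]] <- ci
      } else {
        e_cells[[idx]] <- c(e_cells[[idx]], ci)
      }
    }
  }
  v1 <- vapply(edges, `[`, numeric(1), 1)
  v2 <- vapply(edges, `[`, numeric(1), 2)
  cell1 <- vapply(e_cells, `[`, numeric(1), 1)
  cell2 <- vapply(e_cells, function(x) if (length(x) > 1) x[2] else NA_real_,
                  numeric(1))
  if (any(vapply(e_cells, length, integer(1)) > 2)) {
    stop("generation error: wall shared by more than 2 cells")
  }
  cls <- mapply(function(c1, c2) {
    t1 <- tissue[c1]
    t2 <- if (is.na(c2)) NA_character_ else tissue[c2]
    wall_class(t1, t2)
  }, cell1, cell2)
  len <- sqrt(rowSums((vertices[v1, , drop = FALSE] -
                         vertices[v2, , drop = FALSE])^2))
  walls <- data.frame(v1 = as.integer(v1), v2 = as.integer(v2),
                      class = cls, cell1 = as.integer(cell1),
                      cell2 = as.integer(cell2), rest_length = len,
                      stringsAsFactors = FALSE)
  structure(list(vertices = vertices, cells = cells, tissue = tissue,
                 walls = walls),
            class = "cross_section_mesh")
}

wall_classes <- function() {
  c("outer-epidermal", "epidermal-other", "cortex", "outer-endodermal",
    "inner-endodermal", "pericycle-stele")
}

wall_class <- function(t1, t2) {
  is_epi <- function(t) !is.na(t) && grepl("epidermis", t)
  ts <- c(t1, t2)
  if (is.na(t2)) {
    return(if (is_epi(t1)) "outer-epidermal" else "outer-epidermal")
  }
  if (is_epi(t1) || is_epi(t2)) return("epidermal-other")
  if (setequal(ts, c("cortex", "endodermis"))) return("outer-endodermal")
  if (setequal(ts, c("endodermis", "pericycle"))) return("inner-endodermal")
  if ("cortex" %in% ts) return("cortex")
  "pericycle-stele"
}

#' Validate a cross-section mesh
#'
#' Checks that every cell polygon is simple and counter-clockwise, that
#' every internal wall is shared by exactly two cells and every boundary
#' wall by one, and that all walls have positive length.
#'
#' @param mesh A `cross_section_mesh`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "cross_section_mesh"))
  areas <- cell_areas(mesh)
  if (any(areas <= 0)) {
    stop("generation error: cell polygon not counter-clockwise or degenerate")
  }
  for (ci in seq_along(mesh$cells)) {
    if (!polygon_is_simple(mesh$vertices[mesh$cells[[ci]], , drop = FALSE])) {
      stop(sprintf("generation error: cell %d polygon self-intersects", ci))
    }
  }
  nshare <- ifelse(is.na(mesh$walls$cell2), 1L, 2L)
  if (any(nshare < 1 | nshare > 2)) {
    stop("generation error: wall sharing violated")
  }
  len <- wall_lengths(mesh)
  if (any(len <= 1e-12)) stop("generation error: zero-length wall")
  invisible(TRUE)
}

wall_lengths <- function(mesh) {
  v <- mesh$vertices
  sqrt(rowSums((v[mesh$walls$v1, , drop = FALSE] -
                  v[mesh$walls$v2, , drop = FALSE])^2))
}

# Shoelace signed area of each cell polygon (positive = CCW).
cell_areas <- function(mesh) {
  vapply(mesh$cells, function(loop) {
    p <- mesh$vertices[loop, , drop = FALSE]
    x <- p[, 1]; y <- p[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    sum(x * yn - xn * y) / 2
  }, numeric(1))
}

# O(n^2) segment-intersection simplicity test; polygons here are small.
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- a[3:4] - a[1:2]; d2 <- b[3:4] - b[1:2]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((b[1] - a[1]) * d2[2] - (b[2] - a[2]) * d2[1]) / den
    u <- ((b[1] - a[1]) * d1[2] - (b[2] - a[2]) * d1[1]) / den
    eps <- 1e-10
    t > eps && t < 1 - eps && u > eps && u < 1 - eps
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Per-tissue cross-section areas
#'
#' Sums shoelace polygon areas of all cells of each tissue.
#'
#' @param mesh A `cross_section_mesh`.
#' @return Named numeric of per-tissue areas (um^2), with attributes
#'   `total` (um^2), `inner` (endodermis + pericycle + stele) and `outer`
#'   (epidermis + cortex).
#' @export
tissue_areas <- function(mesh) {
  stopifnot(inherits(mesh, "cross_section_mesh"))
  areas <- cell_areas(mesh)
  if (any(areas <= 0)) stop("geometry error: non-positive cell area")
  per <- tapply(areas, mesh$tissue, sum)
  per <- setNames(as.numeric(per), names(per))
  inner_t <- c("endodermis", "pericycle", "stele")
  outer_t <- setdiff(names(per), inner_t)
  attr(per, "total") <- sum(areas)
  attr(per, "inner") <- sum(per[intersect(names(per), inner_t)])
  attr(per, "outer") <- sum(per[outer_t])
  per
}

#' Normalize a series of radial area profiles to its first entry
#'
#' @param x Numeric vector (or matrix with sections in rows) of areas along
#'   the meristem; the first section is the reference.
#' @return `x` divided element-wise by its first entry (or row).
#' @export
normalize_profile <- function(x) {
  if (is.matrix(x)) {
    sweep(x, 2, x[1, ], "/")
  } else {
    x / x[1]
  }
}

#' Write a cross-section mesh to JSON
#'
#' Serializes vertices (id, x, y in um), walls (id, vertex pair, wall class,
#' rest length) and cells (id, ordered wall loop, tissue).
#'
#' @param mesh A `cross_section_mesh`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_mesh_json <- function(mesh, path) {
  stopifnot(inherits(mesh, "cross_section_mesh"))
  wkey <- paste(pmin(mesh$walls$v1, mesh$walls$v2),
                pmax(mesh$walls$v1, mesh$walls$v2))
  cell_wall_loops <- lapply(mesh$cells, function(loop) {
    nb <- c(loop[-1], loop[1])
    match(paste(pmin(loop, nb), pmax(loop, nb)), wkey)
  })
  obj <- list(
    vertices = data.frame(id = seq_len(nrow(mesh$vertices)),
                          x = mesh$vertices[, 1], y = mesh$vertices[, 2]),
    walls = data.frame(id = seq_len(nrow(mesh$walls)),
                       v1 = mesh$walls$v1, v2 = mesh$walls$v2,
                       wall_class = mesh$walls$class,
                       rest_length = mesh$walls$rest_length),
    cells = lapply(seq_along(mesh$cells), function(ci) {
      list(id = ci, walls = cell_wall_loops[[ci]],
           tissue = mesh$tissue[ci])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cross-section mesh from JSON
#'
#' Inverse of [write_mesh_json()]. Cell vertex loops are reconstructed from
#' the ordered wall loops and re-oriented counter-clockwise.
#'
#' @param path JSON file path.
#' @return A `cross_section_mesh`.
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  verts <- as.matrix(obj$vertices[order(obj$vertices$id), c("x", "y")])
  dimnames(verts) <- NULL
  wdf <- obj$walls[order(obj$walls$id), ]
  cells_raw <- obj$cells
  if (is.data.frame(cells_raw)) {
    loops_w <- cells_raw$walls
    tiss <- cells_raw$tissue
    ord <- order(cells_raw$id)
    loops_w <- loops_w[ord]; tiss <- tiss[ord]
  } else {
    loops_w <- lapply(cells_raw, function(c) unlist(c$walls))
    tiss <- vapply(cells_raw, function(c) c$tissue, character(1))
  }
  cells <- lapply(loops_w, function(wids) {
    a <- wdf$v1[wids]; b <- wdf$v2[wids]
    n <- length(wids)
    loop <- integer(n)
    # orient the first wall so that it chains into the second
    if (a[1] %in% c(a[2], b[2])) {
      loop[1] <- b[1]; cur <- a[1]
    } else {
      loop[1] <- a[1]; cur <- b[1]
    }
    for (k in 2:n) {
      loop[k] <- cur
      cur <- if (a[k] == cur) b[k] else a[k]
    }
    p <- verts[loop, , drop = FALSE]
    x <- p[, 1]; y <- p[, 2]
    s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    if (s < 0) loop <- rev(loop)
    loop
  })
  mesh <- build_mesh(verts, cells, tiss)
  # preserve stored rest lengths (walls were rebuilt in the same v-pair keying)
  key_new <- paste(mesh$walls$v1, mesh$walls$v2)
  key_old <- paste(pmin(wdf$v1, wdf$v2), pmax(wdf$v1, wdf$v2))
  if (!is.null(wdf$rest_length)) {
    mesh$walls$rest_length <- wdf$rest_length[match(key_new, key_old)]
  }
  if (!is.null(wdf$wall_class)) {
    mesh$walls$class <- wdf$wall_class[match(key_new, key_old)]
  }
  validate_mesh(mesh)
  mesh
}

#' @export
print.cross_section_mesh <- function(x, ...) {
  per <- table(x$tissue)
  cat("cross_section_mesh:", length(x$cells), "cells,",
      nrow(x$vertices), "vertices,", nrow(x$walls), "walls\n")
  cat("  cells per tissue:",
      paste(sprintf("%s=%d", names(per), as.integer(per)), collapse = ", "),
      "\n")
  cat(sprintf("  total area: %.1f um^2\n", sum(cell_areas(x))))
  invisible(x)
}

#' @export
plot.cross_section_mesh <- function(x, col_by = c("tissue", "class"), ...) {
  col_by <- match.arg(col_by)
  v <- x$vertices
  plot(v, type = "n", asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  tiss <- factor(x$tissue)
  cols <- grDevices::hcl.colors(nlevels(tiss), "Set 2")[as.integer(tiss)]
  for (ci in seq_along(x$cells)) {
    p <- v[x$cells[[ci]], , drop = FALSE]
    graphics::polygon(p[, 1], p[, 2], col = cols[ci], border = "grey30")
  }
  invisible(x)
}
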