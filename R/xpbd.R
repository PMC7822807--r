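#' Solver configuration
#'
#' Hyper-parameters of the XPBD time stepper. Defaults are standard cloth
#' settings that keep the synthetic fixtures stable: `dt = 1e-3` s split into
#' 4 substeps, 20 nonlinear Gauss--Seidel sweeps per substep, velocity damping
#' 0.1 per substep, and a 0.5 mm contact thickness.
#'
#' @param dt step size in seconds.
#' @param substeps number of substeps per step.
#' @param iterations Gauss--Seidel sweeps per substep.
#' @param damping velocity loss per step, in `[0, 1]`; applied as an
#'   equivalent per-substep factor at each velocity update.
#' @param contact_thickness collision thickness h in mm; vertex--triangle
#'   pairs closer than h are pushed apart.
#' @param steady_tol steady-state tolerance: maximum per-vertex displacement
#'   per step (mm) below which the scene counts as quiescent.
#' @param steady_window number of consecutive quiescent steps required to
#'   declare steady state.
#' @param max_steps step cap for [simulate_until_steady()].
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 1e-3, substeps = 4L, iterations = 20L,
                          damping = 0.1, contact_thickness = 0.5,
                          steady_tol = 2e-4, steady_window = 25L,
                          max_steps = 4000L) {
  stopifnot(dt > 0, substeps >= 1, iterations >= 1,
            damping >= 0, damping <= 1, contact_thickness > 0,
            steady_tol > 0, steady_window >= 1, max_steps >= 1)
  structure(list(dt = dt, substeps = as.integer(substeps),
                 iterations = as.integer(iterations), damping = damping,
                 contact_thickness = contact_thickness,
                 steady_tol = steady_tol,
                 steady_window = as.integer(steady_window),
                 max_steps = as.integer(max_steps)),
            class = "solver_config")
}

#' Force-field configuration for one cardiac phase
#'
#' The external load is a pressure field acting along per-vertex surface
#' normals plus a velocity field realized as linear drag toward a uniform
#' target flow along the annulus-plane normal:
#' `f_i = s * P * A_i * n_i + gamma * m_i * (s * target_speed * (-n_AP) - v_i)`.
#' Switching between systole (closing, `phase_sign = +1`) and diastole
#' (opening, `-1`) only flips the sign `s`; see [switch_phase()].
#'
#' @param pressure pressure magnitude P (force per mm^2, model units).
#' @param velocity_gain drag coefficient gamma (1/s) toward the target flow.
#' @param target_speed target flow speed (mm/s) along the annulus normal
#'   axis; with the sign convention above, a negative value makes the
#'   closing-phase flow run ventricle-to-atrium, the direction that carries
#'   the leaflets toward closure.
#' @param phase_sign `+1` for closing (systole), `-1` for opening (diastole).
#' @return An object of class `force_phase`.
#' @export
force_phase <- function(pressure = 1500, velocity_gain = 20,
                        target_speed = -40, phase_sign = 1) {
  stopifnot(pressure >= 0, velocity_gain >= 0, phase_sign %in% c(-1, 1))
  structure(list(pressure = pressure, velocity_gain = velocity_gain,
                 target_speed = target_speed, phase_sign = phase_sign),
            class = "force_phase")
}

#' Material compliances for the leaflet constraint set
#'
#' XPBD compliance (inverse stiffness) per constraint family. `0` means rigid
#' (hard constraint). Leaflet tissue is modeled nearly inextensible with soft
#' bending.
#'
#' @param distance compliance of edge distance constraints.
#' @param bending compliance of dihedral-angle constraints.
#' @param area compliance of per-triangle area constraints.
#' @return A list of class `material_params`.
#' @export
material_params <- function(distance = 1e-8, bending = 3e-4, area = 0) {
  stopifnot(distance >= 0, bending >= 0, area >= 0)
  structure(list(distance = distance, bending = bending, area = area),
            class = "material_params")
}

#' Build the leaflet constraint set from a mesh
#'
#' One distance constraint per unique mesh edge (rest length = initial
#' endpoint distance), one dihedral bending constraint per interior
#' (two-triangle) edge (rest angle = initial dihedral, pi when flat), and one
#' area constraint per triangle (rest area = initial area).
#'
#' @param mesh a [valve_mesh()].
#' @param material a [material_params()].
#' @return A list of class `constraint_set` with data frames `distance`
#'   (i, j, l0, alpha), `bending` (i, j, k, l, phi0, alpha; i--j the shared
#'   edge, k/l the opposite vertices) and `area` (i, j, k, a0, alpha).
#' @export
build_constraints <- function(mesh, material = material_params()) {
  stopifnot(inherits(mesh, "valve_mesh"))
  pos <- mesh$positions
  tri <- mesh$triangles

  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  tri_of_edge <- rep(seq_len(nrow(tri)), 3L)
  opp <- c(tri[, 3], tri[, 1], tri[, 2])     # vertex opposite each edge
  i <- pmin(e[, 1], e[, 2]); j <- pmax(e[, 1], e[, 2])
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; opp <- opp[ord]; tri_of_edge <- tri_of_edge[ord]
  key <- paste(i, j)
  first <- !duplicated(key)
  counts <- as.integer(table(key)[key[first]])
  if (any(counts > 2L)) {
    b <- which(counts > 2L)[1]
    stop("build_constraints: non-manifold edge (", i[first][b], ", ",
         j[first][b], ") with ", counts[b], " incident triangles")
  }

  ui <- i[first]; uj <- j[first]
  l0 <- sqrt(rowSums((pos[ui, , drop = FALSE] - pos[uj, , drop = FALSE])^2))
  distance <- data.frame(i = ui, j = uj, l0 = l0,
                         alpha = material$distance)

  interior <- counts == 2L
  if (any(interior)) {
    # for each interior edge, the two opposite vertices in edge-sorted order
    dup <- duplicated(key)
    opp2 <- opp[dup][match(key[first][interior], key[dup])]
    bi <- ui[interior]; bj <- uj[interior]
    bk <- opp[first][interior]; bl <- opp2
    phi0 <- vapply(seq_along(bi), function(q) {
      cpp_dihedral_angle(pos[c(bi[q], bj[q], bk[q], bl[q]), , drop = FALSE])
    }, numeric(1))
    bending <- data.frame(i = bi, j = bj, k = bk, l = bl, phi0 = phi0,
                          alpha = material$bending)
  } else {
    bending <- data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), phi0 = numeric(), alpha = numeric())
  }

  area <- data.frame(i = tri[, 1], j = tri[, 2], k = tri[, 3],
                     a0 = triangle_areas(pos, tri),
                     alpha = material$area)

  structure(list(distance = distance, bending = bending, area = area),
            class = "constraint_set")
}

#' Per-vertex normals and lumped areas
#'
#' The vertex normal is the normalized area-weighted mean of incident triangle
#' normals; the lumped vertex area is one third of the incident triangle
#' areas, so lumped areas sum exactly to the total surface area.
#'
#' @param pos n x 3 vertex positions.
#' @param triangles m x 3 triangle index matrix (1-based).
#' @return A list with `normals` (n x 3, unit rows where area > 0), `areas`
#'   (length n, mm^2) and `total_area`.
#' @export
vertex_normals_and_areas <- function(pos, triangles) {
  cpp_vertex_normals_areas(as_matrix3(pos, "pos"),
                           matrix(as.integer(triangles), ncol = 3L))
}

#' External pressure and velocity-field forces
#'
#' Evaluates `f_i = s * P * A_i * n_i + gamma * m_i * (s * v_t * (-n_AP) - v_i)`
#' per vertex; Dirichlet vertices (inverse mass 0) receive zero force.
#'
#' @param state a [sim_state()].
#' @param mesh a [valve_mesh()] (connectivity only; positions from `state`).
#' @param phase a [force_phase()].
#' @param plane an oriented [fit_annulus_plane()] result.
#' @return n x 3 matrix of forces.
#' @export
external_forces <- function(state, mesh, phase, plane) {
  na <- vertex_normals_and_areas(state$pos, mesh$triangles)
  s <- phase$phase_sign
  f <- s * phase$pressure * na$areas * na$normals
  if (phase$velocity_gain > 0) {
    m <- ifelse(state$inv_mass > 0, 1 / state$inv_mass, 0)
    vt <- matrix(s * phase$target_speed * (-plane$normal), nrow(f), 3,
                 byrow = TRUE)
    f <- f + phase$velocity_gain * m * (vt - state$vel)
  }
  f[state$inv_mass == 0, ] <- 0
  f
}

#' Detect vertex--triangle proximity constraints
#'
#' One transient collision constraint per (vertex, non-incident triangle) pair
#' whose exact point--triangle distance is below the contact thickness `h`,
#' found with a uniform spatial hash (cell size >= h). The result equals the
#' brute-force all-pairs scan.
#'
#' @param pos n x 3 vertex positions.
#' @param triangles m x 3 triangle indices (1-based).
#' @param h contact thickness (mm, > 0).
#' @return Integer matrix with columns `vertex`, `triangle`, ordered by
#'   (triangle, vertex); zero rows when nothing is in proximity.
#' @export
detect_collisions <- function(pos, triangles, h) {
  stopifnot(h > 0)
  cpp_detect_collisions(as_matrix3(pos, "pos"),
                        matrix(as.integer(triangles), ncol = 3L), h)
}

#' Simulation state
#'
#' Time-dependent per-vertex positions, velocities and inverse masses.
#' Dirichlet vertices (the annulus ring) carry inverse mass exactly 0 and
#' follow the prescribed annulus interpolation; all free vertices have unit
#' mass.
#'
#' @param mesh a [valve_mesh()]; positions initialize the state.
#' @param dirichlet_ids vertex indices with prescribed motion (defaults to the
#'   mesh annulus ring).
#' @return An object of class `sim_state` with fields `pos`, `vel`,
#'   `inv_mass`, `t`, `dirichlet_ids`.
#' @export
sim_state <- function(mesh, dirichlet_ids = mesh$annulus_ids) {
  n <- nrow(mesh$positions)
  inv_mass <- rep(1, n)
  inv_mass[dirichlet_ids] <- 0
  structure(list(pos = mesh$positions,
                 vel = matrix(0, n, 3),
                 inv_mass = inv_mass,
                 t = 0,
                 dirichlet_ids = as.integer(dirichlet_ids)),
            class = "sim_state")
}

#' Project a single constraint (XPBD update)
#'
#' One XPBD projection `dlambda = (-C - at*lambda) / (sum_k w_k |grad_k C|^2 + at)`
#' with `at = alpha / dt^2`; vertices with inverse mass 0 never move. Cord and
#' collision constraints are one-sided. This is the same compiled kernel the
#' solver loop uses, exposed for verification.
#'
#' @param c a constraint: a list with a `type` in
#'   `"distance"`, `"bending"`, `"area"`, `"cord"`, `"collision"` and the
#'   fields that type needs (see Details).
#' @param positions matrix of the participating vertex positions, one row per
#'   vertex in constraint order (for `"cord"`: the single leaflet vertex; the
#'   tip is `c$tip`).
#' @param w inverse masses matching `positions` rows.
#' @param dt substep size (s).
#' @param lambda accumulated multiplier (0 at substep start).
#' @return list with updated `positions` (same shape) and `lambda`.
#' @details Required fields by type: distance: `l0`, `alpha`; bending: `phi0`,
#'   `alpha` (rows ordered shared-edge i, j then opposite k, l); area: `a0`,
#'   `alpha`; cord: `tip` (length-3), `l0`, `alpha`; collision: rows ordered
#'   vertex then triangle a, b, c, plus `h`.
#' @export
project_constraint <- function(c, positions, w, dt, lambda = 0) {
  positions <- as_matrix3(positions, "positions")
  switch(c$type,
    distance = cpp_project_distance(positions, w, c$l0, c$alpha, dt, lambda),
    bending = cpp_project_bending(positions, w, c$phi0, c$alpha, dt, lambda),
    area = cpp_project_area(positions, w, c$a0, c$alpha, dt, lambda),
    cord = {
      r <- cpp_project_cord(c$tip, positions[1, ], w[1], c$l0, c$alpha, dt, lambda)
      list(positions = matrix(r$position, 1, 3), lambda = r$lambda)
    },
    collision = {
      r <- cpp_project_collision(positions[1, ], positions[2:4, , drop = FALSE],
                                 w, c$h, lambda)
      r
    },
    stop("unknown constraint type: ", c$type))
}

## --- mirror pairing ---------------------------------------------------------

# Vertex and triangle permutations of the x-z mirror image, or NULL when the
# mesh is not (numerically) mirror-symmetric.
mirror_permutation <- function(pos, triangles, tol = 1e-6) {
  pm <- pos
  pm[, 2] <- -pm[, 2]
  key <- function(m) sprintf("%.3f|%.3f|%.3f", m[, 1], m[, 2], m[, 3])
  vm <- match(key(pm), key(pos))
  # verify the hash join (and resolve boundary-rounding misses exactly)
  for (v in which(is.na(vm) |
                  sqrt(rowSums((pos[ifelse(is.na(vm), 1L, vm), , drop = FALSE] -
                                  pm)^2)) > tol)) {
    d2 <- colSums((t(pos) - pm[v, ])^2)
    j <- which.min(d2)
    if (d2[j] > tol^2) return(NULL)
    vm[v] <- j
  }
  if (any(vm[vm] != seq_along(vm))) return(NULL)
  key <- function(tr) apply(tr, 1, function(r) paste(sort(r), collapse = "-"))
  k0 <- key(triangles)
  km <- key(matrix(vm[triangles], ncol = 3))
  tm <- match(km, k0)
  if (anyNA(tm)) return(NULL)
  list(vertex = vm, triangle = tm)
}

# Row order placing each constraint next to its mirror image, plus a flag
# marking the first member of each adjacent pair. Constraints are encoded by
# their sorted vertex-index set; the pair's canonical member comes first. The
# solver projects both members of a pair from the same state and applies the
# corrections together, which keeps the sweep exactly mirror-equivariant
# (and is bit-identical to plain Gauss-Seidel when the pair shares no
# vertex).
pair_order <- function(index_matrix, mirror_vertex, n) {
  if (nrow(index_matrix) == 0)
    return(list(order = integer(), pair = integer()))
  enc <- function(M) {
    Ms <- t(apply(M, 1, sort))
    b <- n + 1
    drop(Ms %*% b^(seq_len(ncol(Ms)) - 1))
  }
  k1 <- enc(index_matrix)
  k2 <- enc(matrix(mirror_vertex[as.matrix(index_matrix)],
                   ncol = ncol(index_matrix)))
  ord <- order(pmin(k1, k2), k1 > k2)
  canon <- pmin(k1, k2)[ord]
  second <- (k1 > k2)[ord]
  m <- length(ord)
  pair <- integer(m)
  if (m > 1) {
    first_of_pair <- canon[-m] == canon[-1] & !second[-m] & second[-1]
    pair[which(first_of_pair)] <- 1L
  }
  list(order = ord, pair = pair)
}

# Reorder all permanent constraints of a constraint_set for a symmetric
# scene; attaches the per-family pair flags as attributes.
pair_order_constraints <- function(constraints, mirror_vertex, n) {
  od <- pair_order(as.matrix(constraints$distance[, c("i", "j")]),
                   mirror_vertex, n)
  constraints$distance <- constraints$distance[od$order, , drop = FALSE]
  attr(constraints$distance, "pair") <- od$pair
  ob <- pair_order(as.matrix(constraints$bending[, c("i", "j", "k", "l")]),
                   mirror_vertex, n)
  constraints$bending <- constraints$bending[ob$order, , drop = FALSE]
  attr(constraints$bending, "pair") <- ob$pair
  oa <- pair_order(as.matrix(constraints$area[, c("i", "j", "k")]),
                   mirror_vertex, n)
  constraints$area <- constraints$area[oa$order, , drop = FALSE]
  attr(constraints$area, "pair") <- oa$pair
  constraints
}

## --- stepping ---------------------------------------------------------------

# Internal: one call into the compiled loop. `scene` supplies connectivity,
# contour, cords; `state` the positions; returns list(state, log, converged).
xpbd_run <- function(state, scene, constraints, phase, config,
                     n_steps, steady = FALSE) {
  cords <- scene$cords
  ct <- cord_table(cords)
  tips <- tip_keyframes(cords)
  if (!is.null(scene$mirror)) {
    constraints <- pair_order_constraints(constraints, scene$mirror$vertex,
                                          nrow(state$pos))
    mv <- scene$mirror$vertex
    mf <- scene$mirror$triangle
  } else {
    mv <- integer()
    mf <- integer()
  }
  pair_of <- function(df) {
    pr <- attr(df, "pair")
    if (is.null(pr)) integer() else as.integer(pr)
  }
  cord_pair <- integer()
  if (!is.null(scene$mirror) && length(ct$vertex) > 0) {
    # cord (tip, v) mirrors to (other tip, mirror(v))
    n <- nrow(state$pos)
    k1 <- ct$tip_index * (n + 1) + ct$vertex
    k2 <- (3L - ct$tip_index) * (n + 1) + mv[ct$vertex]
    co <- order(pmin(k1, k2), k1 > k2)
    ct <- lapply(ct, function(x) x[co])
    canon <- pmin(k1, k2)[co]; second <- (k1 > k2)[co]
    m <- length(co)
    cord_pair <- integer(m)
    if (m > 1)
      cord_pair[which(canon[-m] == canon[-1] & !second[-m] & second[-1])] <- 1L
  }
  res <- cpp_xpbd_run(
    state$pos, state$vel, state$inv_mass, state$t,
    scene$mesh$triangles,
    as.matrix(constraints$distance[, c("i", "j")]),
    constraints$distance$l0, constraints$distance$alpha,
    as.matrix(constraints$bending[, c("i", "j", "k", "l")]),
    constraints$bending$phi0, constraints$bending$alpha,
    as.matrix(constraints$area[, c("i", "j", "k")]),
    constraints$area$a0, constraints$area$alpha,
    ct$tip_index, ct$vertex, ct$rest_length, ct$compliance,
    tips$open, tips$closed,
    scene$mesh$annulus_ids, scene$contour$open, scene$contour$closed,
    scene$contour$close_duration,
    phase$phase_sign, phase$pressure, phase$velocity_gain,
    phase$target_speed, scene$plane$normal,
    config$dt, config$substeps, config$iterations, config$damping,
    config$contact_thickness,
    as.integer(n_steps),
    if (steady) config$steady_tol else 0,
    if (steady) config$steady_window else 0L,
    mv, mf,
    pair_of(constraints$distance), pair_of(constraints$bending),
    pair_of(constraints$area), cord_pair)
  state$pos <- res$pos
  state$vel <- res$vel
  state$t <- res$t
  log <- as.data.frame(res$log)
  names(log) <- c("step", "time", "max_displacement", "total_area", "contacts")
  list(state = state, log = log, converged = res$converged, steps = res$steps)
}

#' Advance the simulation by a fixed number of steps
#'
#' Each step runs `substeps` substeps of: (1) set Dirichlet positions from the
#' annulus interpolation and papillary tip trajectories; (2) semi-implicit
#' Euler predictor under the external forces; (3) reset multipliers and run
#' `iterations` Gauss--Seidel sweeps over distance, bending, area, cord and
#' freshly detected collision constraints, in that fixed order; (4) velocity
#' update `(pos_new - pos_old)/dt` scaled by `1 - damping`. Deterministic:
#' identical inputs give bit-identical outputs.
#'
#' @param state a [sim_state()].
#' @param scene a `valve_scene` (see [generate_scene()] or [load_scene()]).
#' @param constraints a [build_constraints()] result.
#' @param phase a [force_phase()].
#' @param config a [solver_config()].
#' @param n_steps number of steps to advance.
#' @return list with the advanced `state`, the per-step convergence `log`
#'   data frame (step, time, max_displacement, total_area, contacts).
#' @export
sim_step <- function(state, scene, constraints, phase, config = solver_config(),
                     n_steps = 1L) {
  xpbd_run(state, scene, constraints, phase, config, n_steps, steady = FALSE)
}

#' Simulate until steady state
#'
#' Steps the scene until the maximum per-vertex displacement per step stays
#' below `config$steady_tol` for `config$steady_window` consecutive steps, or
#' `config$max_steps` is reached (flagged, not an error).
#'
#' @inheritParams sim_step
#' @param state optional starting [sim_state()]; defaults to the open state.
#' @return An object of class `mv_simulation`: fields `state`, `log`,
#'   `converged`, `scene`, `phase`, `config`.
#' @export
simulate_until_steady <- function(scene, phase = force_phase(),
                                  config = solver_config(),
                                  state = sim_state(scene$mesh),
                                  constraints = build_constraints(scene$mesh,
                                                                  scene$material)) {
  res <- xpbd_run(state, scene, constraints, phase, config,
                  config$max_steps, steady = TRUE)
  structure(list(state = res$state, log = res$log, converged = res$converged,
                 scene = scene, phase = phase, config = config,
                 constraints = constraints),
            class = "mv_simulation")
}

#' Simulate valve closure (and optionally reopening)
#'
#' Convenience driver: closes the valve from the open state to steady state
#' under the closing phase; with `cycle = TRUE` it then flips the force fields
#' and runs the opening phase to steady state as well, returning both
#' segments' logs concatenated.
#'
#' @inheritParams simulate_until_steady
#' @param cycle if `TRUE`, run a full close--open cycle: after the closing
#'   phase reaches steady state, the force fields are switched and the
#'   opening phase runs with the same step budget the closing phase used
#'   (reopened leaflets keep a small contact flutter that need not fall
#'   below the steady tolerance).
#' @return An `mv_simulation` object; with `cycle = TRUE` it gains fields
#'   `converged_close` / `converged_open` and `converged` reports the
#'   closing phase.
#' @export
simulate_valve <- function(scene, phase = force_phase(),
                           config = solver_config(), cycle = FALSE) {
  constraints <- build_constraints(scene$mesh, scene$material)
  sim <- simulate_until_steady(scene, phase, config,
                               constraints = constraints)
  if (cycle) {
    phase2 <- switch_phase(phase)
    res2 <- xpbd_run(sim$state, scene, constraints, phase2, config,
                     nrow(sim$log), steady = TRUE)
    res2$log$step <- res2$log$step + nrow(sim$log)
    sim$converged_close <- sim$converged
    sim$converged_open <- res2$converged
    sim$state <- res2$state
    sim$log <- rbind(sim$log, res2$log)
  }
  sim
}

#' @export
print.mv_simulation <- function(x, ...) {
  cat(sprintf("mv_simulation: %d steps to t = %.3f s, %s\n",
              nrow(x$log), x$state$t,
              if (x$converged) "converged" else "step cap reached"))
  a0 <- x$log$total_area[1]; a1 <- x$log$total_area[nrow(x$log)]
  cat(sprintf("  total area %.1f -> %.1f mm^2 (%+.2f%%), %d contacts at end\n",
              a0, a1, 100 * (a1 - a0) / a0,
              x$log$contacts[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.mv_simulation <- function(object, ...) {
  log <- object$log
  out <- list(
    steps = nrow(log), t_end = object$state$t, converged = object$converged,
    area_initial = log$total_area[1],
    area_final = log$total_area[nrow(log)],
    max_displacement_final = log$max_displacement[nrow(log)],
    contacts_final = log$contacts[nrow(log)])
  class(out) <- "summary.mv_simulation"
  out
}

#' @export
print.summary.mv_simulation <- function(x, ...) {
  cat(sprintf(paste0(
    "XPBD valve simulation\n",
    "  steps: %d (t = %.3f s), converged: %s\n",
    "  surface area: %.1f -> %.1f mm^2 (drift %.3f%%)\n",
    "  final max displacement/step: %.2e mm; active contacts: %d\n"),
    x$steps, x$t_end, x$converged, x$area_initial, x$area_final,
    100 * abs(x$area_final - x$area_initial) / x$area_initial,
    x$max_displacement_final, x$contacts_final))
  invisible(x)
}

#' @export
plot.mv_simulation <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(log$step, log$max_displacement, type = "l", log = "y",
                 xlab = "step", ylab = "max displacement [mm]",
                 main = "convergence", ...)
  graphics::plot(log$step, log$total_area, type = "l",
                 xlab = "step", ylab = "total area [mm^2]",
                 main = "area conservation", ...)
  invisible(x)
}
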