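test_that("constraint construction counts follow mesh combinatorics", {
  tri1 <- toy_scene(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1L, 2L, 3L)))
  cs1 <- build_constraints(tri1$mesh)
  expect_equal(nrow(cs1$distance), 3)
  expect_equal(nrow(cs1$area), 1)
  expect_equal(nrow(cs1$bending), 0)

  q <- flat_quad()
  cs2 <- build_constraints(toy_scene(q$pos, q$tri)$mesh)
  expect_equal(nrow(cs2$distance), 5)
  expect_equal(nrow(cs2$area), 2)
  expect_equal(nrow(cs2$bending), 1)
  expect_equal(cs2$bending$phi0, pi)              # coplanar faces are flat
  expect_equal(cs2$distance$l0[1],
               sqrt(sum((q$pos[1, ] - q$pos[2, ])^2)))
})

test_that("dihedral rest angles match an independent hinge-angle oracle", {
  set.seed(11)
  for (rep in 1:20) {
    P <- matrix(rnorm(12), 4, 3)
    ang <- mitralsim:::cpp_dihedral_angle(P)
    if (is.na(ang)) next
    expect_equal(ang, bf_dihedral(P), tolerance = 1e-9)
  }
})

test_that("vertex normals and lumped areas partition the surface", {
  p <- flat_patch(4, 4, d = 1)
  na <- vertex_normals_and_areas(p$pos, p$tri)
  expect_true(all(abs(abs(na$normals[, 3]) - 1) < 1e-12))
  expect_equal(sum(na$areas), 9)                 # 3x3 unit squares
  expect_equal(na$total_area, sum(na$areas), tolerance = 1e-12)

  s <- uv_sphere(r = 2, nu = 16, nv = 10)
  ns <- vertex_normals_and_areas(s$pos, s$tri)
  radial <- s$pos / sqrt(rowSums(s$pos^2))
  ang <- acos(pmin(1, abs(rowSums(ns$normals * radial))))
  expect_lt(max(ang), 0.2)                       # near-radial on a sphere
})

test_that("external force field follows the stated formula", {
  p <- flat_patch(3, 3, d = 1)
  sc <- toy_scene(p$pos, p$tri)
  st <- sim_state(sc$mesh, dirichlet_ids = integer())

  f0 <- external_forces(st, sc$mesh, force_phase(pressure = 0, velocity_gain = 0),
                        sc$plane)
  expect_true(all(f0 == 0))

  ph <- force_phase(pressure = 10, velocity_gain = 0, phase_sign = 1)
  f1 <- external_forces(st, sc$mesh, ph, sc$plane)
  na <- vertex_normals_and_areas(st$pos, sc$mesh$triangles)
  expect_equal(f1[, 3], 10 * na$areas * na$normals[, 3])
  expect_true(all(abs(f1[, 1:2]) < 1e-12))

  # drag equilibrium: velocity already at the target flow
  ph2 <- force_phase(pressure = 0, velocity_gain = 5, target_speed = -30)
  st2 <- st
  st2$vel <- matrix(rep(1 * 30 * sc$plane$normal, each = nrow(st$pos)),
                    ncol = 3)
  f2 <- external_forces(st2, sc$mesh, ph2, sc$plane)
  expect_lt(max(abs(f2)), 1e-9)
})

test_that("distance projection matches the closed-form PBD oracle", {
  p1 <- c(0, 0, 0); p2 <- c(2, 0, 0)      # twice the rest length apart
  r <- project_constraint(list(type = "distance", l0 = 1, alpha = 0),
                          rbind(p1, p2), w = c(1, 1), dt = 0.01)
  expect_equal(sqrt(sum((r$positions[1, ] - r$positions[2, ])^2)), 1,
               tolerance = 1e-12)
  oracle <- bf_distance_projection(p1, p2, 1, 1, 1)
  expect_equal(r$positions[1, ], oracle$p1, tolerance = 1e-12)
  expect_equal(r$positions[2, ], oracle$p2, tolerance = 1e-12)

  # satisfied constraint: zero correction
  r0 <- project_constraint(list(type = "distance", l0 = 2, alpha = 0),
                           rbind(p1, p2), w = c(1, 1), dt = 0.01)
  expect_identical(r0$positions, unname(rbind(p1, p2)))

  # pinned endpoint takes no correction; the free one takes all of it
  rp <- project_constraint(list(type = "distance", l0 = 1, alpha = 0),
                           rbind(p1, p2), w = c(0, 1), dt = 0.01)
  expect_identical(rp$positions[1, ], p1)
  op <- bf_distance_projection(p1, p2, 0, 1, 1)
  expect_equal(rp$positions[2, ], op$p2, tolerance = 1e-12)
})

test_that("randomized single projections satisfy their constraints", {
  set.seed(7)
  for (rep in 1:25) {
    P <- matrix(rnorm(6, sd = 2), 2, 3)
    l0 <- runif(1, 0.5, 2)
    r <- project_constraint(list(type = "distance", l0 = l0, alpha = 0),
                            P, w = runif(2, 0.5, 2), dt = 0.01)
    expect_equal(sqrt(sum((r$positions[1, ] - r$positions[2, ])^2)), l0,
                 tolerance = 1e-9)

    Pa <- matrix(rnorm(9), 3, 3)
    a0 <- runif(1, 0.2, 1)
    ra <- project_constraint(list(type = "area", a0 = a0, alpha = 0),
                             Pa, w = rep(1, 3), dt = 0.01)
    # one Newton-like projection moves the area toward a0
    area_new <- mitralsim:::triangle_areas(ra$positions, rbind(1:3))
    area_old <- mitralsim:::triangle_areas(Pa, rbind(1:3))
    expect_lt(abs(area_new - a0), abs(area_old - a0) + 1e-12)
  }
})

test_that("bending projection reduces the angle error with the standard gradient", {
  set.seed(3)
  for (rep in 1:15) {
    P <- matrix(rnorm(12), 4, 3)
    phi <- mitralsim:::cpp_dihedral_angle(P)
    if (is.na(phi)) next
    phi0 <- runif(1, 0.2, pi - 0.2)
    r <- project_constraint(list(type = "bending", phi0 = phi0, alpha = 0),
                            P, w = rep(1, 4), dt = 0.01)
    phi_new <- mitralsim:::cpp_dihedral_angle(r$positions)
    expect_lt(abs(phi_new - phi0), abs(phi - phi0) + 1e-12)
  }
})

test_that("collision detection equals brute force and honors thickness", {
  # two parallel patches far apart: nothing detected
  a <- flat_patch(3, 3, d = 2, z = 0)
  b <- flat_patch(3, 3, d = 2, z = 5)
  pos <- rbind(a$pos, b$pos)
  tri <- rbind(a$tri, b$tri + nrow(a$pos))
  expect_equal(nrow(detect_collisions(pos, tri, h = 0.5)), 0)

  # vertex hovering h/2 above a triangle interior: exactly one pair
  tpos <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(1, 1, 0.25))
  ttri <- rbind(c(1L, 2L, 3L))
  hits <- detect_collisions(tpos, ttri, h = 0.5)
  expect_equal(nrow(hits), 1)
  expect_equal(unname(hits[1, ]), c(4L, 1L))

  # hash-accelerated result equals brute force on random scenes
  set.seed(9)
  for (rep in 1:3) {
    sph <- uv_sphere(r = 3, nu = 14, nv = 9)
    jit <- sph$pos + matrix(rnorm(length(sph$pos), sd = 0.3), ncol = 3)
    got <- detect_collisions(jit, sph$tri, h = 0.6)
    want <- bf_collisions(jit, sph$tri, h = 0.6)
    expect_equal(nrow(got), nrow(want))
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(got), key(want))
  }
})

test_that("one-sided contact projection pushes out of the thickness shell", {
  tripts <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0))
  r <- project_constraint(list(type = "collision", h = 0.5),
                          rbind(c(1, 1, 0.2), tripts), w = c(1, 0, 0, 0),
                          dt = 0.01)
  expect_equal(r$positions[1, 3], 0.5, tolerance = 1e-12)
  # separated pair is untouched
  r2 <- project_constraint(list(type = "collision", h = 0.5),
                           rbind(c(1, 1, 3), tripts), w = c(1, 0, 0, 0),
                           dt = 0.01)
  expect_identical(r2$positions[1, ], c(1, 1, 3))
})

test_that("a step integrates a single drag-forced vertex like symplectic Euler", {
  pos <- rbind(c(0, 0, 5), c(100, 0, 0), c(101, 0, 0), c(100.5, 1, 0))
  tri <- rbind(c(2L, 3L, 4L))
  sc <- toy_scene(pos, tri)
  st <- sim_state(sc$mesh, dirichlet_ids = integer())
  cons <- build_constraints(sc$mesh, material_params())
  gamma <- 4; vt <- -25; damping <- 0.1; dt <- 1e-3
  cfg <- solver_config(dt = dt, substeps = 1L, iterations = 1L,
                       damping = damping)
  ph <- force_phase(pressure = 0, velocity_gain = gamma, target_speed = vt)
  res <- sim_step(st, sc, cons, ph, cfg, n_steps = 1L)
  f <- gamma * (vt * -sc$plane$normal)           # force at v = 0, m = 1
  expect_equal(res$state$pos[1, ], pos[1, ] + dt^2 * f, tolerance = 1e-9)
  expect_equal(res$state$vel[1, ], dt * f * (1 - damping), tolerance = 1e-9)
})

test_that("a satisfied unforced scene stays put and steps are deterministic", {
  p <- flat_patch(3, 3)
  sc <- toy_scene(p$pos, p$tri)
  st <- sim_state(sc$mesh, dirichlet_ids = integer())
  cons <- build_constraints(sc$mesh)
  ph0 <- force_phase(pressure = 0, velocity_gain = 0)
  r <- sim_step(st, sc, cons, ph0, solver_config(), n_steps = 5L)
  expect_identical(r$state$pos, st$pos)
  expect_equal(r$state$t, 5e-3)

  sc2 <- competent_scene()
  st2 <- sim_state(sc2$mesh)
  cons2 <- build_constraints(sc2$mesh, sc2$material)
  a <- sim_step(st2, sc2, cons2, force_phase(), solver_config(), n_steps = 25L)
  b <- sim_step(st2, sc2, cons2, force_phase(), solver_config(), n_steps = 25L)
  expect_identical(a$state$pos, b$state$pos)
  expect_identical(a$state$vel, b$state$vel)
})

test_that("annulus vertices track the prescribed interpolation exactly", {
  sc <- competent_scene()
  st <- sim_state(sc$mesh)
  cons <- build_constraints(sc$mesh, sc$material)
  r <- sim_step(st, sc, cons, force_phase(), solver_config(), n_steps = 37L)
  expect_identical(r$state$pos[sc$mesh$annulus_ids, ],
                   annulus_positions_at(sc$contour, r$state$t))
})

test_that("steady-state detection terminates and degenerates gracefully", {
  p <- flat_patch(3, 3)
  sc <- toy_scene(p$pos, p$tri)
  cfg <- solver_config(steady_window = 5L, max_steps = 50L)
  sim <- simulate_until_steady(sc, force_phase(pressure = 0, velocity_gain = 0),
                               cfg, state = sim_state(sc$mesh, integer()))
  expect_true(sim$converged)
  expect_equal(nrow(sim$log), 5)

  cfg2 <- solver_config(steady_tol = Inf, steady_window = 1L)
  sim2 <- simulate_until_steady(sc, force_phase(), cfg2,
                                state = sim_state(sc$mesh, integer()))
  expect_true(sim2$converged)
  expect_equal(nrow(sim2$log), 1)
})

test_that("the closing fixture converges within the step cap", {
  sim <- closed_competent()
  expect_true(sim$converged)
  expect_lt(nrow(sim$log), solver_config()$max_steps)
})
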