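test_that("cord weight switches exactly at the rest length", {
  expect_equal(cord_weight(c(0, 0, 0), c(0.5, 0, 0), 1), 0)   # compression
  expect_equal(cord_weight(c(0, 0, 0), c(1, 0, 0), 1), 1)     # boundary
  expect_equal(cord_weight(c(0, 0, 0), c(2, 0, 0), 1), 1)     # stretching
})

test_that("cord weight agrees with the piecewise definition on random triples", {
  set.seed(5)
  n <- 2000
  pi_ <- matrix(rnorm(3 * n), n, 3)
  pj <- matrix(rnorm(3 * n), n, 3)
  l0 <- runif(n, 0, 3)
  # force some exact-boundary cases
  bd <- 1:50
  l0[bd] <- sqrt(rowSums((pj[bd, ] - pi_[bd, ])^2))
  got <- vapply(seq_len(n), function(k) cord_weight(pi_[k, ], pj[k, ], l0[k]),
                numeric(1))
  want <- ifelse(sqrt(rowSums((pj - pi_)^2)) - l0 < 0, 0, 1)
  expect_identical(got, want)
})

test_that("heuristic tips sit at the mirrored plane distance of the centroid", {
  # plane z = 0 with atrial normal +z; subset centroid (3, 0, -2)
  pos <- rbind(c(3, 1, -2), c(3, -1, -2), c(0, 2, -3), c(0, -2, -3),
               c(5, 0, 1), c(6, 0, 1), c(5, 1, 1))
  mesh <- valve_mesh(pos, rbind(c(5L, 6L, 7L)), rep("anterior", 7),
                     integer(), integer())
  plane <- structure(list(center = c(0, 0, 0), normal = c(0, 0, 1)),
                     class = "annulus_plane")
  tips <- heuristic_pm_tips(mesh, list(anterolateral = 1:2,
                                       posteromedial = 3:4), plane)
  expect_equal(tips$anterolateral$open, c(3, 0, -4))
  expect_equal(tips$posteromedial$open, c(0, 0, -6))
  expect_true(tips$anterolateral$static)

  # centroid exactly on the plane: tip equals centroid, with a warning
  mesh2 <- valve_mesh(rbind(c(1, 0, 0), c(-1, 0, 0), pos[5:7, ]),
                      rbind(c(3L, 4L, 5L)), rep("anterior", 5),
                      integer(), integer())
  w <- capture_warnings(
    t2 <- heuristic_pm_tips(mesh2, list(anterolateral = 1:2,
                                        posteromedial = 1:2), plane))
  expect_length(w, 2)                   # one per degenerate tip
  expect_match(w, "centroid", all = TRUE)
  expect_equal(t2$anterolateral$open, c(0, 0, 0))
  expect_error(heuristic_pm_tips(mesh, list(anterolateral = integer(),
                                            posteromedial = 3:4), plane),
               "empty subset")
})

test_that("tip placement and rest lengths are rotation equivariant", {
  sc <- competent_scene()
  th <- 0.6
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  posr <- sc$mesh$positions %*% t(R)
  meshr <- valve_mesh(posr, sc$mesh$triangles, sc$mesh$leaflet_label,
                      sc$mesh$annulus_ids, sc$mesh$free_edge_ids)
  planer <- orient_plane(fit_annulus_plane(posr[sc$mesh$annulus_ids, ]), meshr)
  tips <- heuristic_pm_tips(sc$mesh, sc$subsets,
                            orient_plane(fit_annulus_plane(sc$contour$open),
                                         sc$mesh))
  tipsr <- heuristic_pm_tips(meshr, sc$subsets, planer)
  expect_equal(tipsr$anterolateral$open, drop(R %*% tips$anterolateral$open),
               tolerance = 1e-7)
  expect_equal(tipsr$posteromedial$open, drop(R %*% tips$posteromedial$open),
               tolerance = 1e-7)
})

test_that("heuristic tip geometry invariants hold on generated scenes", {
  set.seed(21)
  for (rep in 1:10) {
    prm <- valve_params(a = runif(1, 14, 20), b = runif(1, 10, 14),
                        saddle_height = runif(1, 0.5, 3),
                        leaflet_depth = runif(1, 12, 16),
                        mesh_resolution = 3.5)
    sc <- generate_scene(prm)
    pl <- sc$plane
    for (nm in names(sc$subsets)) {
      ci <- colMeans(sc$mesh$positions[sc$subsets[[nm]], , drop = FALSE])
      di <- abs(plane_signed_distance(ci, pl))
      tip <- sc$cords$tips[[nm]]$open
      v <- tip - ci
      cr <- c(v[2] * pl$normal[3] - v[3] * pl$normal[2],
              v[3] * pl$normal[1] - v[1] * pl$normal[3],
              v[1] * pl$normal[2] - v[2] * pl$normal[1])
      expect_lt(sqrt(sum(cr^2)), 1e-9)                       # parallel to n_AP
      expect_equal(abs(plane_signed_distance(tip, pl)), 2 * di,
                   tolerance = 1e-9)
    }
  }
})

test_that("initial rest length is the sum of the two unsigned distances", {
  plane <- structure(list(center = c(0, 0, 0), normal = c(0, 0, 1)),
                     class = "annulus_plane")
  expect_equal(initial_rest_length(c(1, 2, 0), plane, c(4, 6, 0)), 5)
  expect_equal(initial_rest_length(c(1, 0, -1), plane, c(0, 0, -3)),
               1 + sqrt(5))
  expect_equal(initial_rest_length(c(2, 0, 0), plane, c(2, 0, 0)), 0)
  # monotone in both distance terms
  expect_gt(initial_rest_length(c(1, 0, -2), plane, c(0, 0, -3)),
            initial_rest_length(c(1, 0, -1), plane, c(0, 0, -3)))
})

test_that("cords near the orifice are primary, belly cords secondary", {
  sc <- competent_scene()
  fe <- sc$mesh$free_edge_ids[1]
  expect_equal(classify_cord(sc$mesh, fe), "primary")
  expect_equal(classify_cord(sc$mesh, fe, ring = 0L), "primary")
  # a vertex adjacent to the annulus is many rings from the free edge
  adj <- setdiff(unique(as.vector(
    sc$mesh$triangles[apply(sc$mesh$triangles, 1,
                            function(r) any(r %in% sc$mesh$annulus_ids)), ])),
    sc$mesh$annulus_ids)[1]
  expect_equal(classify_cord(sc$mesh, adj), "secondary")
  # ring = 0 restricts the primary set to the free edge itself
  not_fe <- setdiff(seq_len(nrow(sc$mesh$positions)), sc$mesh$free_edge_ids)
  expect_equal(classify_cord(sc$mesh, not_fe[1], ring = 0L), "secondary")
})

test_that("compliance modes set rigid or inverse-modulus values per class", {
  sc <- competent_scene()
  cs <- set_compliance(sc$cords, "rigid")
  expect_true(all(cs$cords$compliance == 0))
  ce <- set_compliance(sc$cords, "elastic", E_primary = 2, E_secondary = 8)
  expect_equal(unique(ce$cords$compliance[ce$cords$class == "primary"]), 0.5)
  expect_equal(unique(ce$cords$compliance[ce$cords$class == "secondary"]),
               0.125)
  expect_equal(length(unique(ce$cords$compliance)), 2)
  expect_error(set_compliance(sc$cords, "elastic", E_primary = 2),
               "E_primary and E_secondary")
})

test_that("cord projection is one-sided and respects the Dirichlet tip", {
  tip <- c(0, 0, 0)
  # slack: no correction at all
  rs <- project_constraint(list(type = "cord", tip = tip, l0 = 2, alpha = 0),
                           matrix(c(1, 0, 0), 1, 3), w = 1, dt = 0.01)
  expect_identical(rs$positions[1, ], c(1, 0, 0))
  expect_equal(rs$lambda, 0)
  # taut rigid cord: pulled exactly onto the sphere of radius l0
  rt <- project_constraint(list(type = "cord", tip = tip, l0 = 2, alpha = 0),
                           matrix(c(5, 0, 0), 1, 3), w = 1, dt = 0.01)
  expect_equal(rt$positions[1, ], c(2, 0, 0), tolerance = 1e-12)
})

test_that("slack cords leave the step output untouched", {
  sc <- competent_scene()
  st <- sim_state(sc$mesh)
  cons <- build_constraints(sc$mesh, sc$material)
  r1 <- sim_step(st, sc, cons, force_phase(), solver_config(), n_steps = 1L)
  # at t = 0 every cord is slack; deleting them all changes nothing
  sc2 <- sc
  sc2$cords$cords <- sc2$cords$cords[0, , drop = FALSE]
  r2 <- sim_step(st, sc2, cons, force_phase(), solver_config(), n_steps = 1L)
  expect_equal(r1$state$pos, r2$state$pos, tolerance = 1e-12)
})

test_that("rigid cords are inextensible at the closed steady state", {
  sim <- closed_competent()
  sc <- competent_scene()
  ct <- mitralsim:::cord_table(sc$cords)
  tips <- mitralsim:::tip_keyframes(sc$cords)
  d <- sqrt(rowSums((sim$state$pos[ct$vertex, ] -
                       tips$closed[ct$tip_index, ])^2))
  expect_true(all(d <= ct$rest_length * 1.001))
})
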