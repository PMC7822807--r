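test_that("annulus plane PCA matches coplanar and near-coplanar oracles", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  pl <- fit_annulus_plane(sq)
  expect_equal(pl$center, c(0.5, 0.5, 0))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)

  # symmetric +-eps z perturbations keep the PCA normal on z
  pts <- rbind(cbind(cos(1:8), sin(1:8), 1e-3 * c(1, -1, 1, -1, 1, -1, 1, -1)))
  pl2 <- fit_annulus_plane(pts)
  expect_equal(abs(pl2$normal), abs(bf_plane_normal(pts)), tolerance = 1e-9)
  expect_lt(min(sum((pl2$normal - c(0, 0, 1))^2),
                sum((pl2$normal + c(0, 0, 1))^2)), 1e-4)

  # points on x + y + z = 1
  set.seed(1)
  uv <- matrix(runif(20), 10, 2)
  pts3 <- cbind(uv[, 1], uv[, 2], 1 - uv[, 1] - uv[, 2])
  pl3 <- fit_annulus_plane(pts3)
  expect_equal(abs(pl3$normal), rep(1, 3) / sqrt(3), tolerance = 1e-9)
})

test_that("degenerate plane inputs are rejected", {
  expect_error(fit_annulus_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_annulus_plane(line), "collinear")
})

test_that("plane fit is rigid-motion equivariant", {
  set.seed(42)
  pts <- cbind(cos(seq(0, 2 * pi, length.out = 13)[-13]) * 15,
               sin(seq(0, 2 * pi, length.out = 13)[-13]) * 11,
               rnorm(12, sd = 0.5))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
       rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  tvec <- c(3, -2, 7)
  p1 <- fit_annulus_plane(pts)
  p2 <- fit_annulus_plane(sweep(pts %*% t(R), 2, -tvec))
  expect_equal(p2$center, drop(R %*% p1$center) + tvec, tolerance = 1e-7)
  nr <- drop(R %*% p1$normal)
  expect_lt(min(sum((p2$normal - nr)^2), sum((p2$normal + nr)^2)), 1e-14)
})

test_that("orient_plane points the normal at the atrium and is idempotent", {
  sc <- competent_scene()
  pl <- fit_annulus_plane(sc$contour$open)
  for (sgn in c(1, -1)) {
    cand <- pl
    cand$normal <- sgn * cand$normal
    o1 <- orient_plane(cand, sc$mesh)
    fe <- colMeans(sc$mesh$positions[sc$mesh$free_edge_ids, ])
    expect_lt(sum((fe - o1$center) * o1$normal), 0)
    o2 <- orient_plane(o1, sc$mesh)
    expect_identical(o1$normal, o2$normal)
  }
})

test_that("orient_plane flips only when the free edge is on the positive side", {
  sc <- competent_scene()
  pl <- orient_plane(fit_annulus_plane(sc$contour$open), sc$mesh)
  flipped <- pl
  flipped$normal <- -flipped$normal
  expect_equal(orient_plane(flipped, sc$mesh)$normal, pl$normal)
})

test_that("annulus interpolation is exact at the endpoints and linear between", {
  open <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  closed <- open + 2
  ct <- annulus_contour(open, closed, close_duration = 1)
  expect_identical(annulus_positions_at(ct, 0), open)
  expect_equal(annulus_positions_at(ct, 0.5), open + 1)
  expect_identical(annulus_positions_at(ct, 2), ct$closed)   # clamped
  # midpoint example: (0,0,0) matched to (2,0,0) passes through (1,0,0)
  expect_equal(annulus_positions_at(ct, 0.5)[1, ], c(1, 1, 1))
})

test_that("resample_contour spaces points uniformly by arc length", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(resample_contour(sq, 4), sq, tolerance = 1e-12)

  th <- seq(0, 2 * pi, length.out = 201)[-201]
  circ <- cbind(cos(th), sin(th), 0)
  res <- resample_contour(circ, 10)
  seg <- rbind(res[-1, ], res[1, ]) - res
  lens <- sqrt(rowSums(seg^2))
  # chord lengths agree to ~arc-discretization accuracy
  expect_lt(diff(range(lens)), 1e-6)
  expect_equal(res[1, ], circ[1, ])

  expect_error(resample_contour(matrix(0, 4, 3), 4), "zero-length")
  expect_error(resample_contour(sq, 2), ">= 3")
})

test_that("valve mesh invariants reject malformed meshes", {
  q <- flat_quad()
  expect_error(valve_mesh(q$pos, rbind(c(1, 2, 5)), rep("anterior", 4),
                          integer(), integer()), "out of range")
  expect_error(valve_mesh(q$pos, rbind(c(1, 1, 2)), rep("anterior", 4),
                          integer(), integer()), "repeated vertex")
  degen <- rbind(q$pos, c(2, 0, 0))
  expect_error(valve_mesh(degen, rbind(q$tri, c(1, 2, 5)), rep("anterior", 5),
                          integer(), integer()), "zero area|non-manifold")
  expect_error(valve_mesh(q$pos, q$tri, rep("anterior", 3),
                          integer(), integer()), "one entry per vertex")
  expect_error(valve_mesh(q$pos, q$tri, rep("anterior", 4),
                          annulus_ids = 1L, free_edge_ids = 1L), "disjoint")
  # non-manifold: three triangles on one edge
  pos <- rbind(q$pos, c(0.5, 0.5, 1))
  tri <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(valve_mesh(pos, tri, rep("anterior", 5), integer(), integer()),
               "non-manifold")
})
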