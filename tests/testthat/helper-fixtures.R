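# Fixtures are built in code; expensive simulations are cached per session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

competent_scene <- function() cached("competent_scene",
                                     generate_scene(valve_preset("competent")))

closed_competent <- function() cached("closed_competent", {
  simulate_valve(competent_scene())
})

reference_tracings <- function() cached("reference_tracings", {
  sim <- closed_competent()
  sc <- competent_scene()
  generate_reference_tracings(sim$state$pos, sc$mesh$triangles, sc$plane,
                              n_planes = 5, noise_sd = 0.3, seed = 7)
})

# two-triangle flat unit square in z = 0 (boundary-only mesh)
flat_quad <- function() {
  list(pos = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
       tri = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

# regular grid patch in z = 0, nx x ny vertices with spacing `d`
flat_patch <- function(nx = 4, ny = 4, d = 1, z = 0) {
  g <- expand.grid(x = (seq_len(nx) - 1) * d, y = (seq_len(ny) - 1) * d)
  pos <- cbind(g$x, g$y, z)
  tri <- NULL
  id <- function(i, j) (j - 1) * nx + i
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    tri <- rbind(tri, c(id(i, j), id(i + 1, j), id(i, j + 1)),
                 c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  list(pos = pos, tri = tri)
}

# UV sphere approximation (for normal direction checks)
uv_sphere <- function(r = 1, nu = 12, nv = 8) {
  pos <- rbind(c(0, 0, r), c(0, 0, -r))
  for (v in seq_len(nv - 1)) {
    th <- pi * v / nv
    for (u in seq_len(nu)) {
      ph <- 2 * pi * u / nu
      pos <- rbind(pos, r * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)))
    }
  }
  id <- function(v, u) 2 + (v - 1) * nu + ((u - 1) %% nu) + 1
  tri <- NULL
  for (u in seq_len(nu)) {
    tri <- rbind(tri, c(1, id(1, u), id(1, u + 1)),
                 c(2, id(nv - 1, u + 1), id(nv - 1, u)))
  }
  for (v in seq_len(nv - 2)) for (u in seq_len(nu)) {
    a <- id(v, u); b <- id(v, u + 1); cta <- id(v + 1, u); ctb <- id(v + 1, u + 1)
    tri <- rbind(tri, c(a, cta, b), c(b, cta, ctb))
  }
  list(pos = pos, tri = tri)
}

# minimal hand-made scene around arbitrary geometry (no Dirichlet, no cords)
toy_scene <- function(pos, tri) {
  n <- nrow(pos)
  mesh <- valve_mesh(pos, tri,
                     leaflet_label = rep("anterior", n),
                     annulus_ids = integer(), free_edge_ids = integer())
  contour <- annulus_contour(rbind(c(100, 0, 0), c(101, 0, 0), c(100.5, 1, 0)),
                             rbind(c(100, 0, 0), c(101, 0, 0), c(100.5, 1, 0)),
                             close_duration = 1)
  tips <- list(anterolateral = papillary_tip("anterolateral", c(0, 0, -100)),
               posteromedial = papillary_tip("posteromedial", c(0, 0, -100)))
  cords <- cord_set(tips, data.frame(tip = character(), vertex = integer(),
                                     rest_length = numeric(),
                                     class = character(), group = character()))
  plane <- structure(list(center = c(0, 0, 0), normal = c(0, 0, 1)),
                     class = "annulus_plane")
  structure(list(mesh = mesh, contour = contour, plane = plane, cords = cords,
                 subsets = NULL, material = material_params(), params = NULL,
                 mirror = NULL),
            class = "valve_scene")
}

## --- independent oracles ----------------------------------------------------

# brute-force smallest-eigenvector plane fit
bf_plane_normal <- function(points) {
  x <- sweep(points, 2, colMeans(points))
  eigen(crossprod(x) / nrow(points), symmetric = TRUE)$vectors[, 3]
}

# brute-force point-to-mesh distance over all triangles
bf_point_mesh <- function(p, pos, tri) {
  min(vapply(seq_len(nrow(tri)), function(f) {
    cpp_pt <- mitralsim:::cpp_point_triangle(p, pos[tri[f, 1], ],
                                             pos[tri[f, 2], ], pos[tri[f, 3], ])
    cpp_pt$distance
  }, numeric(1)))
}

# brute-force all-pairs vertex/triangle proximity
bf_collisions <- function(pos, tri, h) {
  out <- NULL
  for (f in seq_len(nrow(tri))) {
    for (v in seq_len(nrow(pos))) {
      if (v %in% tri[f, ]) next
      d <- mitralsim:::cpp_point_triangle(pos[v, ], pos[tri[f, 1], ],
                                          pos[tri[f, 2], ], pos[tri[f, 3], ])$distance
      if (d < h) out <- rbind(out, c(v, f))
    }
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# closed-form PBD distance projection (alpha = 0)
bf_distance_projection <- function(p1, p2, w1, w2, l0) {
  d <- p1 - p2
  len <- sqrt(sum(d^2))
  C <- len - l0
  n <- d / len
  list(p1 = p1 - w1 / (w1 + w2) * C * n,
       p2 = p2 + w2 / (w1 + w2) * C * n)
}

# independent dihedral oracle: angle between the two opposite vertices seen
# in the plane perpendicular to the shared edge (flat fold = pi)
bf_dihedral <- function(P) {
  e <- P[2, ] - P[1, ]
  e <- e / sqrt(sum(e^2))
  perp <- function(q) {
    d <- q - P[1, ]
    d <- d - sum(d * e) * e
    d / sqrt(sum(d^2))
  }
  a <- perp(P[3, ]); b <- perp(P[4, ])
  acos(max(-1, min(1, sum(a * b))))
}

mirror_error <- function(pos, vm) {
  m <- pos
  m[, 2] <- -m[, 2]
  max(sqrt(rowSums((m[vm, , drop = FALSE] - pos)^2)))
}
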