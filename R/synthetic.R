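#' Parameters of the synthetic valve generator
#'
#' Describes a stylized two-leaflet valve hanging from a saddle-shaped
#' elliptical annulus. Dimensions follow typical adult mitral anatomy
#' (annulus semi-axes 17 x 13 mm, saddle height 1.5 mm); the open leaflets
#' hang ventricularly by `leaflet_depth` and taper to a free edge at 35% of
#' the annulus radius, which makes them long enough to overlap near the
#' valve center when closed.
#'
#' @param a,b annulus semi-axes (mm) along x (major) and y (minor).
#' @param saddle_height amplitude of the annulus saddle (mm); the ring height
#'   varies as `saddle_height * cos(2 theta)`.
#' @param leaflet_depth how far the open leaflets hang below the annulus (mm).
#' @param anterior_fraction fraction of the annulus circumference owned by
#'   the anterior leaflet (sector centered on +x).
#' @param mesh_resolution target edge length (mm).
#' @param leaflet_scale area multiplier >= 1 (pathology knob); scales
#'   `leaflet_depth`.
#' @param elongated_region optional `list(group =, factor =)` multiplying the
#'   rest lengths of one anatomical cord group (factor >= 1; cord pathology).
#' @param removed_cords optional integer indices of cords to delete (rupture).
#' @param cord_tension global multiplier applied to the heuristic cord rest
#'   lengths (mild refinement of the raw heuristic, which leaves a little too
#'   much headroom on this geometry; 1 = raw heuristic).
#' @param annulus_contraction closed-state in-plane scale of the annulus.
#' @param close_duration seconds over which the annulus transitions.
#' @param seed integer seed; only the tracing noise is stochastic, the mesh
#'   itself is fully deterministic.
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(a = 17, b = 13, saddle_height = 1.5,
                         leaflet_depth = 14, anterior_fraction = 0.45,
                         mesh_resolution = 2.5, leaflet_scale = 1,
                         elongated_region = NULL, removed_cords = NULL,
                         cord_tension = 0.92,
                         annulus_contraction = 0.96, close_duration = 0.25,
                         seed = 1L) {
  stopifnot(a > 0, b > 0, leaflet_depth > 0,
            anterior_fraction > 0, anterior_fraction < 1,
            mesh_resolution > 0, leaflet_scale >= 1, cord_tension > 0,
            annulus_contraction > 0, annulus_contraction <= 1)
  if (!is.null(elongated_region))
    stopifnot(is.list(elongated_region), elongated_region$factor >= 1)
  structure(list(a = a, b = b, saddle_height = saddle_height,
                 leaflet_depth = leaflet_depth,
                 anterior_fraction = anterior_fraction,
                 mesh_resolution = mesh_resolution,
                 leaflet_scale = leaflet_scale,
                 elongated_region = elongated_region,
                 removed_cords = removed_cords,
                 cord_tension = cord_tension,
                 annulus_contraction = annulus_contraction,
                 close_duration = close_duration,
                 seed = as.integer(seed)),
            class = "valve_params")
}

#' Named presets of the generator
#'
#' `competent` closes with coaptation and no prolapse; `prolapse_posterior`
#' elongates the posterior--posteromedial cord group by 1.6 so closure
#' prolapses on the posterior leaflet; `ruptured_cord` removes two primary
#' cords.
#'
#' @param name one of `"competent"`, `"prolapse_posterior"`,
#'   `"ruptured_cord"`.
#' @return A [valve_params()] object.
#' @export
valve_preset <- function(name) {
  switch(name,
    competent = valve_params(),
    prolapse_posterior = valve_params(
      elongated_region = list(group = "posterior-posteromedial", factor = 1.6)),
    ruptured_cord = valve_params(removed_cords = c(1L, 2L)),
    stop("unknown preset '", name, "'; available: competent, ",
         "prolapse_posterior, ruptured_cord"))
}

# annulus ring point at angle theta (open state)
annulus_point <- function(theta, p) {
  cbind(p$a * cos(theta), p$b * sin(theta),
        p$saddle_height * cos(2 * theta))
}

#' Generate a synthetic valve scene
#'
#' Builds the full simulation scene: saddle annulus, two ruled leaflet sheets
#' meshed from the annulus to a free edge (distinct meshes, offset at the
#' commissures so only collision constraints — not shared vertices — create
#' coaptation), the contracted closed annulus contour, cord attachment
#' subsets split into lateral halves (each mixing anterior and posterior
#' vertices), and the heuristic cord model. Fully deterministic.
#'
#' @param params a [valve_params()].
#' @return An object of class `valve_scene` with fields `mesh`, `contour`,
#'   `plane` (oriented), `cords`, `subsets`, `material`, `params`.
#' @export
generate_scene <- function(params = valve_params()) {
  stopifnot(inherits(params, "valve_params"))
  p <- params
  depth <- p$leaflet_depth * p$leaflet_scale
  rho <- 0.35                       # free-edge radius fraction
  perim <- ellipse_perimeter(p$a, p$b)

  # the anterior leaflet is longer than the posterior (as in the heart); the
  # asymmetry also places the coaptation line posteriorly so the free edges
  # shingle into overlap instead of meeting tip-to-tip
  sheets <- list(
    anterior = leaflet_sheet(center = 0, span = 2 * pi * p$anterior_fraction,
                             p = p, depth = 1.15 * depth, rho = rho,
                             perim = perim),
    posterior = leaflet_sheet(center = pi,
                              span = 2 * pi * (1 - p$anterior_fraction),
                              p = p, depth = 0.8 * depth, rho = rho,
                              perim = perim))

  n_ant <- nrow(sheets$anterior$pos)
  pos <- rbind(sheets$anterior$pos, sheets$posterior$pos)
  tri <- rbind(sheets$anterior$tri, sheets$posterior$tri + n_ant)
  label <- c(rep("anterior", n_ant), rep("posterior", nrow(sheets$posterior$pos)))
  annulus_ids <- c(sheets$anterior$annulus, sheets$posterior$annulus + n_ant)
  free_edge_ids <- c(sheets$anterior$free_edge, sheets$posterior$free_edge + n_ant)
  belly_ids <- c(sheets$anterior$belly, sheets$posterior$belly + n_ant)

  mesh <- valve_mesh(pos, tri, label, annulus_ids, free_edge_ids)

  open_poly <- pos[annulus_ids, , drop = FALSE]
  closed_poly <- open_poly
  ctrxy <- colMeans(open_poly)
  closed_poly[, 1] <- ctrxy[1] + p$annulus_contraction * (open_poly[, 1] - ctrxy[1])
  closed_poly[, 2] <- ctrxy[2] + p$annulus_contraction * (open_poly[, 2] - ctrxy[2])
  contour <- annulus_contour(open_poly, closed_poly, p$close_duration)

  plane <- orient_plane(fit_annulus_plane(open_poly), mesh)

  # cord attachments: all free-edge vertices (primary) plus all belly-ring
  # vertices (secondary); lateral halves anchor to one tip each
  attach <- c(free_edge_ids, belly_ids)
  yy <- pos[attach, 2]
  mid <- abs(yy) < 1e-9          # leaflet-midline vertices cord to both tips
  subsets <- list(anterolateral = attach[yy > 0 | mid],
                  posteromedial = attach[yy < 0 | mid])
  tips <- heuristic_pm_tips(mesh, subsets, plane)

  cords <- data.frame(
    tip = c(rep("anterolateral", length(subsets$anterolateral)),
            rep("posteromedial", length(subsets$posteromedial))),
    vertex = c(subsets$anterolateral, subsets$posteromedial),
    rest_length = NA_real_)
  cords <- cord_set(tips, cords, mesh = mesh, plane = plane)
  if (p$cord_tension != 1)
    cords <- apply_edit(cords, edit_command("all", factor = p$cord_tension))

  if (!is.null(p$elongated_region)) {
    cords <- apply_edit(cords, edit_command("group",
                                            p$elongated_region$group,
                                            p$elongated_region$factor))
  }
  if (!is.null(p$removed_cords)) {
    keep <- setdiff(seq_len(nrow(cords$cords)), p$removed_cords)
    cords$cords <- cords$cords[keep, , drop = FALSE]
    rownames(cords$cords) <- NULL
  }

  structure(list(mesh = mesh, contour = contour, plane = plane,
                 cords = cords, subsets = subsets,
                 material = material_params(), params = p,
                 mirror = mirror_permutation(pos, tri)),
            class = "valve_scene")
}

#' @export
print.valve_scene <- function(x, ...) {
  cat("valve_scene\n")
  print(x$mesh)
  print(x$cords)
  invisible(x)
}

# Ramanujan approximation, ample for choosing a column count.
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# One ruled leaflet sheet over annulus sector [center - span/2, center + span/2].
# Columns are inset half a spacing from the sector ends so the two leaflets
# stay distinct at the commissures; the odd column count puts one column
# exactly on the leaflet midline, which keeps the triangulation globally
# mirror-symmetric.
leaflet_sheet <- function(center, span, p, depth, rho, perim) {
  arc <- perim * span / (2 * pi)
  ncol <- max(5L, round(arc / p$mesh_resolution))
  if (ncol %% 2L == 0L) ncol <- ncol + 1L     # odd: exact center column
  meridian <- sqrt(((1 - rho) * max(p$a, p$b))^2 + depth^2)
  nring <- max(3L, ceiling(meridian / p$mesh_resolution))      # >= 3 rings
  # center column lands exactly on the leaflet midline (the x-z symmetry
  # plane for symmetric parameters)
  theta <- center + span * ((seq_len(ncol) - 0.5) / ncol - 0.5)
  tt <- seq(0, 1, length.out = nring + 1)

  nv <- ncol * (nring + 1)
  pos <- matrix(0, nv, 3)
  idx <- function(r, k) r * ncol + k          # r in 0..nring, k in 1..ncol
  ann <- annulus_point(theta, p)
  for (r in 0:nring) {
    t <- tt[r + 1]
    shrink <- 1 - t * (1 - rho)
    rows <- idx(r, seq_len(ncol))
    pos[rows, 1] <- shrink * ann[, 1]
    pos[rows, 2] <- shrink * ann[, 2]
    pos[rows, 3] <- (1 - t) * ann[, 3] - t * depth
  }

  tri <- matrix(0L, 2 * (nring) * (ncol - 1), 3)
  q <- 0L
  half <- (ncol - 1L) %/% 2L
  for (r in 0:(nring - 1)) {
    for (k in 1:(ncol - 1)) {
      v00 <- idx(r, k); v01 <- idx(r, k + 1)
      v10 <- idx(r + 1, k); v11 <- idx(r + 1, k + 1)
      # winding chosen so normals point toward the atrium (inward/up); quads
      # mirrored across the leaflet midline use mirrored diagonals so the
      # triangulation itself is mirror-symmetric
      if (k <= half) {
        tri[q + 1L, ] <- c(v00, v01, v10)
        tri[q + 2L, ] <- c(v01, v11, v10)
      } else {
        tri[q + 1L, ] <- c(v00, v01, v11)
        tri[q + 2L, ] <- c(v00, v11, v10)
      }
      q <- q + 2L
    }
  }
  basal_ring <- max(2L, round(0.4 * nring))
  belly_rows <- setdiff(seq(basal_ring, nring - 1L), integer()) # dense network
  list(pos = pos, tri = tri,
       annulus = idx(0, seq_len(ncol)),
       free_edge = idx(nring, seq_len(ncol)),
       belly = as.integer(unlist(lapply(belly_rows, function(r)
         idx(r, seq_len(ncol))))))
}

#' Synthetic reference tracings of a (closed) valve surface
#'
#' Emulates manually drawn closed-valve tracings on a stack of image planes:
#' the mesh is cut with `n_planes` parallel planes whose normal is
#' perpendicular to the annulus-plane normal (long-axis image planes), the
#' intersection segments are chained into polylines (chains closer than the
#' `join_gap` — e.g. across a coaptation line — are concatenated), and
#' isotropic Gaussian noise of `noise_sd` mm is added to every point.
#'
#' @param pos n x 3 vertex positions of the (deformed) mesh.
#' @param triangles m x 3 triangle indices.
#' @param plane the oriented annulus plane; slicing planes are stacked along
#'   the in-plane y-like axis.
#' @param n_planes number of parallel slicing planes (>= 1).
#' @param noise_sd isotropic noise standard deviation (mm).
#' @param seed RNG seed for the noise.
#' @param join_gap chains with endpoint gaps below this are concatenated
#'   into one polyline (mm).
#' @return An object of class `tracing_set`: list of
#'   `list(plane_id =, points = matrix)` entries. Planes that miss the mesh
#'   are skipped with a warning.
#' @export
generate_reference_tracings <- function(pos, triangles, plane,
                                        n_planes = 5L, noise_sd = 0.3,
                                        seed = 1L, join_gap = 1.0) {
  stopifnot(n_planes >= 1)
  pos <- as_matrix3(pos, "pos")
  # orthonormal in-plane axes of the annulus plane
  ref <- if (abs(plane$normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * plane$normal) * plane$normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(plane$normal[2] * e1[3] - plane$normal[3] * e1[2],
          plane$normal[3] * e1[1] - plane$normal[1] * e1[3],
          plane$normal[1] * e1[2] - plane$normal[2] * e1[1])
  coord <- drop(sweep(pos, 2, plane$center) %*% e2)
  lo <- stats::quantile(coord, 0.15); hi <- stats::quantile(coord, 0.85)
  offsets <- if (n_planes == 1) (lo + hi) / 2 else
    seq(lo, hi, length.out = n_planes)

  set.seed(seed)
  out <- list()
  for (k in seq_len(n_planes)) {
    chains <- slice_mesh(pos, triangles, e2, plane$center, offsets[k])
    if (length(chains) == 0) {
      warning("tracing plane ", k, " misses the mesh; skipped")
      next
    }
    poly <- join_chains(chains, join_gap)
    for (q in seq_along(poly)) {
      pts <- poly[[q]]
      if (noise_sd > 0)
        pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd),
                            nrow(pts), 3)
      out[[length(out) + 1]] <- list(
        plane_id = if (length(poly) == 1) paste0("plane", k)
                   else paste0("plane", k, letters[q]),
        points = pts)
    }
  }
  structure(out, class = "tracing_set")
}

# Intersect mesh with plane {x : dot(x - center, nrm) == off}; returns a list
# of chained polylines (each a matrix of 3D points).
slice_mesh <- function(pos, tri, nrm, center, off) {
  s <- drop(sweep(pos, 2, center) %*% nrm) - off
  segs <- list()
  for (f in seq_len(nrow(tri))) {
    v <- tri[f, ]
    sv <- s[v]
    pospts <- sv > 0
    if (all(pospts) || all(!pospts)) next
    pts <- matrix(0, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- v[e[1]]; b <- v[e[2]]
      if ((s[a] > 0) != (s[b] > 0)) {
        t <- s[a] / (s[a] - s[b])
        pts <- rbind(pts, pos[a, ] + t * (pos[b, ] - pos[a, ]))
      }
    }
    if (nrow(pts) == 2) segs[[length(segs) + 1]] <- pts
  }
  if (length(segs) == 0) return(list())
  chain_segments(segs)
}

# Greedy chaining of 2-point segments into polylines by endpoint proximity.
chain_segments <- function(segs, tol = 1e-7) {
  used <- rep(FALSE, length(segs))
  chains <- list()
  for (start in seq_along(segs)) {
    if (used[start]) next
    used[start] <- TRUE
    chain <- segs[[start]]
    repeat {
      extended <- FALSE
      for (k in seq_along(segs)) {
        if (used[k]) next
        sg <- segs[[k]]
        ends <- list(head = chain[1, ], tail = chain[nrow(chain), ])
        if (sum((sg[1, ] - ends$tail)^2) < tol) {
          chain <- rbind(chain, sg[2, ]); used[k] <- TRUE; extended <- TRUE
        } else if (sum((sg[2, ] - ends$tail)^2) < tol) {
          chain <- rbind(chain, sg[1, ]); used[k] <- TRUE; extended <- TRUE
        } else if (sum((sg[1, ] - ends$head)^2) < tol) {
          chain <- rbind(sg[2, ], chain); used[k] <- TRUE; extended <- TRUE
        } else if (sum((sg[2, ] - ends$head)^2) < tol) {
          chain <- rbind(sg[1, ], chain); used[k] <- TRUE; extended <- TRUE
        }
      }
      if (!extended) break
    }
    chains[[length(chains) + 1]] <- chain
  }
  chains
}

# Concatenate chains whose closest endpoints are within `gap`; returns a list
# of polylines (ideally one per image plane for a coapted valve).
join_chains <- function(chains, gap) {
  repeat {
    if (length(chains) < 2) return(chains)
    best <- NULL; best_d <- gap
    for (i in seq_along(chains)) for (j in seq_along(chains)) {
      if (i >= j) next
      for (ei in c(1, nrow(chains[[i]]))) for (ej in c(1, nrow(chains[[j]]))) {
        d <- sqrt(sum((chains[[i]][ei, ] - chains[[j]][ej, ])^2))
        if (d < best_d) { best_d <- d; best <- c(i, j, ei, ej) }
      }
    }
    if (is.null(best)) return(chains)
    ci <- chains[[best[1]]]; cj <- chains[[best[2]]]
    if (best[3] == 1) ci <- ci[nrow(ci):1, , drop = FALSE]
    if (best[4] != 1) cj <- cj[nrow(cj):1, , drop = FALSE]
    chains[[best[1]]] <- rbind(ci, cj)
    chains[[best[2]]] <- NULL
  }
}
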