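#' Construct a valve mesh
#'
#' A `valve_mesh` holds the open-state (t = 0) triangulated two-leaflet valve
#' surface together with the anatomical vertex sets the simulation needs: the
#' ordered annulus ring (Dirichlet boundary) and the ordered free-edge
#' (orifice) vertices, plus a per-vertex leaflet label.
#'
#' All coordinates are millimetres. Vertex and triangle indices are 1-based in
#' R objects; on-disk landmark files use 0-based indices (see
#' [read_landmarks()]).
#'
#' @param positions numeric n x 3 matrix of vertex positions (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param leaflet_label character vector of length n, each `"anterior"` or
#'   `"posterior"`.
#' @param annulus_ids integer vector of ordered, cyclic vertex indices on the
#'   annulus.
#' @param free_edge_ids integer vector of ordered vertex indices on the
#'   orifice (free leaflet edge).
#' @param validate logical; run the full invariant suite (default `TRUE`).
#' @return An object of class `valve_mesh`.
#' @seealso [validate_valve_mesh()], [fit_annulus_plane()]
#' @export
valve_mesh <- function(positions, triangles, leaflet_label,
                       annulus_ids, free_edge_ids, validate = TRUE) {
  positions <- as_matrix3(positions, "positions")
  triangles <- matrix(as.integer(triangles), ncol = 3L,
                      dimnames = NULL)
  mesh <- structure(
    list(positions = positions,
         triangles = triangles,
         leaflet_label = as.character(leaflet_label),
         annulus_ids = as.integer(annulus_ids),
         free_edge_ids = as.integer(free_edge_ids)),
    class = "valve_mesh")
  if (validate) validate_valve_mesh(mesh)
  mesh
}

#' @export
print.valve_mesh <- function(x, ...) {
  cat(sprintf(
    "valve_mesh: %d vertices, %d triangles (%d anterior / %d posterior vertices)\n",
    nrow(x$positions), nrow(x$triangles),
    sum(x$leaflet_label == "anterior"), sum(x$leaflet_label == "posterior")))
  cat(sprintf("  annulus ring: %d vertices; free edge: %d vertices\n",
              length(x$annulus_ids), length(x$free_edge_ids)))
  cat(sprintf("  total surface area: %.2f mm^2\n",
              total_area(x$positions, x$triangles)))
  invisible(x)
}

#' Validate a valve mesh
#'
#' Checks the structural invariants a simulatable valve surface must satisfy:
#' in-range triangle indices with three distinct vertices, strictly positive
#' triangle areas, a leaflet label for every vertex, annulus and free-edge sets
#' disjoint and located on the mesh boundary, and edge-manifoldness (no edge
#' with three or more incident triangles).
#'
#' @param mesh a [valve_mesh()].
#' @return `mesh`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_valve_mesh <- function(mesh) {
  n <- nrow(mesh$positions)
  tri <- mesh$triangles
  if (!all(is.finite(mesh$positions)))
    stop("valve_mesh: non-finite vertex positions")
  if (any(tri < 1L) || any(tri > n))
    stop("valve_mesh: triangle index out of range [1, ", n, "]")
  if (any(tri[, 1] == tri[, 2] | tri[, 1] == tri[, 3] | tri[, 2] == tri[, 3]))
    stop("valve_mesh: triangle with repeated vertex")
  areas <- triangle_areas(mesh$positions, tri)
  if (any(areas <= 0))
    stop("valve_mesh: degenerate triangle with zero area (first: ",
         which(areas <= 0)[1], ")")
  if (length(mesh$leaflet_label) != n)
    stop("valve_mesh: leaflet_label must have one entry per vertex")
  if (!all(mesh$leaflet_label %in% c("anterior", "posterior")))
    stop("valve_mesh: leaflet_label entries must be 'anterior' or 'posterior'")
  if (length(intersect(mesh$annulus_ids, mesh$free_edge_ids)) > 0L)
    stop("valve_mesh: annulus_ids and free_edge_ids must be disjoint")
  ec <- edge_counts(tri)
  if (any(ec$count > 2L)) {
    bad <- which(ec$count > 2L)[1]
    stop("valve_mesh: non-manifold edge (", ec$i[bad], ", ", ec$j[bad],
         ") with ", ec$count[bad], " incident triangles")
  }
  boundary <- boundary_vertices(tri)
  extras <- setdiff(c(mesh$annulus_ids, mesh$free_edge_ids), boundary)
  if (length(extras) > 0L)
    stop("valve_mesh: landmark vertex ", extras[1], " is not on the mesh boundary")
  invisible(mesh)
}

## --- small mesh helpers -----------------------------------------------------

as_matrix3 <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(what, " must be an n x 3 matrix")
  dimnames(x) <- NULL
  x
}

triangle_areas <- function(pos, tri) {
  u <- pos[tri[, 2], , drop = FALSE] - pos[tri[, 1], , drop = FALSE]
  v <- pos[tri[, 3], , drop = FALSE] - pos[tri[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

total_area <- function(pos, tri) sum(triangle_areas(pos, tri))

# Undirected edge table with incidence counts.
edge_counts <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  i <- pmin(e[, 1], e[, 2]); j <- pmax(e[, 1], e[, 2])
  key <- paste(i, j)
  tab <- table(key)
  first <- !duplicated(key)
  ord <- key[first]
  list(i = i[first], j = j[first], count = as.integer(tab[ord]))
}

# Vertices incident to at least one boundary edge (edge with one triangle).
boundary_vertices <- function(tri) {
  ec <- edge_counts(tri)
  b <- ec$count == 1L
  sort(unique(c(ec$i[b], ec$j[b])))
}

mesh_diameter <- function(pos) {
  rng <- apply(pos, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

## --- annulus contour --------------------------------------------------------

#' Annulus contour keyed between open and closed state
#'
#' The annulus ring is a Dirichlet boundary in the simulation: its vertices do
#' not respond to forces but follow a prescribed interpolation between the
#' open-state contour (matching the mesh at t = 0) and the closed-state
#' contour, over `close_duration` seconds.
#'
#' The closed polyline is resampled to the open polyline's point count by arc
#' length and rotationally aligned (over cyclic shifts and orientation
#' reversal, minimizing the sum of squared distances) so that point k of the
#' open contour corresponds to point k of the closed contour.
#'
#' @param open_polyline k x 3 matrix, ordered closed polyline of the open
#'   annulus (mm); row k matches `annulus_ids[k]` of the mesh.
#' @param closed_polyline matrix (>= 3 rows), ordered closed polyline of the
#'   closed annulus (mm); any point count, resampled internally.
#' @param close_duration simulated seconds over which the transition runs.
#' @return An object of class `annulus_contour` with correspondence-matched
#'   `open` and `closed` matrices of equal size.
#' @export
annulus_contour <- function(open_polyline, closed_polyline, close_duration) {
  open_polyline <- as_matrix3(open_polyline, "open_polyline")
  closed_polyline <- as_matrix3(closed_polyline, "closed_polyline")
  if (nrow(open_polyline) < 3L || nrow(closed_polyline) < 3L)
    stop("annulus contours need at least 3 points")
  if (close_duration <= 0) stop("close_duration must be > 0")
  if (nrow(closed_polyline) == nrow(open_polyline)) {
    # matching point counts: the given correspondence is kept verbatim
    closed <- closed_polyline
  } else {
    closed <- resample_contour(closed_polyline, nrow(open_polyline))
    closed <- align_cyclic(open_polyline, closed)
  }
  if (nrow(closed) != nrow(open_polyline))
    stop("annulus correspondence failed after resampling")
  structure(list(open = open_polyline, closed = closed,
                 close_duration = close_duration),
            class = "annulus_contour")
}

#' Interpolated annulus positions at a simulation time
#'
#' Linear interpolation between the open and closed contour with blend
#' `s = clamp(t / close_duration, 0, 1)`: `t = 0` reproduces the open contour
#' exactly and `t >= close_duration` the (resampled, aligned) closed contour.
#'
#' @param contour an [annulus_contour()].
#' @param t simulation time in seconds (>= 0).
#' @return k x 3 matrix of annulus vertex positions.
#' @export
annulus_positions_at <- function(contour, t) {
  stopifnot(inherits(contour, "annulus_contour"), t >= 0)
  s <- min(max(t / contour$close_duration, 0), 1)
  if (s == 0) return(contour$open)
  if (s == 1) return(contour$closed)
  (1 - s) * contour$open + s * contour$closed
}

#' Resample a closed polyline at uniform arc length
#'
#' Returns `n` points equally spaced along the closed polyline's arc length,
#' starting at the input's first vertex and preserving orientation.
#'
#' @param points k x 3 matrix, ordered closed polyline.
#' @param n number of output points (>= 3).
#' @return n x 3 matrix.
#' @export
resample_contour <- function(points, n) {
  points <- as_matrix3(points, "points")
  if (n < 3L) stop("resample_contour: n must be >= 3")
  k <- nrow(points)
  seg <- points[c(2:k, 1), , drop = FALSE] - points
  len <- sqrt(rowSums(seg^2))
  total <- sum(len)
  if (total <= 0) stop("resample_contour: zero-length polyline")
  cum <- c(0, cumsum(len))            # length k + 1, cum[k+1] == total
  s <- total * (seq_len(n) - 1) / n   # target arc positions
  out <- matrix(0, n, 3)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > k] <- k
  frac <- (s - cum[idx]) / len[idx]
  frac[!is.finite(frac)] <- 0         # zero-length segment
  nxt <- c(2:k, 1)
  out <- points[idx, , drop = FALSE] +
    frac * (points[nxt[idx], , drop = FALSE] - points[idx, , drop = FALSE])
  out
}

# Cyclic (and reversed) alignment of `cand` onto `ref`, both n x 3, by
# minimum sum of squared point distances.
align_cyclic <- function(ref, cand) {
  n <- nrow(ref)
  best <- NULL; best_ss <- Inf
  for (rev in c(FALSE, TRUE)) {
    cc <- if (rev) cand[n:1, , drop = FALSE] else cand
    for (shift in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + shift) %% n) + 1
      ss <- sum((cc[idx, , drop = FALSE] - ref)^2)
      if (ss < best_ss) { best_ss <- ss; best <- cc[idx, , drop = FALSE] }
    }
  }
  best
}

## --- annulus plane ----------------------------------------------------------

#' Fit the annulus plane by principal component analysis
#'
#' The annulus plane (AP) is the least-squares plane through the annulus
#' contour: its center is the point centroid and its normal is the eigenvector
#' of the 3 x 3 point covariance with the smallest eigenvalue. The normal's
#' sign is arbitrary until fixed with [orient_plane()].
#'
#' @param points k x 3 matrix of contour points (k >= 3, not collinear).
#' @return An object of class `annulus_plane` with fields `center` and
#'   `normal` (unit length).
#' @export
fit_annulus_plane <- function(points) {
  points <- as_matrix3(points, "points")
  if (nrow(points) < 3L)
    stop("fit_annulus_plane: need at least 3 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  cov3 <- crossprod(x) / nrow(points)
  eg <- eigen(cov3, symmetric = TRUE)
  # eigenvalues in decreasing order; collinear points have rank <= 1
  if (eg$values[2] <= max(eg$values[1], 1) * 1e-12)
    stop("fit_annulus_plane: degenerate geometry (collinear points)")
  nrm <- eg$vectors[, 3]
  nrm <- nrm / sqrt(sum(nrm^2))
  structure(list(center = ctr, normal = nrm), class = "annulus_plane")
}

#' @export
print.annulus_plane <- function(x, ...) {
  cat(sprintf("annulus_plane: center (%.3f, %.3f, %.3f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$center[1], x$center[2], x$center[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Orient the annulus plane normal toward the atrium
#'
#' Resolves the PCA normal's sign so that the free-edge (orifice) vertices —
#' which hang into the ventricle in the open state — lie on the negative side
#' of the plane. The positive side is then the atrial side and the normal is
#' the main flow axis used by the force fields.
#'
#' @param plane an [fit_annulus_plane()] result.
#' @param mesh a [valve_mesh()] with non-empty `free_edge_ids`.
#' @return The plane, with `normal` possibly negated. Idempotent.
#' @export
orient_plane <- function(plane, mesh) {
  stopifnot(inherits(plane, "annulus_plane"), inherits(mesh, "valve_mesh"))
  if (length(mesh$free_edge_ids) == 0L)
    stop("orient_plane: mesh has no free-edge vertices")
  fe <- colMeans(mesh$positions[mesh$free_edge_ids, , drop = FALSE])
  h <- sum((fe - plane$center) * plane$normal)
  if (h == 0)
    stop("orient_plane: free-edge centroid lies exactly on the plane; ",
         "orientation is ambiguous")
  if (h > 0) plane$normal <- -plane$normal
  plane
}

#' Signed distance of points to a plane
#'
#' Positive on the side the normal points to (the atrial side after
#' [orient_plane()]).
#'
#' @param points n x 3 matrix or length-3 vector.
#' @param plane an `annulus_plane`.
#' @return numeric vector of signed distances (mm).
#' @export
plane_signed_distance <- function(points, plane) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  drop(sweep(points, 2, plane$center) %*% plane$normal)
}
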