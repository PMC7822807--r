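#' One-sided cord weight (tension switch)
#'
#' A cord only acts under tension: its constraint is weighted by
#' `k = 0` when compressed (`|p_j - p_i| - l0 < 0`) and `k = 1` when
#' stretched (`|p_j - p_i| - l0 >= 0`; the boundary counts as stretching).
#' With `k = 0` the leaflet vertex moves freely.
#'
#' @param p_i papillary tip position (length-3).
#' @param p_j leaflet vertex position (length-3).
#' @param l0 rest length (mm, >= 0).
#' @return 0 or 1.
#' @export
cord_weight <- function(p_i, p_j, l0) {
  stopifnot(l0 >= 0)
  d <- sqrt(sum((p_j - p_i)^2))
  if (d - l0 < 0) 0 else 1
}

#' Heuristic papillary-muscle tip placement
#'
#' When the papillary muscles cannot be located in the images, the two tips
#' are placed from the cord attachment selections alone: for each of the two
#' leaflet-vertex subsets, take its centroid `c_i`, its unsigned distance
#' `d_i` to the annulus plane, and put the tip at `c_i - d_i * n_AP` with the
#' atrium-oriented normal — i.e. the centroid pushed the same distance again
#' away from the annulus plane, deeper into the ventricle. The tip's unsigned
#' plane distance is therefore `2 * d_i`, and `tip - c_i` is parallel to the
#' plane normal. Heuristic tips are static over time.
#'
#' @param mesh a [valve_mesh()].
#' @param subsets list of two integer vectors of leaflet-vertex indices, named
#'   `anterolateral` and `posteromedial`; each subset should mix anterior and
#'   posterior leaflet vertices (one lateral half of the valve each).
#' @param plane oriented [fit_annulus_plane()] result (normal toward atrium).
#' @return Named list of two `papillary_tip` objects, each with `id`, `open`
#'   and `closed` positions (equal: static) and `static = TRUE`.
#' @export
heuristic_pm_tips <- function(mesh, subsets, plane) {
  stopifnot(inherits(mesh, "valve_mesh"), inherits(plane, "annulus_plane"))
  if (is.null(names(subsets)) || !setequal(names(subsets),
                                           c("anterolateral", "posteromedial")))
    subsets <- stats::setNames(subsets, c("anterolateral", "posteromedial"))
  out <- lapply(names(subsets), function(nm) {
    idx <- subsets[[nm]]
    if (length(idx) == 0L) stop("heuristic_pm_tips: empty subset '", nm, "'")
    ci <- colMeans(mesh$positions[idx, , drop = FALSE])
    di <- abs(plane_signed_distance(ci, plane))
    if (di == 0)
      warning("heuristic_pm_tips: subset centroid lies on the annulus plane; ",
              "tip coincides with centroid")
    tip <- ci - di * plane$normal
    papillary_tip(nm, tip)
  })
  stats::setNames(out, names(subsets))
}

#' Papillary tip with (optionally keyed) trajectory
#'
#' @param id `"anterolateral"` or `"posteromedial"`.
#' @param open tip position at t = 0 (length-3, mm).
#' @param closed tip position in the closed state; defaults to `open`
#'   (static tip, the heuristic case). Keyed tips are interpolated linearly
#'   over the annulus close duration.
#' @return An object of class `papillary_tip`.
#' @export
papillary_tip <- function(id, open, closed = open) {
  stopifnot(id %in% c("anterolateral", "posteromedial"),
            length(open) == 3, all(is.finite(open)), all(is.finite(closed)))
  structure(list(id = id, open = as.numeric(open),
                 closed = as.numeric(closed),
                 static = identical(as.numeric(open), as.numeric(closed))),
            class = "papillary_tip")
}

#' Heuristic initial cord rest length
#'
#' The rest length that matters is the cord's length in the closed state,
#' which is unknown at setup time. It is approximated from the open state as
#' the sum of two unsigned distances: leaflet vertex to annulus plane, plus
#' leaflet vertex to papillary tip.
#'
#' @param p_j leaflet vertex position at t = 0 (length-3, mm).
#' @param plane the annulus plane.
#' @param tip a [papillary_tip()] (its open position is used) or a length-3
#'   position.
#' @return rest length l0 in mm.
#' @export
initial_rest_length <- function(p_j, plane, tip) {
  tp <- if (inherits(tip, "papillary_tip")) tip$open else as.numeric(tip)
  abs(plane_signed_distance(p_j, plane)) + sqrt(sum((p_j - tp)^2))
}

#' Classify a cord as primary or secondary
#'
#' Cords attached near the orifice (free edge) are primary; cords on the
#' leaflet belly are secondary. "Near" means within `ring` edge-graph hops of
#' a free-edge vertex (`ring = 0`: exactly the free edge).
#'
#' @param mesh a [valve_mesh()].
#' @param j leaflet vertex index.
#' @param ring neighborhood radius in mesh edges (default 1).
#' @return `"primary"` or `"secondary"`.
#' @export
classify_cord <- function(mesh, j, ring = 1L) {
  stopifnot(j >= 1, j <= nrow(mesh$positions))
  if (j %in% mesh$free_edge_ids) return("primary")
  if (ring < 1L) return("secondary")
  # breadth-first over mesh edges from the free edge, `ring` levels
  adj <- mesh_adjacency(mesh$triangles, nrow(mesh$positions))
  frontier <- mesh$free_edge_ids
  seen <- frontier
  for (r in seq_len(ring)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    if (j %in% frontier) return("primary")
    seen <- c(seen, frontier)
  }
  "secondary"
}

mesh_adjacency <- function(tri, n) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  out <- vector("list", n)
  out[as.integer(names(adj))] <- lapply(adj, unique)
  out
}

#' Assemble a cord set
#'
#' @param tips named list of two [papillary_tip()] objects (`anterolateral`,
#'   `posteromedial`).
#' @param cords data frame with columns `tip` (tip id), `vertex` (leaflet
#'   vertex index), `rest_length` (mm; `NA` triggers [initial_rest_length()]
#'   when a plane is given), `class` (`"primary"`/`"secondary"`), `group`
#'   (one of the four anatomical groups, filled automatically when missing)
#'   and optionally `compliance` (default 0, rigid).
#' @param mesh,plane needed to fill in `NA` rest lengths, classes or groups.
#' @return An object of class `cord_set`.
#' @export
cord_set <- function(tips, cords, mesh = NULL, plane = NULL) {
  stopifnot(setequal(names(tips), c("anterolateral", "posteromedial")))
  cords <- as.data.frame(cords)
  if (is.null(cords$compliance)) cords$compliance <- rep(0, nrow(cords))
  if (!is.null(mesh)) {
    leaf <- mesh$leaflet_label[cords$vertex]
    cords$group <- paste0(leaf, "-", cords$tip)
    if (is.null(cords$class) || anyNA(cords$class))
      cords$class <- vapply(cords$vertex, function(j) classify_cord(mesh, j),
                            character(1))
  }
  cords$vertex <- as.integer(cords$vertex)
  if (!is.null(plane) && anyNA(cords$rest_length)) {
    nas <- which(is.na(cords$rest_length))
    cords$rest_length[nas] <- vapply(nas, function(k) {
      initial_rest_length(mesh$positions[cords$vertex[k], ], plane,
                          tips[[cords$tip[k]]])
    }, numeric(1))
  }
  stopifnot(all(cords$tip %in% c("anterolateral", "posteromedial")),
            all(cords$rest_length >= 0), all(cords$compliance >= 0))
  if (anyDuplicated(cords[, c("tip", "vertex")]))
    stop("cord_set: duplicate (tip, vertex) cord")
  rownames(cords) <- NULL
  structure(list(tips = tips, cords = cords), class = "cord_set")
}

#' @export
print.cord_set <- function(x, ...) {
  cat(sprintf("cord_set: %d cords (%d primary, %d secondary)\n",
              nrow(x$cords), sum(x$cords$class == "primary"),
              sum(x$cords$class == "secondary")))
  print(table(x$cords$group))
  invisible(x)
}

#' Set cord compliance
#'
#' Rigid mode sets every cord compliance to 0: cords cannot stretch past
#' their rest lengths and no biomechanical material assumption is needed.
#' Elastic mode sets the compliance to the inverse Young's modulus, per cord
#' class (primary/secondary moduli differ in the literature and must be
#' supplied).
#'
#' @param cordset a [cord_set()].
#' @param mode `"rigid"` or `"elastic"`.
#' @param E_primary,E_secondary Young's moduli (> 0) for elastic mode.
#' @return The updated cord set.
#' @export
set_compliance <- function(cordset, mode = c("rigid", "elastic"),
                           E_primary = NULL, E_secondary = NULL) {
  mode <- match.arg(mode)
  if (mode == "rigid") {
    cordset$cords$compliance <- 0
  } else {
    if (is.null(E_primary) || is.null(E_secondary) ||
        E_primary <= 0 || E_secondary <= 0)
      stop("elastic mode requires positive E_primary and E_secondary")
    cordset$cords$compliance <- ifelse(cordset$cords$class == "primary",
                                       1 / E_primary, 1 / E_secondary)
  }
  cordset
}

# Internal: flatten for the compiled loop.
cord_table <- function(cordset) {
  cd <- cordset$cords
  list(tip_index = ifelse(cd$tip == "anterolateral", 1L, 2L),
       vertex = as.integer(cd$vertex),
       rest_length = as.numeric(cd$rest_length),
       compliance = as.numeric(cd$compliance))
}

tip_keyframes <- function(cordset) {
  al <- cordset$tips$anterolateral
  pm <- cordset$tips$posteromedial
  list(open = rbind(al$open, pm$open),
       closed = rbind(al$closed, pm$closed))
}
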