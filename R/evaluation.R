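#' Exact point-to-surface distance
#'
#' Minimum Euclidean distance from each query point to the triangle mesh,
#' handling vertex, edge and face closest-point cases, accelerated by an
#' axis-aligned bounding-box tree; the result equals the brute-force minimum
#' over all triangles.
#'
#' @param p query point (length-3) or n x 3 matrix.
#' @param pos mesh vertex positions.
#' @param triangles mesh triangle indices (1-based).
#' @return list with `distance` (vector), `closest` (n x 3) and `triangle`
#'   (index of the closest triangle).
#' @export
point_to_surface <- function(p, pos, triangles) {
  if (is.null(dim(p))) p <- matrix(p, 1, 3)
  cpp_points_to_mesh(as_matrix3(p, "p"), as_matrix3(pos, "pos"),
                     matrix(as.integer(triangles), ncol = 3L))
}

#' Tracing set
#'
#' A bundle of closed-valve tracing polylines, each tagged with the image
#' plane it was drawn on.
#'
#' @param polylines list of `list(plane_id =, points = matrix)` entries; each
#'   polyline needs at least 2 points.
#' @return An object of class `tracing_set`.
#' @export
tracing_set <- function(polylines) {
  for (pl in polylines) {
    if (is.null(pl$points) || nrow(pl$points) < 2)
      stop("tracing_set: each polyline needs at least 2 points")
  }
  structure(lapply(polylines, function(pl)
    list(plane_id = as.character(pl$plane_id),
         points = as_matrix3(pl$points, "tracing points"))),
    class = "tracing_set")
}

#' Deviation of tracings to the simulated surface
#'
#' Reproduces the closed-valve scoring: every tracing polyline is resampled
#' at `sample_spacing` along its arc length, each sample's exact distance to
#' the surface is computed (tracing-to-surface direction), and the pooled
#' distances are summarized as minimum, median, maximum and mean +- SD. The
#' median of an even pool is the average of the two central values.
#'
#' @param pos deformed mesh vertex positions (n x 3).
#' @param triangles mesh triangles.
#' @param tracings a [tracing_set()].
#' @param sample_spacing resampling step along each polyline (mm).
#' @return An object of class `deviation_report` with fields `min_d`,
#'   `med_d`, `max_d`, `avg_d`, `sd_d`, `n_points` and the retained
#'   `distances` vector.
#' @export
evaluate_deviation <- function(pos, triangles, tracings, sample_spacing = 0.5) {
  stopifnot(inherits(tracings, "tracing_set"), sample_spacing > 0,
            length(tracings) > 0)
  samples <- do.call(rbind, lapply(tracings, function(pl)
    resample_polyline_open(pl$points, sample_spacing)))
  if (is.null(samples) || nrow(samples) == 0)
    stop("evaluate_deviation: empty sample pool")
  d <- point_to_surface(samples, pos, triangles)$distance
  structure(list(min_d = min(d), med_d = stats::median(d), max_d = max(d),
                 avg_d = mean(d), sd_d = stats::sd(d),
                 n_points = length(d), distances = d),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf(
    "deviation over %d samples: min %.2f | med %.2f | max %.2f | avg %.2f +- %.2f mm\n",
    x$n_points, x$min_d, x$med_d, x$max_d, x$avg_d, x$sd_d))
  invisible(x)
}

# Resample an open polyline at roughly `spacing` arc length (endpoints kept).
resample_polyline_open <- function(points, spacing) {
  k <- nrow(points)
  if (k == 1) return(points)
  seg <- points[-1, , drop = FALSE] - points[-k, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  total <- sum(len)
  if (total == 0) return(points[1, , drop = FALSE])
  n <- max(2, ceiling(total / spacing) + 1)
  s <- seq(0, total, length.out = n)
  cum <- c(0, cumsum(len))
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE), k - 1)
  frac <- (s - cum[idx]) / len[idx]
  frac[!is.finite(frac)] <- 0
  points[idx, , drop = FALSE] +
    frac * (points[idx + 1, , drop = FALSE] - points[idx, , drop = FALSE])
}

#' Detect leaflet prolapse in the closed state
#'
#' Measures the signed height of every non-annulus leaflet vertex above the
#' best-fit plane of the closed annulus contour (atrial side positive).
#' Prolapse is flagged when any height exceeds `threshold`; offending
#' vertices and their leaflet labels are reported.
#'
#' @param pos deformed mesh vertex positions at the closed steady state.
#' @param mesh the [valve_mesh()] (labels, annulus ids).
#' @param contour the [annulus_contour()]; its closed polyline defines the
#'   reference plane.
#' @param threshold prolapse height threshold (mm, default 2).
#' @return An object of class `prolapse_report`: `prolapse` (logical),
#'   `offending_vertices`, `max_height` (mm), `region` (leaflet labels of
#'   offenders), `heights` (all non-annulus signed heights).
#' @export
detect_prolapse <- function(pos, mesh, contour, threshold = 2) {
  pos <- as_matrix3(pos, "pos")
  ref <- fit_annulus_plane(contour$closed)
  # orient like the open-state annulus plane (atrium positive)
  open_plane <- orient_plane(fit_annulus_plane(contour$open), mesh)
  if (sum(ref$normal * open_plane$normal) < 0) ref$normal <- -ref$normal
  cand <- setdiff(seq_len(nrow(pos)), mesh$annulus_ids)
  h <- plane_signed_distance(pos[cand, , drop = FALSE], ref)
  offending <- cand[h > threshold]
  structure(list(prolapse = length(offending) > 0,
                 offending_vertices = offending,
                 max_height = max(h),
                 region = unique(mesh$leaflet_label[offending]),
                 threshold = threshold,
                 heights = h),
            class = "prolapse_report")
}

#' @export
print.prolapse_report <- function(x, ...) {
  if (x$prolapse)
    cat(sprintf("prolapse: YES (%d vertices on %s leaflet, max height %.2f mm > %.1f mm)\n",
                length(x$offending_vertices),
                paste(x$region, collapse = "+"), x$max_height, x$threshold))
  else
    cat(sprintf("prolapse: no (max height %.2f mm <= %.1f mm)\n",
                x$max_height, x$threshold))
  invisible(x)
}
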