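## File formats: ASCII OBJ/PLY for meshes, JSON for landmarks/cords/tracings/
## session scripts, YAML for solver configuration, CSV for reports. Writers
## are deterministic: stable key order, floats at 9 significant digits.
## On-disk vertex indices are 0-based; in-memory R objects are 1-based.

fmt9 <- function(x) signif(x, 9)

#' Write / read a triangle mesh (ASCII OBJ or PLY)
#'
#' Triangles only. The format is chosen from the file extension
#' (`.obj` / `.ply`).
#'
#' @param pos n x 3 vertex positions.
#' @param triangles m x 3 triangle indices (1-based in R).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(pos, triangles, path) {
  pos <- as_matrix3(pos, "pos")
  tri <- matrix(as.integer(triangles), ncol = 3L)
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", pos[, 1], pos[, 2], pos[, 3]),
               sprintf("f %d %d %d", tri[, 1], tri[, 2], tri[, 3]))
  } else if (ext == "ply") {
    lines <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pos)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(tri)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.9g %.9g %.9g", pos[, 1], pos[, 2], pos[, 3]),
               sprintf("3 %d %d %d", tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L))
  } else stop("write_mesh: unsupported extension '", ext, "' (use .obj/.ply)")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mesh
#' @return For `read_mesh`: list with `pos` and `triangles` (1-based).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("read_mesh: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    if (length(vl) == 0) stop("read_mesh: malformed OBJ (no vertices): ", path)
    pos <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    tri <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
      ids <- as.integer(sub("/.*", "", x[-1]))
      if (length(ids) != 3) stop("read_mesh: non-triangular face in ", path)
      ids
    }))
  } else if (ext == "ply") {
    if (lines[1] != "ply" || !any(grepl("^format ascii", lines)))
      stop("read_mesh: ", path, " is not ASCII PLY")
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    body <- which(lines == "end_header") + 1L
    pos <- do.call(rbind, lapply(strsplit(lines[body:(body + nv - 1)], "\\s+"),
                                 function(x) as.numeric(x[1:3])))
    fl <- strsplit(lines[(body + nv):(body + nv + nf - 1)], "\\s+")
    tri <- do.call(rbind, lapply(fl, function(x) {
      if (as.integer(x[1]) != 3) stop("read_mesh: non-triangular face in ", path)
      as.integer(x[2:4]) + 1L
    }))
  } else stop("read_mesh: unsupported extension '", ext, "'")
  if (any(is.na(pos)) || any(is.na(tri)))
    stop("read_mesh: malformed numeric data in ", path)
  list(pos = pos, triangles = tri)
}

#' Write / read the landmark sidecar file
#'
#' JSON schema (indices 0-based on disk): `annulus_ids`, `free_edge_ids`,
#' `leaflet_label`, `annulus_open`, `annulus_closed` (point lists),
#' `close_duration` (s).
#' @param mesh a [valve_mesh()].
#' @param contour an [annulus_contour()].
#' @param path file path.
#' @export
write_landmarks <- function(mesh, contour, path) {
  obj <- list(annulus_ids = mesh$annulus_ids - 1L,
              free_edge_ids = mesh$free_edge_ids - 1L,
              leaflet_label = mesh$leaflet_label,
              annulus_open = fmt9(unname(contour$open)),
              annulus_closed = fmt9(unname(contour$closed)),
              close_duration = contour$close_duration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("read_landmarks: no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("annulus_ids", "free_edge_ids", "leaflet_label",
                "annulus_open", "annulus_closed", "close_duration"))
    if (is.null(x[[key]]))
      stop("read_landmarks: ", path, " is missing required key '", key, "'")
  x$annulus_ids <- as.integer(x$annulus_ids) + 1L
  x$free_edge_ids <- as.integer(x$free_edge_ids) + 1L
  x
}

#' Write / read a cord file
#'
#' JSON schema: `tips` mapping tip id to either a static position or
#' `{"open": [...], "closed": [...]}`; `cords`: list of
#' `{"tip", "vertex" (0-based), "group", "class", "rest_length"}` with
#' `null` rest_length meaning "initialize heuristically on load".
#'
#' @param cordset a [cord_set()].
#' @param path file path.
#' @export
write_cords <- function(cordset, path) {
  tips <- lapply(cordset$tips, function(tp) {
    if (tp$static) fmt9(tp$open)
    else list(open = fmt9(tp$open), closed = fmt9(tp$closed))
  })
  cd <- cordset$cords
  cords <- lapply(seq_len(nrow(cd)), function(k)
    list(tip = cd$tip[k], vertex = cd$vertex[k] - 1L,
         group = cd$group[k], class = cd$class[k],
         rest_length = fmt9(cd$rest_length[k]),
         compliance = fmt9(cd$compliance[k])))
  jsonlite::write_json(list(tips = tips, cords = cords), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cords
#' @param mesh,plane used to fill heuristic rest lengths / classes on load.
#' @export
read_cords <- function(path, mesh = NULL, plane = NULL) {
  if (!file.exists(path)) stop("read_cords: no such file: ", path)
  x <- jsonlite::read_json(path)
  if (is.null(x$tips) || is.null(x$cords))
    stop("read_cords: ", path, " is missing 'tips' or 'cords'")
  tips <- lapply(names(x$tips), function(nm) {
    tp <- x$tips[[nm]]
    if (!is.null(tp$open)) papillary_tip(nm, unlist(tp$open), unlist(tp$closed))
    else papillary_tip(nm, unlist(tp))
  })
  names(tips) <- names(x$tips)
  cd <- do.call(rbind, lapply(x$cords, function(cc) data.frame(
    tip = cc$tip, vertex = as.integer(cc$vertex) + 1L,
    group = if (is.null(cc$group)) NA_character_ else cc$group,
    class = if (is.null(cc$class)) NA_character_ else cc$class,
    rest_length = if (is.null(cc$rest_length)) NA_real_ else cc$rest_length,
    compliance = if (is.null(cc$compliance)) 0 else cc$compliance)))
  if (!is.null(mesh) && any(cd$vertex > nrow(mesh$positions) | cd$vertex < 1)) {
    bad <- which(cd$vertex > nrow(mesh$positions) | cd$vertex < 1)[1]
    stop("read_cords: ", path, ": cord ", bad, " references vertex index ",
         cd$vertex[bad] - 1L, " outside the mesh (0-based range 0..",
         nrow(mesh$positions) - 1L, ")")
  }
  cord_set(tips, cd, mesh = mesh, plane = plane)
}

#' Write / read tracing polylines
#'
#' JSON schema: a list of `{"plane_id": "...", "points": [[x,y,z], ...]}`.
#' @param tracings a [tracing_set()].
#' @param path file path.
#' @export
write_tracings <- function(tracings, path) {
  obj <- lapply(tracings, function(pl)
    list(plane_id = pl$plane_id, points = fmt9(unname(pl$points))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tracings
#' @export
read_tracings <- function(path) {
  if (!file.exists(path)) stop("read_tracings: no such file: ", path)
  x <- jsonlite::read_json(path)
  tracing_set(lapply(x, function(pl) {
    if (is.null(pl$plane_id) || is.null(pl$points))
      stop("read_tracings: ", path,
           ": each entry needs 'plane_id' and 'points'")
    list(plane_id = pl$plane_id,
         points = do.call(rbind, lapply(pl$points, unlist)))
  }))
}

#' Write / read the solver + force configuration (YAML)
#'
#' One documented file holding every solver default: `solver` ([solver_config()]
#' fields) and `phase` ([force_phase()] fields).
#' @param config a [solver_config()].
#' @param phase a [force_phase()].
#' @param path file path.
#' @export
write_config <- function(config, phase, path) {
  yaml::write_yaml(list(solver = unclass(config), phase = unclass(phase)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  x <- yaml::read_yaml(path)
  list(solver = do.call(solver_config, x$solver),
       phase = do.call(force_phase, x$phase))
}

#' Write a scene bundle to a directory
#'
#' Writes `mesh.ply`, `landmarks.json`, `cords.json`, `config.yaml` and, when
#' present, `tracings.json`.
#'
#' @param scene a `valve_scene`.
#' @param dir output directory (created if needed).
#' @param config,phase solver configuration stored alongside.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, config = solver_config(),
                        phase = force_phase()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(scene$mesh$positions, scene$mesh$triangles,
             file.path(dir, "mesh.ply"))
  write_landmarks(scene$mesh, scene$contour, file.path(dir, "landmarks.json"))
  write_cords(scene$cords, file.path(dir, "cords.json"))
  write_config(config, phase, file.path(dir, "config.yaml"))
  if (!is.null(scene$tracings))
    write_tracings(scene$tracings, file.path(dir, "tracings.json"))
  invisible(dir)
}

#' Load and cross-validate a scene bundle
#'
#' Reads the bundle written by [write_scene()], validates every schema,
#' checks cross-file index references, rebuilds the oriented annulus plane
#' and returns a simulatable `valve_scene`.
#'
#' @param dir bundle directory.
#' @return A `valve_scene` (plus `config`/`phase` attributes from
#'   `config.yaml` when present).
#' @export
load_scene <- function(dir) {
  m <- read_mesh(file.path(dir, "mesh.ply"))
  lm <- read_landmarks(file.path(dir, "landmarks.json"))
  if (length(lm$leaflet_label) != nrow(m$pos))
    stop("load_scene: landmarks.json leaflet_label length ",
         length(lm$leaflet_label), " does not match mesh vertex count ",
         nrow(m$pos))
  if (any(lm$annulus_ids > nrow(m$pos)) || any(lm$free_edge_ids > nrow(m$pos)))
    stop("load_scene: landmarks.json contains out-of-range vertex indices")
  mesh <- valve_mesh(m$pos, m$triangles, lm$leaflet_label,
                     lm$annulus_ids, lm$free_edge_ids)
  open_poly <- matrix(unlist(lm$annulus_open), ncol = 3,
                      byrow = !is.matrix(lm$annulus_open))
  closed_poly <- matrix(unlist(lm$annulus_closed), ncol = 3,
                        byrow = !is.matrix(lm$annulus_closed))
  contour <- annulus_contour(open_poly, closed_poly, lm$close_duration)
  plane <- orient_plane(fit_annulus_plane(contour$open), mesh)
  cords <- read_cords(file.path(dir, "cords.json"), mesh = mesh, plane = plane)
  tracings <- if (file.exists(file.path(dir, "tracings.json")))
    read_tracings(file.path(dir, "tracings.json")) else NULL
  scene <- structure(list(mesh = mesh, contour = contour, plane = plane,
                          cords = cords, subsets = NULL,
                          material = material_params(), params = NULL,
                          tracings = tracings),
                     class = "valve_scene")
  if (file.exists(file.path(dir, "config.yaml"))) {
    cf <- read_config(file.path(dir, "config.yaml"))
    attr(scene, "config") <- cf$solver
    attr(scene, "phase") <- cf$phase
  }
  scene
}

#' Write a Table-1-style deviation report row / CSV
#'
#' Columns: Case, Area_mm2, MinD, MedD, MaxD, AvgD, SD, Prolapse.
#'
#' @param case case label.
#' @param area total leaflet surface area (mm^2).
#' @param deviation a `deviation_report` (or `NULL`).
#' @param prolapse a `prolapse_report` (or `NULL`).
#' @return One-row data frame.
#' @export
report_row <- function(case, area, deviation = NULL, prolapse = NULL) {
  data.frame(
    Case = case, Area_mm2 = round(area),
    MinD = if (is.null(deviation)) NA else round(deviation$min_d, 2),
    MedD = if (is.null(deviation)) NA else round(deviation$med_d, 2),
    MaxD = if (is.null(deviation)) NA else round(deviation$max_d, 2),
    AvgD = if (is.null(deviation)) NA else round(deviation$avg_d, 2),
    SD = if (is.null(deviation)) NA else round(deviation$sd_d, 2),
    Prolapse = if (is.null(prolapse)) NA else
      (if (prolapse$prolapse) "Yes" else "No"))
}

## --- session script JSON ----------------------------------------------------

#' Read a session script
#'
#' JSON: a list of entries, each either
#' `{"t": 0.25, "scope": "group", "target": "...", "factor": 0.85}` or
#' `{"t": 0.5, "switch_phase": true}`.
#' @param path file path.
#' @return list of commands for [run_session()].
#' @export
read_session_script <- function(path) {
  if (!file.exists(path)) stop("read_session_script: no such file: ", path)
  x <- jsonlite::read_json(path)
  lapply(x, function(e) {
    if (isTRUE(e$switch_phase)) list(t = e$t, switch_phase = TRUE)
    else list(t = e$t,
              command = edit_command(e$scope,
                                     if (e$scope == "single") as.integer(e$target) + 1L
                                     else e$target,
                                     e$factor,
                                     absolute = isTRUE(e$absolute)))
  })
}
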