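#' Triangle mesh
#'
#' An indexed triangle surface in millimetres. Vertices are stored as an
#' `n x 3` numeric matrix, faces as an `m x 3` integer matrix of 1-based
#' vertex indices. On construction duplicate vertices are merged within
#' `merge_tol` and degenerate (zero-area or repeated-index) faces are
#' dropped, so a valid mesh never contains them.
#'
#' The shared coordinate frame is right-handed and patient-supine:
#' +x left, +y superior, +z anterior. All lengths are millimetres.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates, mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param name text label carried through I/O and reports.
#' @param clean merge duplicate vertices and drop degenerate faces
#'   (default `TRUE`).
#' @param merge_tol vertex merge tolerance in mm (default `1e-6`, well below
#'   anatomical relevance).
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh", clean = TRUE,
                          merge_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) {
    stop("vertices must have 3 columns (x, y, z in mm)", call. = FALSE)
  }
  if (!all(is.finite(vertices))) {
    stop("vertices contain non-finite coordinates", call. = FALSE)
  }
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L && ncol(faces) != 3L) {
    stop("faces must have 3 columns", call. = FALSE)
  }
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  mesh <- structure(
    list(vertices = unname(vertices), faces = unname(faces),
         name = as.character(name)[1]),
    class = "triangle_mesh"
  )
  if (clean) mesh <- clean_mesh(mesh, merge_tol = merge_tol)
  if (nrow(mesh$faces) == 0L) {
    stop("mesh '", mesh$name, "' has no faces after cleaning", call. = FALSE)
  }
  mesh
}

#' Merge duplicate vertices and drop degenerate faces
#'
#' Vertices closer than `merge_tol` (snapped to a grid of that pitch) are
#' merged; faces with repeated indices or zero area are removed. Cleaning
#' never increases vertex or face counts.
#'
#' @param mesh a `triangle_mesh`.
#' @param merge_tol merge tolerance in mm.
#' @return The cleaned `triangle_mesh`.
#' @export
clean_mesh <- function(mesh, merge_tol = 1e-6) {
  v <- mesh$vertices
  f <- mesh$faces
  key <- apply(round(v / merge_tol), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  v <- v[first, , drop = FALSE]
  if (nrow(f) > 0L) {
    f <- matrix(remap[f], ncol = 3L)
    keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[keep, , drop = FALSE]
    if (nrow(f) > 0L) {
      f <- f[face_areas_of(v, f) > 0, , drop = FALSE]
    }
  }
  # drop unreferenced vertices
  if (nrow(f) > 0L) {
    used <- sort(unique(as.vector(f)))
    f <- matrix(match(f, used), ncol = 3L)
    v <- v[used, , drop = FALSE]
  }
  mesh$vertices <- v
  mesh$faces <- f
  mesh
}

face_areas_of <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Extract a sub-mesh of selected faces
#'
#' Keeps the listed faces (and the vertices they reference). Used e.g. to
#' isolate the skull's outer table as the occluder for exposure
#' evaluation.
#'
#' @param mesh a `triangle_mesh`.
#' @param faces face indices to keep.
#' @return A `triangle_mesh`.
#' @export
submesh <- function(mesh, faces) {
  triangle_mesh(mesh$vertices, mesh$faces[faces, , drop = FALSE],
                name = mesh$name)
}

#' Per-face areas, centroids and normals
#'
#' @param mesh a `triangle_mesh`.
#' @return `face_areas`: numeric vector of triangle areas in mm^2.
#' @export
face_areas <- function(mesh) face_areas_of(mesh$vertices, mesh$faces)

#' @rdname face_areas
#' @return `face_centroids`: m x 3 matrix of triangle centroids.
#' @export
face_centroids <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' @rdname face_areas
#' @return `face_normals`: m x 3 matrix of unit normals (right-hand rule).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
}

#' Edge table of a mesh
#'
#' Unique undirected edges with their incident faces. Edge indices returned
#' by other operations (barrier edges, boundary scans) refer to rows of this
#' table.
#'
#' @param mesh a `triangle_mesh`.
#' @return A list with `edges` (e x 2 matrix, v1 < v2), `n_incident`
#'   (faces per edge), `face_edges` (m x 3 matrix: edge index of each face
#'   side), and `edge_faces` (list of incident face indices per edge).
#' @export
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  ea <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  es <- cbind(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  key <- es[, 1] * (nrow(mesh$vertices) + 1) + es[, 2]
  first <- !duplicated(key)
  idx <- match(key, key[first])
  edges <- es[first, , drop = FALSE]
  face_of <- rep(seq_len(m), 3L)
  edge_faces <- split(face_of, idx)
  edge_faces <- edge_faces[order(as.integer(names(edge_faces)))]
  list(
    edges = edges,
    n_incident = tabulate(idx, nbins = nrow(edges)),
    face_edges = matrix(idx, nrow = m, ncol = 3L),
    edge_faces = unname(edge_faces)
  )
}

#' Boundary edges and watertightness
#'
#' A watertight (closed) mesh has every edge shared by exactly two faces.
#'
#' @param mesh a `triangle_mesh`.
#' @param edge_table optional precomputed [mesh_edge_table()].
#' @return `boundary_edges`: indices into the edge table of edges with a
#'   single incident face.
#' @export
boundary_edges <- function(mesh, edge_table = mesh_edge_table(mesh)) {
  which(edge_table$n_incident == 1L)
}

#' @rdname boundary_edges
#' @return `is_watertight`: `TRUE` iff every edge has exactly two incident
#'   faces.
#' @export
is_watertight <- function(mesh, edge_table = mesh_edge_table(mesh)) {
  all(edge_table$n_incident == 2L)
}

#' Euler characteristic per connected component
#'
#' Components are taken over shared vertices. A closed surface of sphere
#' topology has characteristic V - E + F = 2.
#'
#' @param mesh a `triangle_mesh`.
#' @return Integer vector, one Euler characteristic per component.
#' @export
euler_characteristics <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  # union-find over vertices joined by faces
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(f))) {
    r1 <- find(f[k, 1]); r2 <- find(f[k, 2]); r3 <- find(f[k, 3])
    parent[r2] <- r1
    parent[find(r3)] <- r1
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  comp <- match(roots, unique(roots))
  et <- mesh_edge_table(mesh)
  vcomp <- tabulate(comp, nbins = max(comp))
  ecomp <- tabulate(comp[et$edges[, 1]], nbins = max(comp))
  fcomp <- tabulate(comp[f[, 1]], nbins = max(comp))
  as.integer(vcomp - ecomp + fcomp)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces (mm)\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Surface contour
#'
#' An ordered 3-D polyline in millimetres, optionally closed (the last point
#' connects back to the first). Consecutive duplicate points are removed on
#' construction; a closed contour whose stored last point equals its first
#' has the repeat dropped.
#'
#' @param points numeric matrix (n x 3) of points in mm.
#' @param closed logical; treat first and last point as connected.
#' @param name text label.
#' @param line_width_mm optional stroke width of the drawn line, mm
#'   (metadata; used by the phantom templates).
#' @return An object of class `surface_contour`.
#' @export
surface_contour <- function(points, closed = FALSE, name = "contour",
                            line_width_mm = NA_real_) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("contour points must be x,y,z", call. = FALSE)
  if (!all(is.finite(points))) {
    stop("contour points contain non-finite values", call. = FALSE)
  }
  if (nrow(points) > 1L) {
    d <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
    points <- points[c(TRUE, d > 0), , drop = FALSE]
  }
  if (isTRUE(closed) && nrow(points) > 2L &&
      sqrt(sum((points[1L, ] - points[nrow(points), ])^2)) == 0) {
    points <- points[-nrow(points), , drop = FALSE]
  }
  if (nrow(points) < 2L) {
    stop("a contour needs at least 2 distinct points", call. = FALSE)
  }
  structure(
    list(points = unname(points), closed = isTRUE(closed),
         name = as.character(name)[1],
         line_width_mm = as.numeric(line_width_mm)[1]),
    class = "surface_contour"
  )
}

#' @export
print.surface_contour <- function(x, ...) {
  cat(sprintf("surface_contour '%s': %d points, %s, length %.2f mm\n",
              x$name, nrow(x$points), if (x$closed) "closed" else "open",
              contour_length(x)))
  invisible(x)
}

#' Total polyline length (including the closing segment if closed)
#'
#' @param contour a `surface_contour`.
#' @return Length in mm.
#' @export
contour_length <- function(contour) {
  p <- contour$points
  if (contour$closed) p <- rbind(p, p[1L, ])
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                      p[-nrow(p), , drop = FALSE])^2)))
}

contour_segments <- function(contour) {
  p <- contour$points
  if (contour$closed) p <- rbind(p, p[1L, ])
  list(a = p[-nrow(p), , drop = FALSE], b = p[-1L, , drop = FALSE])
}

#' Named anatomical landmark
#'
#' @param name non-empty label, e.g. `"optic_nerve"`, `"pterion"`,
#'   `"target"`.
#' @param position 3-D point, mm.
#' @return An object of class `landmark`.
#' @export
landmark <- function(name, position) {
  name <- as.character(name)[1]
  if (is.na(name) || !nzchar(name)) {
    stop("landmark name must be non-empty", call. = FALSE)
  }
  position <- as.numeric(position)
  if (length(position) != 3L || !all(is.finite(position))) {
    stop("landmark position must be a finite 3-vector", call. = FALSE)
  }
  structure(list(name = name, position = position), class = "landmark")
}

#' @export
print.landmark <- function(x, ...) {
  cat(sprintf("landmark '%s' at (%.2f, %.2f, %.2f) mm\n", x$name,
              x$position[1], x$position[2], x$position[3]))
  invisible(x)
}
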