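#' Outer-surface faces of a skull mesh
#'
#' Only the outer table of the skull participates in craniotomy drawing,
#' region growing and excision. On the phantom shell the outer surface is
#' identified by face-centroid radius above the mean shell radius; on a
#' single-sheet mesh (all centroid radii within 20% of each other) every
#' face is outer. For arbitrary meshes an explicit label vector can be
#' supplied instead.
#'
#' @param mesh a `triangle_mesh`.
#' @param labels optional logical vector (one per face): `TRUE` = outer.
#' @return Integer vector of outer face indices.
#' @export
outer_surface_faces <- function(mesh, labels = NULL) {
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(mesh$faces))
    return(which(as.logical(labels)))
  }
  cen <- face_centroids(mesh)
  ctr <- colMeans(mesh$vertices)
  r <- sqrt(rowSums(sweep(cen, 2, ctr)^2))
  # a single-sheet sphere-like mesh varies by faceting sag only (<2%);
  # a shell separates cleanly about the mean radius
  if (max(r) / max(min(r), 1e-12) < 1.02) return(seq_len(nrow(mesh$faces)))
  which(r > mean(r))
}

#' Project a drawn contour onto the skull surface
#'
#' Each raw point is snapped to its nearest point on the mesh; consecutive
#' snapped points are connected along the surface by recursive chord
#' subdivision (a chord is split until its midpoint lies within
#' `snap_tol_mm` of the surface and its endpoints lie in edge-adjacent
#' faces). Mesh edges crossed by the resulting surface path are collected
#' as barrier edges for region growing; a path that slips through a vertex
#' is routed around that vertex's one-ring so the barrier stays sealed.
#'
#' @param skull a `triangle_mesh`.
#' @param raw a `surface_contour` with at least 3 points (the freehand
#'   drawing).
#' @param snap_tol_mm snap tolerance, mm (default 0.5). Also used as the
#'   endpoint-gap tolerance for closure: the projected contour is closed
#'   iff its first and last points coincide within `snap_tol_mm` (or the
#'   raw contour is flagged closed).
#' @param outer_labels optional per-face outer-surface labels, see
#'   [outer_surface_faces()]; drawing only ever targets the outer table.
#' @return A `projected_contour`: `contour` (dense on-surface polyline),
#'   `barrier_edges` (row indices into [mesh_edge_table()] of the skull),
#'   `closed`, `snap_tol_mm`, and the cached `edge_table`.
#' @export
project_contour <- function(skull, raw, snap_tol_mm = 0.5,
                            outer_labels = NULL) {
  stopifnot(inherits(raw, "surface_contour"))
  if (nrow(raw$points) < 3L) {
    stop("a drawn contour needs at least 3 points", call. = FALSE)
  }
  outer <- outer_surface_faces(skull, outer_labels)
  pr <- nearest_point_on_mesh(skull, raw$points, face_subset = outer)
  if (any(pr$distances > 10 * snap_tol_mm)) {
    stop(sprintf("drawn point %.1f mm from the skull surface (limit %.1f)",
                 max(pr$distances), 10 * snap_tol_mm), call. = FALSE)
  }
  n_raw <- nrow(pr$points)
  gap <- sqrt(sum((pr$points[1L, ] - pr$points[n_raw, ])^2))
  closed <- isTRUE(raw$closed) || gap <= snap_tol_mm

  et <- mesh_edge_table(skull)
  pts <- pr$points
  fcs <- pr$faces
  if (closed) {
    pts <- rbind(pts, pts[1L, ])
    fcs <- c(fcs, fcs[1L])
  }

  path_p <- list(pts[1L, ])
  path_f <- list(fcs[1L])
  for (i in seq_len(nrow(pts) - 1L)) {
    seg <- subdivide_chord(skull, et, outer, pts[i, ], fcs[i],
                           pts[i + 1L, ], fcs[i + 1L], snap_tol_mm,
                           depth = 0L)
    path_p <- c(path_p, seg$points, list(pts[i + 1L, ]))
    path_f <- c(path_f, seg$faces, list(fcs[i + 1L]))
  }
  dense_p <- do.call(rbind, path_p)
  dense_f <- unlist(path_f)

  # reject drawings whose surface path crosses itself
  check_path_self_intersection(dense_p, dense_f, et, closed, snap_tol_mm)

  barrier <- collect_barrier_edges(skull, et, dense_f)
  dense_contour <- surface_contour(
    if (closed) dense_p[-nrow(dense_p), , drop = FALSE] else dense_p,
    closed = closed, name = paste0(raw$name, "_projected")
  )
  structure(
    list(contour = dense_contour, barrier_edges = barrier,
         path_faces = unique(dense_f), closed = closed,
         snap_tol_mm = snap_tol_mm, edge_table = et),
    class = "projected_contour"
  )
}

#' @export
print.projected_contour <- function(x, ...) {
  cat(sprintf(
    "projected_contour: %d surface points, %d barrier edges, %s\n",
    nrow(x$contour$points), length(x$barrier_edges),
    if (x$closed) "closed" else "open"))
  invisible(x)
}

# A genuine self-crossing of the surface path happens inside (or at the
# rim of) a single face, so only segment pairs whose assigned faces are
# equal or edge-adjacent need an exact distance test. Pairs close along
# the curve (arc-length separation under 4 snap tolerances) are the
# path's own continuity, not a crossing, and are skipped.
check_path_self_intersection <- function(pts, fcs, et, closed, tol) {
  ns <- nrow(pts) - 1L
  if (ns < 3L) return(invisible(TRUE))
  seg_len <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2))
  live <- which(seg_len > 1e-12)
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  min_sep <- 4 * tol
  for (a in seq_along(live)) {
    i <- live[a]
    for (b in seq_along(live)) {
      if (b <= a) next
      j <- live[b]
      # arc gap between the end of segment i and the start of segment j
      # (and around the closure): consecutive stretches of the curve may
      # touch, far-apart ones may not
      ds <- cum[j] - cum[i + 1L]
      if (closed) ds <- min(ds, total - (cum[j + 1L] - cum[i]))
      if (ds < min_sep) next
      if (fcs[i] != fcs[j] && !faces_share_edge(et, fcs[i], fcs[j])) next
      d <- segment_segment_distance(pts[i, ], pts[i + 1L, ],
                                    pts[j, ], pts[j + 1L, ])
      if (d < 1e-6) {
        stop("drawn contour intersects itself", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

faces_share_edge <- function(et, fa, fb) {
  length(intersect(et$face_edges[fa, ], et$face_edges[fb, ])) > 0L
}

# Interior points/faces of the surface path between two snapped points.
subdivide_chord <- function(skull, et, outer, pa, fa, pb, fb, tol, depth) {
  if (depth > 24L || sum((pa - pb)^2) < 1e-14) {
    return(list(points = list(), faces = list()))
  }
  mid <- (pa + pb) / 2
  nm <- nearest_point_on_mesh(skull, mid, face_subset = outer)
  need <- nm$distances[1] > tol ||
    (fa != fb && !faces_share_edge(et, fa, fb))
  if (!need) return(list(points = list(), faces = list()))
  pm <- nm$points[1, ]
  fm <- nm$faces[1]
  left <- subdivide_chord(skull, et, outer, pa, fa, pm, fm, tol,
                          depth + 1L)
  right <- subdivide_chord(skull, et, outer, pm, fm, pb, fb, tol,
                           depth + 1L)
  list(points = c(left$points, list(pm), right$points),
       faces = c(left$faces, list(fm), right$faces))
}

# Edges crossed by the face sequence of the dense path. Consecutive
# distinct faces contribute their shared edge; a vertex crossing (faces
# sharing only a vertex) is sealed by walking the one-ring between them.
collect_barrier_edges <- function(skull, et, face_seq) {
  fs <- face_seq[c(TRUE, diff(face_seq) != 0L)]
  barrier <- integer(0)
  for (i in seq_len(length(fs) - 1L)) {
    fa <- fs[i]; fb <- fs[i + 1L]
    shared <- intersect(et$face_edges[fa, ], et$face_edges[fb, ])
    if (length(shared)) {
      barrier <- c(barrier, shared[1L])
    } else {
      barrier <- c(barrier, one_ring_route(skull, et, fa, fb))
    }
  }
  sort(unique(barrier))
}

# Edges crossed when hopping between two faces that share only a vertex:
# BFS through the faces incident to the shared vertex.
one_ring_route <- function(skull, et, fa, fb) {
  va <- skull$faces[fa, ]
  vb <- skull$faces[fb, ]
  v <- intersect(va, vb)
  if (length(v) == 0L) {
    stop("projected path jumped between unconnected faces; ",
         "increase sampling density (smaller snap_tol_mm)", call. = FALSE)
  }
  v <- v[1L]
  ring <- which(rowSums(skull$faces == v) > 0L)
  # BFS over the ring from fa to fb, recording shared edges along the path
  prev <- stats::setNames(rep(NA_integer_, length(ring)), ring)
  queue <- fa
  prev[as.character(fa)] <- 0L
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    if (cur == fb) break
    for (nb in ring) {
      if (!is.na(prev[as.character(nb)])) next
      if (faces_share_edge(et, cur, nb)) {
        prev[as.character(nb)] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  if (is.na(prev[as.character(fb)])) return(integer(0))
  edges <- integer(0)
  cur <- fb
  while (prev[as.character(cur)] != 0L) {
    p <- prev[as.character(cur)]
    edges <- c(edges, intersect(et$face_edges[p, ],
                                et$face_edges[cur, ])[1L])
    cur <- p
  }
  edges
}

#' Grow the craniotomy region inside a closed contour
#'
#' Breadth-first growth over the face-adjacency graph of the skull's outer
#' surface, starting from the face containing the seed point and never
#' crossing a barrier edge of the projected contour. Growth that reaches
#' more than `leak_fraction` of the outer-surface area aborts as a leak,
#' signalling a gap in the barrier.
#'
#' @param skull a `triangle_mesh`.
#' @param contour a `projected_contour` with `closed = TRUE`.
#' @param seed_point 3-vector, mm; must lie within the snap tolerance of
#'   the outer surface and not on a barrier edge.
#' @param leak_fraction abort threshold as a fraction of total
#'   outer-surface area (default 0.5).
#' @param outer_labels optional per-face outer-surface labels, see
#'   [outer_surface_faces()].
#' @return A `craniotomy_region`: `face_ids`, `seed_face`, `area_mm2`,
#'   `barrier_edges`.
#' @export
region_grow <- function(skull, contour, seed_point, leak_fraction = 0.5,
                        outer_labels = NULL) {
  stopifnot(inherits(contour, "projected_contour"))
  if (!contour$closed) {
    stop(errorCondition("contour is not closed; cannot region-grow",
                        class = c("craniotome_open_contour_error", "error")))
  }
  et <- contour$edge_table
  outer <- outer_surface_faces(skull, outer_labels)
  nm <- nearest_point_on_mesh(skull, seed_point, face_subset = outer)
  if (nm$distances[1] > contour$snap_tol_mm) {
    stop(errorCondition(
      sprintf("seed point is %.2f mm from the outer surface",
              nm$distances[1]),
      class = c("craniotome_seed_error", "error")))
  }
  seed_face <- nm$faces[1]
  if (length(contour$barrier_edges)) {
    be <- et$edges[contour$barrier_edges, , drop = FALSE]
    d <- point_segment_distances(seed_point,
                                 skull$vertices[be[, 1], , drop = FALSE],
                                 skull$vertices[be[, 2], , drop = FALSE])
    if (min(d) < 1e-6) {
      stop(errorCondition("seed point lies on a barrier edge",
                          class = c("craniotome_seed_error", "error")))
    }
  }
  grown <- flood_fill_faces(skull, et, seed_face, contour$barrier_edges,
                            outer)
  areas <- face_areas(skull)
  total <- sum(areas[outer])
  area <- sum(areas[grown])
  if (area > leak_fraction * total) {
    stop(errorCondition(
      sprintf(paste0("region growing leaked: %.0f of %.0f mm^2 (%.0f%%) ",
                     "reached; the contour barrier has a gap"),
              area, total, 100 * area / total),
      class = c("craniotome_leak_error", "error")))
  }
  structure(
    list(face_ids = sort(grown), seed_face = seed_face, area_mm2 = area,
         barrier_edges = contour$barrier_edges),
    class = "craniotomy_region"
  )
}

#' @export
print.craniotomy_region <- function(x, ...) {
  cat(sprintf("craniotomy_region: %d faces, %.1f mm^2\n",
              length(x$face_ids), x$area_mm2))
  invisible(x)
}

# BFS flood fill over face adjacency restricted to `outer`, never crossing
# barrier edges.
flood_fill_faces <- function(mesh, et, seed_face, barrier_edges, outer) {
  m <- nrow(mesh$faces)
  is_outer <- logical(m)
  is_outer[outer] <- TRUE
  is_barrier <- logical(length(et$n_incident))
  is_barrier[barrier_edges] <- TRUE
  visited <- logical(m)
  visited[seed_face] <- TRUE
  queue <- seed_face
  head <- 1L
  while (head <= length(queue)) {
    cur <- queue[head]; head <- head + 1L
    for (e in et$face_edges[cur, ]) {
      if (is_barrier[e] || et$n_incident[e] != 2L) next
      for (nb in et$edge_faces[[e]]) {
        if (!visited[nb] && is_outer[nb]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  which(visited)
}

#' Excise the craniotomy bone patch
#'
#' Removes the region's faces from the skull mesh. For a region grown
#' inside a closed contour the result gains exactly one new boundary loop
#' tracing the barrier cycle.
#'
#' @param skull a `triangle_mesh`.
#' @param region a `craniotomy_region` (an empty `face_ids` vector returns
#'   the skull unchanged).
#' @return The cut `triangle_mesh`.
#' @export
excise <- function(skull, region) {
  ids <- region$face_ids
  if (length(ids) == 0L) return(skull)
  if (min(ids) < 1L || max(ids) > nrow(skull$faces)) {
    stop("region references faces absent from the skull", call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(skull$faces)), ids)
  triangle_mesh(skull$vertices, skull$faces[keep, , drop = FALSE],
                name = paste0(skull$name, "_cut"))
}
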