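# Geometry kernel: closest points, ray casting, segment distances.
# All routines vectorise over triangles/segments for a single query and
# loop over queries; mesh sizes here (<= ~10^4 faces) keep this fast.

# Closest point on each triangle (a, b, c row-matrices) to point p.
# Ericson-style region classification, vectorised over triangles.
closest_point_on_triangles <- function(p, a, b, c) {
  ab <- b - a
  ac <- c - a
  ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- matrix(p, nrow(a), 3, byrow = TRUE) - b
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- matrix(p, nrow(a), 3, byrow = TRUE) - c
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  q <- matrix(NA_real_, nrow(a), 3)
  done <- rep(FALSE, nrow(a))

  set_q <- function(mask, val) {
    mask <- mask & !done
    if (any(mask)) {
      q[mask, ] <<- val[mask, , drop = FALSE]
      done[mask] <<- TRUE
    }
  }
  set_q(d1 <= 0 & d2 <= 0, a)                               # vertex a
  set_q(d3 >= 0 & d4 <= d3, b)                              # vertex b
  set_q(d6 >= 0 & d5 <= d6, c)                              # vertex c
  t_ab <- d1 / (d1 - d3)
  set_q(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * t_ab)         # edge ab
  t_ac <- d2 / (d2 - d6)
  set_q(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * t_ac)         # edge ac
  t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_q(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
        b + (c - b) * t_bc)                                 # edge bc
  denom <- va + vb + vc
  v <- vb / denom
  w <- vc / denom
  set_q(!done, a + ab * v + ac * w)                         # interior
  q
}

#' Nearest point on a mesh surface
#'
#' Exact closest-point query against every triangle (with a cheap
#' centroid-based prefilter), one query point at a time.
#'
#' @param mesh a `triangle_mesh`.
#' @param points query point (3-vector) or n x 3 matrix.
#' @param face_subset optional face indices to restrict the query to
#'   (e.g. the skull's outer surface); returned face ids stay in the full
#'   mesh's indexing.
#' @return A list with `points` (n x 3 nearest surface points), `faces`
#'   (index of the realising triangle) and `distances` (mm).
#' @export
nearest_point_on_mesh <- function(mesh, points, face_subset = NULL) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  points <- as.matrix(points)
  v <- mesh$vertices
  f <- mesh$faces
  remap <- NULL
  if (!is.null(face_subset)) {
    remap <- as.integer(face_subset)
    f <- f[remap, , drop = FALSE]
  }
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  cen <- (a + b + c) / 3
  # circumradius bound: max distance from centroid to a corner
  rad <- sqrt(pmax(rowSums((a - cen)^2),
                   rowSums((b - cen)^2),
                   rowSums((c - cen)^2)))
  n <- nrow(points)
  out_p <- matrix(NA_real_, n, 3)
  out_f <- integer(n)
  out_d <- numeric(n)
  for (i in seq_len(n)) {
    p <- points[i, ]
    dc <- sqrt(rowSums((cen - matrix(p, nrow(cen), 3, byrow = TRUE))^2))
    lb <- dc - rad                      # lower bound on true distance
    cut <- min(dc + rad)                # best achievable upper bound
    cand <- which(lb <= cut)
    q <- closest_point_on_triangles(p, a[cand, , drop = FALSE],
                                    b[cand, , drop = FALSE],
                                    c[cand, , drop = FALSE])
    d <- sqrt(rowSums((q - matrix(p, length(cand), 3, byrow = TRUE))^2))
    j <- which.min(d)
    out_p[i, ] <- q[j, ]
    out_f[i] <- if (is.null(remap)) cand[j] else remap[cand[j]]
    out_d[i] <- d[j]
  }
  list(points = out_p, faces = out_f, distances = out_d)
}

# Moller-Trumbore segment/triangle intersection test.
# Returns TRUE if the open segment p0 -> p1 hits any listed triangle.
segment_hits_mesh <- function(mesh, p0, p1, eps = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  d <- p1 - p0
  dm <- matrix(d, nrow(a), 3, byrow = TRUE)
  pv <- cbind(dm[, 2] * e2[, 3] - dm[, 3] * e2[, 2],
              dm[, 3] * e2[, 1] - dm[, 1] * e2[, 3],
              dm[, 1] * e2[, 2] - dm[, 2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > eps
  if (!any(ok)) return(FALSE)
  tv <- matrix(p0, nrow(a), 3, byrow = TRUE) - a
  u <- rowSums(tv * pv) / det
  ok <- ok & u >= 0 & u <= 1
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  w <- rowSums(dm * qv) / det
  ok <- ok & w >= 0 & (u + w) <= 1
  tt <- rowSums(e2 * qv) / det
  any(ok & tt > eps & tt < 1 - eps)
}

# Distance from point p to each segment (a[i,] -> b[i,]).
point_segment_distances <- function(p, a, b) {
  ab <- b - a
  ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a
  len2 <- rowSums(ab^2)
  t <- ifelse(len2 > 0, rowSums(ap * ab) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  q <- a + ab * t
  sqrt(rowSums((q - matrix(p, nrow(a), 3, byrow = TRUE))^2))
}

#' Exact distance from a point to a polyline
#'
#' Minimum over all segments of the exact point-to-segment distance
#' (including the closing segment of a closed contour).
#'
#' @param p 3-vector, mm.
#' @param contour a `surface_contour`.
#' @return Distance in mm.
#' @export
point_to_contour_distance <- function(p, contour) {
  seg <- contour_segments(contour)
  min(point_segment_distances(p, seg$a, seg$b))
}

# Minimum distance between two 3-D segments (p1->p2, q1->q2).
segment_segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-300 && e <= 1e-300) return(sqrt(sum(r^2)))
  if (a <= 1e-300) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    cc <- sum(d1 * r)
    if (e <= 1e-300) {
      t <- 0; s <- min(max(-cc / a, 0), 1)
    } else {
      bb <- sum(d1 * d2)
      den <- a * e - bb * bb
      s <- if (den > 0) min(max((bb * f - cc * e) / den, 0), 1) else 0
      t <- (bb * s + f) / e
      if (t < 0) {
        t <- 0; s <- min(max(-cc / a, 0), 1)
      } else if (t > 1) {
        t <- 1; s <- min(max((bb - cc) / a, 0), 1)
      }
    }
  }
  sqrt(sum((p1 + d1 * s - (q1 + d2 * t))^2))
}

# Rotation matrix about a unit axis by angle (degrees), right-handed.
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * co + si * K + (1 - co) * (u %o% u)
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# Two unit vectors spanning the plane orthogonal to unit normal n.
plane_basis <- function(n) {
  n <- normalize3(n)
  h <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize3(c(h[2] * n[3] - h[3] * n[2],
                    h[3] * n[1] - h[1] * n[3],
                    h[1] * n[2] - h[2] * n[1]))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}
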