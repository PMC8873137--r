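# Fixtures are built in code; heavier scenes are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

test_scene <- function(level = 3L) {
  cached(paste0("scene", level), function() {
    generate_phantom(phantom_config(subdivision_level = level))
  })
}

cube_mesh <- function(size = 1) {
  v <- size * as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  triangle_mesh(v, f, name = "cube")
}

random_polyline <- function(n, scale = 30, closed = FALSE) {
  surface_contour(matrix(stats::runif(3 * n, -scale, scale), ncol = 3),
                  closed = closed)
}

# Square occluder plane at z = z0 spanning +/-half, with a square hole
# |x|,|y| < hole_half. Exact geometry for analytic visibility checks.
plane_with_hole <- function(z0 = 40, half = 300, hole_half = 6) {
  h <- hole_half
  H <- half
  v <- rbind(
    c(-H, -H, z0), c(H, -H, z0), c(H, H, z0), c(-H, H, z0),
    c(-h, -h, z0), c(h, -h, z0), c(h, h, z0), c(-h, h, z0)
  )
  f <- rbind(
    c(1, 2, 6), c(1, 6, 5),
    c(2, 3, 7), c(2, 7, 6),
    c(3, 4, 8), c(3, 8, 7),
    c(4, 1, 5), c(4, 5, 8)
  )
  triangle_mesh(v, f, name = "plane_with_hole")
}

# ---- independent oracles ----

# Arc-length resampler coded independently of resample_contour().
oracle_resample <- function(contour, step) {
  p <- contour$points
  if (contour$closed) p <- rbind(p, p[1, ])
  lens <- sqrt(rowSums(diff(p)^2))
  total <- sum(lens)
  n <- ceiling(total / step)
  targets <- if (contour$closed) total * (0:(n - 1)) / n else total * (0:n) / n
  out <- matrix(NA_real_, length(targets), 3)
  for (k in seq_along(targets)) {
    s <- targets[k]
    acc <- 0
    for (i in seq_along(lens)) {
      if (s <= acc + lens[i] + 1e-12) {
        t <- if (lens[i] > 0) (s - acc) / lens[i] else 0
        out[k, ] <- p[i, ] + t * (p[i + 1, ] - p[i, ])
        break
      }
      acc <- acc + lens[i]
    }
  }
  out
}

# Exhaustive point-to-segment distance, explicit loops.
oracle_point_polyline_dist <- function(q, contour) {
  p <- contour$points
  if (contour$closed) p <- rbind(p, p[1, ])
  best <- Inf
  for (i in seq_len(nrow(p) - 1)) {
    a <- p[i, ]; b <- p[i + 1, ]
    ab <- b - a
    t <- sum((q - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    best <- min(best, sqrt(sum((a + t * ab - q)^2)))
  }
  best
}

oracle_hausdorff <- function(A, B, step) {
  pa <- oracle_resample(A, step)
  pb <- oracle_resample(B, step)
  h_ab <- max(vapply(seq_len(nrow(pa)), function(i) {
    oracle_point_polyline_dist(pa[i, ], B)
  }, numeric(1)))
  h_ba <- max(vapply(seq_len(nrow(pb)), function(i) {
    oracle_point_polyline_dist(pb[i, ], A)
  }, numeric(1)))
  max(h_ab, h_ba)
}

oracle_surface_dsc <- function(A, B, tol, step) {
  pa <- oracle_resample(A, step)
  pb <- oracle_resample(B, step)
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pa))) {
    if (oracle_point_polyline_dist(pa[i, ], B) <= tol) tp <- tp + 1
    else fp <- fp + 1
  }
  for (i in seq_len(nrow(pb))) {
    if (oracle_point_polyline_dist(pb[i, ], A) > tol) fn <- fn + 1
  }
  2 * tp / (2 * tp + fp + fn)
}

# Flood fill over face adjacency, built from scratch (its own adjacency
# construction and a stack-based fill).
oracle_flood_fill <- function(mesh, seed_face, barrier_edges, outer) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  ekey <- function(i, j) pmin(i, j) * (nv + 1) + pmax(i, j)
  # barrier edge keys from the package edge table rows
  et <- mesh_edge_table(mesh)
  bkeys <- ekey(et$edges[barrier_edges, 1], et$edges[barrier_edges, 2])
  keys <- cbind(ekey(f[, 1], f[, 2]), ekey(f[, 2], f[, 3]),
                ekey(f[, 3], f[, 1]))
  is_outer <- logical(nrow(f)); is_outer[outer] <- TRUE
  # adjacency: faces sharing a non-barrier edge key
  adj <- vector("list", nrow(f))
  by_key <- split(rep(seq_len(nrow(f)), 3), as.vector(keys))
  for (k in names(by_key)) {
    fs <- by_key[[k]]
    if (length(fs) == 2 && !(as.numeric(k) %in% bkeys)) {
      adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
      adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
    }
  }
  seen <- logical(nrow(f))
  stack <- seed_face
  seen[seed_face] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (nb in adj[[cur]]) {
      if (!seen[nb] && is_outer[nb]) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  which(seen)
}

# Draw a latitude circle (polar angle theta about `axis`) on a sphere of
# radius r centred at the origin, as a closed raw contour.
latitude_contour <- function(axis, r, theta, n = 48) {
  axis <- axis / sqrt(sum(axis^2))
  h <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- h - sum(h * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  az <- 2 * pi * (seq_len(n) - 1) / n
  pts <- r * (sin(theta) * (cos(az) %o% u + sin(az) %o% v) +
                cos(theta) * matrix(axis, n, 3, byrow = TRUE))
  surface_contour(pts, closed = TRUE)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Free mass-spring particle for integrator tests (documented list layout).
free_particle_system <- function(mass = 0.001, dt = 0.005, damping = 0) {
  structure(
    list(positions = matrix(0, 1, 3), prev_positions = matrix(0, 1, 3),
         masses = mass, fixed = FALSE, lobe_label = "frontal",
         springs = matrix(numeric(0), 0, 4,
                          dimnames = list(NULL, c("i", "j", "rest_length",
                                                  "stiffness"))),
         damping = damping, dt = dt),
    class = "mass_spring_system"
  )
}
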