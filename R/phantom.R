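#' Synthetic anatomy configuration
#'
#' Parameters of the deterministic phantom scene that stands in for
#' segmented patient models: a thick spherical skull shell, a brain split
#' into frontal and temporal lobes at a planar Sylvian-fissure stand-in, a
#' Circle-of-Willis stand-in vessel polyline running in the fissure, two
#' point landmarks (optic nerve, pterion) and four craniotomy template
#' contours (2 locations x 2 line widths). All dimensions are
#' implementer-chosen adult-scale defaults in mm; none are taken from a
#' specific patient.
#'
#' @param skull_outer_radius outer skull radius, mm.
#' @param skull_thickness shell thickness, mm.
#' @param brain_radius lobe hemisphere radius, mm; must fit inside the
#'   inner skull surface.
#' @param fissure_point,fissure_normal point and unit normal of the fissure
#'   plane (the normal points toward the frontal lobe).
#' @param fissure_gap separation between the two lobes across the plane, mm.
#' @param template_locations 2 x 3 matrix of unit directions from the skull
#'   centre to the two template centres.
#' @param template_line_widths two stroke widths, mm (the two line
#'   thicknesses of the tracing task).
#' @param template_radius geodesic radius of the circular templates, mm.
#' @param vessel_waypoints optional k x 3 matrix of waypoints for the
#'   vessel polyline, expressed in fissure-plane coordinates
#'   (u, v, offset-along-normal), mm; default traces ICA terminus, M1 and a
#'   post-bifurcation M2 stub. Rows 2 and 3 bound the M1 segment.
#' @param m1_length length of the M1 segment between its two designated
#'   waypoints, mm (default 15, a typical adult value).
#' @param subdivision_level icosphere subdivision of the outer skull
#'   surface (default 4: 5120 faces).
#' @param jitter_sd Gaussian vertex jitter, mm (default 0 = exact
#'   primitives).
#' @param seed RNG seed controlling jitter.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(skull_outer_radius = 85,
                           skull_thickness = 6,
                           brain_radius = 75,
                           fissure_point = c(0, 0, 0),
                           fissure_normal = c(0.25, 0.9, 0.35),
                           fissure_gap = 2,
                           template_locations = rbind(
                             c(0.80, 0.35, 0.49),
                             c(0.75, 0.55, -0.37)),
                           template_line_widths = c(1, 3),
                           template_radius = 25,
                           vessel_waypoints = NULL,
                           m1_length = 15,
                           subdivision_level = 4,
                           jitter_sd = 0,
                           seed = 1L) {
  cfg <- list(
    skull_outer_radius = skull_outer_radius,
    skull_thickness = skull_thickness,
    brain_radius = brain_radius,
    fissure_point = as.numeric(fissure_point),
    fissure_normal = normalize3(as.numeric(fissure_normal)),
    fissure_gap = fissure_gap,
    template_locations = as.matrix(template_locations),
    template_line_widths = as.numeric(template_line_widths),
    template_radius = template_radius,
    vessel_waypoints = vessel_waypoints,
    m1_length = m1_length,
    subdivision_level = as.integer(subdivision_level),
    jitter_sd = jitter_sd,
    seed = as.integer(seed)
  )
  if (cfg$skull_thickness <= 0 ||
      cfg$skull_thickness >= cfg$skull_outer_radius) {
    stop("skull thickness must be positive and below the outer radius",
         call. = FALSE)
  }
  if (cfg$brain_radius >= cfg$skull_outer_radius - cfg$skull_thickness) {
    stop("brain radius must be below the inner skull radius", call. = FALSE)
  }
  if (nrow(cfg$template_locations) != 2L ||
      length(cfg$template_line_widths) != 2L) {
    stop("exactly 2 template locations and 2 line widths are required",
         call. = FALSE)
  }
  class(cfg) <- "phantom_config"
  cfg
}

#' Unit icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; the standard closed
#' test surface (Euler characteristic 2, 20 * 4^level faces).
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 1:4 subdivision passes.
#' @param center sphere centre.
#' @return A [triangle_mesh()].
#' @export
icosphere <- function(radius = 1, subdivisions = 2, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      id <- edge_key[[k]]
      if (is.null(id)) {
        m <- v[i, ] + v[j, ]
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        id <- nrow(v)
        edge_key[[k]] <- id
      }
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  triangle_mesh(v * radius + matrix(center, nrow(v), 3, byrow = TRUE), f,
                name = sprintf("icosphere_r%g_s%d", radius, subdivisions),
                clean = FALSE)
}

# Closed hemisphere: spherical dome (pole along +axis) capped with a flat
# triangle fan at its equator plane. Watertight, Euler characteristic 2.
hemisphere_mesh <- function(radius, center, axis, n_rings = 12,
                            n_around = 24, name = "hemisphere") {
  axis <- normalize3(axis)
  bb <- plane_basis(axis)
  verts <- matrix(axis * radius, 1, 3)            # apex (pole)
  for (k in seq_len(n_rings)) {
    th <- k * (pi / 2) / n_rings                  # polar angle
    az <- 2 * pi * (seq_len(n_around) - 1L) / n_around
    ring <- radius * (sin(th) * (cos(az) %o% bb$u + sin(az) %o% bb$v) +
                        cos(th) * matrix(axis, n_around, 3, byrow = TRUE))
    verts <- rbind(verts, ring)
  }
  verts <- rbind(verts, c(0, 0, 0))               # cap centre (plane)
  cap_center <- nrow(verts)
  ring_id <- function(k, i) 1L + (k - 1L) * n_around + ((i - 1L) %% n_around) + 1L
  faces <- list()
  for (i in seq_len(n_around)) {                  # apex fan
    faces[[length(faces) + 1L]] <- c(1L, ring_id(1L, i), ring_id(1L, i + 1L))
  }
  for (k in seq_len(n_rings - 1L)) {              # quad strips
    for (i in seq_len(n_around)) {
      a <- ring_id(k, i); b <- ring_id(k, i + 1L)
      c <- ring_id(k + 1L, i); d <- ring_id(k + 1L, i + 1L)
      faces[[length(faces) + 1L]] <- c(a, c, d)
      faces[[length(faces) + 1L]] <- c(a, d, b)
    }
  }
  for (i in seq_len(n_around)) {                  # flat cap, outward = -axis
    faces[[length(faces) + 1L]] <- c(cap_center, ring_id(n_rings, i + 1L),
                                     ring_id(n_rings, i))
  }
  f <- do.call(rbind, faces)
  verts <- verts + matrix(center, nrow(verts), 3, byrow = TRUE)
  triangle_mesh(verts, f, name = name, clean = FALSE)
}

#' Generate the synthetic anatomy scene
#'
#' Deterministic for a fixed config (including seed): the skull is a
#' watertight thick spherical shell (outer icosphere plus inward-facing
#' inner icosphere), the brain is two closed hemisphere meshes separated by
#' the fissure plane, the vessel polyline runs inside the fissure gap with
#' its M1 segment scaled to exactly `m1_length`, and the four template
#' contours are circles snapped onto the outer skull surface.
#'
#' @param config a [phantom_config()].
#' @return A `phantom_scene` list with elements `skull`, `brain_frontal`,
#'   `brain_temporal`, `vessel`, `landmarks`, `templates`, `fissure`
#'   (point + normal) and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  r_out <- config$skull_outer_radius
  r_in <- r_out - config$skull_thickness
  outer <- icosphere(r_out, config$subdivision_level)
  inner <- icosphere(r_in, max(config$subdivision_level - 1L, 1L))
  inner$faces <- inner$faces[, c(1, 3, 2)]        # flip: normals point in
  skull <- triangle_mesh(
    rbind(outer$vertices, inner$vertices),
    rbind(outer$faces, inner$faces + nrow(outer$vertices)),
    name = "skull", clean = FALSE
  )

  n <- config$fissure_normal
  p0 <- config$fissure_point
  half_gap <- config$fissure_gap / 2
  frontal <- hemisphere_mesh(config$brain_radius, p0 + n * half_gap, n,
                             name = "brain_frontal")
  temporal <- hemisphere_mesh(config$brain_radius, p0 - n * half_gap, -n,
                              name = "brain_temporal")

  if (config$jitter_sd > 0) {
    set.seed(config$seed)
    jig <- function(m) {
      m$vertices <- m$vertices +
        matrix(stats::rnorm(length(m$vertices), 0, config$jitter_sd),
               ncol = 3)
      m
    }
    skull <- jig(skull); frontal <- jig(frontal); temporal <- jig(temporal)
  }

  bb <- plane_basis(n)
  wp <- config$vessel_waypoints
  if (is.null(wp)) {
    # (u, v, normal-offset) mm: ICA terminus -> M1 origin -> M1 end
    # (MCA bifurcation) -> M2 stub; M1 is rows 2 -> 3
    wp <- rbind(c(-10, -6, 0), c(0, 0, 0), c(15, 5, 0), c(24, 14, 0))
  }
  pts <- wp[, 1] %o% bb$u + wp[, 2] %o% bb$v + wp[, 3] %o% n +
    matrix(p0, nrow(wp), 3, byrow = TRUE)
  # scale segment between waypoints 2 and 3 to exactly m1_length
  d <- pts[3, ] - pts[2, ]
  scale <- config$m1_length / sqrt(sum(d^2))
  shift <- (pts[2, ] + d * scale) - pts[3, ]
  pts[3:nrow(pts), ] <- pts[3:nrow(pts), ] +
    matrix(shift, nrow(pts) - 2L, 3, byrow = TRUE)
  vessel <- surface_contour(pts, closed = FALSE, name = "vessel_cow")

  landmarks <- list(
    # schematic points: optic nerve near the vessel origin at the brain
    # base, pterion on the outer skull over the temple
    landmark("optic_nerve", p0 - 10 * bb$u - 5 * n),
    landmark("pterion", r_out * normalize3(c(0.9, 0.25, 0.35)))
  )

  templates <- list()
  for (li in 1:2) {
    dir <- normalize3(config$template_locations[li, ])
    circ <- circle_on_sphere(dir, r_out, config$template_radius,
                             n_points = 64)
    snapped <- nearest_point_on_mesh(skull, circ)$points
    for (wi in 1:2) {
      templates[[length(templates) + 1L]] <- surface_contour(
        snapped, closed = TRUE,
        name = sprintf("template_L%d_w%g", li,
                       config$template_line_widths[wi]),
        line_width_mm = config$template_line_widths[wi]
      )
    }
  }

  structure(
    list(skull = skull, brain_frontal = frontal, brain_temporal = temporal,
         vessel = vessel, landmarks = landmarks, templates = templates,
         fissure = list(point = p0, normal = n), config = config),
    class = "phantom_scene"
  )
}

# Small circle of geodesic radius `geodesic_mm` around unit direction `dir`
# on the sphere of radius r.
circle_on_sphere <- function(dir, r, geodesic_mm, n_points = 64) {
  dir <- normalize3(dir)
  alpha <- geodesic_mm / r                 # polar half-angle
  bb <- plane_basis(dir)
  az <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  r * (sin(alpha) * (cos(az) %o% bb$u + sin(az) %o% bb$v) +
         cos(alpha) * matrix(dir, n_points, 3, byrow = TRUE))
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat("phantom_scene:\n")
  cat(sprintf("  skull: %d faces; lobes: %d + %d faces\n",
              nrow(x$skull$faces), nrow(x$brain_frontal$faces),
              nrow(x$brain_temporal$faces)))
  cat(sprintf("  vessel: %d waypoints; %d landmarks; %d templates\n",
              nrow(x$vessel$points), length(x$landmarks),
              length(x$templates)))
  invisible(x)
}

#' Place the surgical target on the vessel
#'
#' Puts the target landmark (a small sphere standing in for an aneurysm)
#' on the vessel polyline at a normalized arc-length position, and appends
#' it to the scene's landmarks.
#'
#' @param scene a `phantom_scene`.
#' @param arclength_fraction position along the vessel in `[0, 1]`
#'   (0 = first waypoint, 1 = last).
#' @return The scene with a `"target"` landmark appended; the landmark
#'   itself is attached as attribute `"target"`.
#' @export
place_target <- function(scene, arclength_fraction) {
  if (!is.finite(arclength_fraction) || arclength_fraction < 0 ||
      arclength_fraction > 1) {
    stop("arclength_fraction must lie in [0, 1]", call. = FALSE)
  }
  pos <- point_at_arclength(scene$vessel, arclength_fraction)
  lm <- landmark("target", pos)
  scene$landmarks <- c(scene$landmarks, list(lm))
  attr(scene, "target") <- lm
  scene
}

# Point at normalized arc length s along an open polyline.
point_at_arclength <- function(contour, s) {
  p <- contour$points
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                         p[-nrow(p), , drop = FALSE])^2))
  total <- sum(seg)
  target <- s * total
  cum <- c(0, cumsum(seg))
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(seg))
  t <- if (seg[i] > 0) (target - cum[i]) / seg[i] else 0
  p[i, ] + t * (p[i + 1L, ] - p[i, ])
}

#' Write and read a phantom scene directory
#'
#' Meshes are stored as ASCII STL, the vessel and templates as CSV + JSON
#' sidecars, landmarks and the fissure plane as JSON.
#'
#' @param scene a `phantom_scene`.
#' @param dir directory (created if missing).
#' @return `write_scene`: invisibly, `dir`; `read_scene`: the scene.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_mesh(scene$skull, file.path(dir, "skull.stl"))
  save_mesh(scene$brain_frontal, file.path(dir, "brain_frontal.stl"))
  save_mesh(scene$brain_temporal, file.path(dir, "brain_temporal.stl"))
  save_contour(scene$vessel, file.path(dir, "vessel.csv"))
  for (i in seq_along(scene$templates)) {
    save_contour(scene$templates[[i]],
                 file.path(dir, sprintf("template_%d.csv", i)))
  }
  lms <- lapply(scene$landmarks, function(l) {
    list(name = l$name, position = l$position)
  })
  jsonlite::write_json(list(landmarks = lms, fissure = scene$fissure),
                       file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  need <- file.path(dir, c("skull.stl", "brain_frontal.stl",
                           "brain_temporal.stl", "vessel.csv",
                           "scene.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("scene input missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- jsonlite::fromJSON(file.path(dir, "scene.json"),
                             simplifyVector = FALSE)
  tfiles <- sort(list.files(dir, pattern = "^template_\\d+\\.csv$",
                            full.names = TRUE))
  structure(
    list(
      skull = suppressMessages(load_mesh(need[1])),
      brain_frontal = suppressMessages(load_mesh(need[2])),
      brain_temporal = suppressMessages(load_mesh(need[3])),
      vessel = load_contour(need[4]),
      landmarks = lapply(meta$landmarks, function(l) {
        landmark(l$name, unlist(l$position))
      }),
      templates = lapply(tfiles, load_contour),
      fissure = list(point = unlist(meta$fissure$point),
                     normal = unlist(meta$fissure$normal)),
      config = NULL
    ),
    class = "phantom_scene"
  )
}
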