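#' Build a mass-spring system from the two brain lobes
#'
#' One particle per mesh vertex, one Hookean spring per unique mesh edge
#' with rest length equal to the initial edge length. The two lobes share
#' no springs, so they deform independently (retracting one leaves the
#' other untouched). Particles farther from the fissure plane than
#' `fixation_depth_mm` are fixed, anchoring each lobe in place of its
#' skull attachment.
#'
#' Default constants (stiffness 1 N/mm, particle mass 1 g, dt 5 ms,
#' damping 0.02, fixation depth 15 mm) are stability-chosen module
#' defaults, with dt^2 * stiffness / mass well below 1.
#'
#' @param brain_frontal,brain_temporal the lobe meshes.
#' @param fissure list with `point` and `normal` defining the fissure
#'   plane (distance to this plane drives fixation).
#' @param stiffness spring stiffness, N/mm.
#' @param damping velocity damping per step, in `[0, 1)`.
#' @param dt time step, seconds.
#' @param mass particle mass, kg.
#' @param fixation_depth_mm particles with |signed distance| to the
#'   fissure plane above this are fixed.
#' @return A `mass_spring_system`: `positions`, `prev_positions`, `masses`,
#'   `fixed`, `lobe_label`, `springs` (i, j, rest_length, stiffness),
#'   `damping`, `dt`.
#' @export
build_system <- function(brain_frontal, brain_temporal, fissure,
                         stiffness = 1, damping = 0.02, dt = 0.005,
                         mass = 0.001, fixation_depth_mm = 15) {
  for (m in list(brain_frontal, brain_temporal)) {
    if (!inherits(m, "triangle_mesh") || nrow(m$vertices) == 0L) {
      stop("both lobe meshes must be non-empty triangle meshes",
           call. = FALSE)
    }
  }
  if (damping < 0 || damping >= 1) {
    stop("damping must lie in [0, 1)", call. = FALSE)
  }
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  pos <- rbind(brain_frontal$vertices, brain_temporal$vertices)
  nf <- nrow(brain_frontal$vertices)
  lobe <- c(rep("frontal", nf),
            rep("temporal", nrow(brain_temporal$vertices)))
  ef <- mesh_edge_table(brain_frontal)$edges
  et <- mesh_edge_table(brain_temporal)$edges + nf
  springs <- rbind(ef, et)
  rest <- sqrt(rowSums((pos[springs[, 1], , drop = FALSE] -
                          pos[springs[, 2], , drop = FALSE])^2))
  if (any(rest <= 0)) stop("zero-length mesh edge", call. = FALSE)
  nrm <- normalize3(fissure$normal)
  sd_plane <- drop(sweep(pos, 2, fissure$point) %*% nrm)
  structure(
    list(
      positions = pos, prev_positions = pos,
      masses = rep(mass, nrow(pos)),
      fixed = abs(sd_plane) > fixation_depth_mm,
      lobe_label = lobe,
      springs = cbind(i = springs[, 1], j = springs[, 2],
                      rest_length = rest, stiffness = stiffness),
      damping = damping, dt = dt
    ),
    class = "mass_spring_system"
  )
}

#' @export
print.mass_spring_system <- function(x, ...) {
  cat(sprintf(paste0("mass_spring_system: %d particles (%d fixed), ",
                     "%d springs, dt %.3g s, damping %.3g\n"),
              nrow(x$positions), sum(x$fixed), nrow(x$springs), x$dt,
              x$damping))
  invisible(x)
}

spring_forces <- function(system) {
  sp <- system$springs
  pos <- system$positions
  if (is.null(sp) || nrow(sp) == 0L) return(matrix(0, nrow(pos), 3))
  d <- pos[sp[, "j"], , drop = FALSE] - pos[sp[, "i"], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  len <- pmax(len, 1e-12)
  fmag <- sp[, "stiffness"] * (len - sp[, "rest_length"])
  fvec <- d * (fmag / len)
  idx <- c(sp[, "i"], sp[, "j"])
  contrib <- rbind(fvec, -fvec)
  out <- matrix(0, nrow(pos), 3)
  agg <- rowsum(contrib, idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Advance the mass-spring system by position-Verlet steps
#'
#' Update rule per free particle:
#' `x' = x + (1 - damping) * (x - x_prev) + a * dt^2`, with acceleration
#' `a = (spring forces + external force) / mass`. Fixed particles never
#' move. Spring forces are Hookean along the spring axis, proportional to
#' (length - rest_length).
#'
#' @param system a `mass_spring_system`.
#' @param external_force per-particle n x 3 force matrix (N), or `NULL`.
#' @param n_steps number of integration steps (>= 1).
#' @return The advanced system.
#' @export
step_system <- function(system, external_force = NULL, n_steps = 1L) {
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  n <- nrow(system$positions)
  if (is.null(external_force)) external_force <- matrix(0, n, 3)
  external_force <- as.matrix(external_force)
  stopifnot(nrow(external_force) == n)
  free <- !system$fixed
  for (k in seq_len(n_steps)) {
    acc <- (spring_forces(system) + external_force) / system$masses
    new <- system$positions +
      (1 - system$damping) * (system$positions - system$prev_positions) +
      acc * system$dt^2
    new[system$fixed, ] <- system$positions[system$fixed, ]
    if (!all(is.finite(new[free, ]))) {
      k_max <- if (nrow(system$springs)) {
        max(system$springs[, "stiffness"])
      } else 0
      stop(sprintf(paste0("numerical instability at step %d: reduce dt ",
                          "(%.3g s) or stiffness (%.3g N/mm)"),
                   k, system$dt, k_max),
           call. = FALSE)
    }
    system$prev_positions <- system$positions
    system$prev_positions[system$fixed, ] <-
      system$positions[system$fixed, ]
    system$positions <- new
  }
  system
}

#' Spatula for brain retraction
#'
#' @param position 3-D point on the fissure, mm.
#' @param direction retraction direction (normalized internally).
#' @param influence_radius_mm particles of the retracted lobe within this
#'   distance of the spatula are pulled.
#' @return A `spatula`.
#' @export
spatula <- function(position, direction, influence_radius_mm = 25) {
  if (influence_radius_mm <= 0) {
    stop("influence radius must be positive", call. = FALSE)
  }
  structure(
    list(position = as.numeric(position),
         direction = normalize3(as.numeric(direction)),
         influence_radius_mm = influence_radius_mm),
    class = "spatula"
  )
}

#' Retract one lobe with a spatula
#'
#' Displacement-controlled retraction: particles of the chosen lobe within
#' the spatula's influence radius are pulled along its direction, ramped
#' linearly from 0 to `amount_mm` over `n_steps`, with linear falloff
#' `1 - d/r` by distance `d` from the spatula. Pulled particles are moving
#' constraints during the ramp; the rest of the lobe follows through its
#' springs. The frontal and temporal lobes share no springs, so the other
#' lobe does not move.
#'
#' @param system a `mass_spring_system` from [build_system()].
#' @param spat a [spatula()].
#' @param lobe `"frontal"` or `"temporal"`.
#' @param amount_mm maximal pull distance, mm (>= 0; 0 is a no-op).
#' @param n_steps ramp length in integration steps.
#' @return The deformed system; attribute `"pulled"` holds the constrained
#'   particle indices.
#' @export
retract_lobe <- function(system, spat, lobe, amount_mm, n_steps = 200L) {
  lobe <- match.arg(lobe, c("frontal", "temporal"))
  stopifnot(inherits(spat, "spatula"))
  if (amount_mm < 0) stop("amount_mm must be >= 0", call. = FALSE)
  if (amount_mm == 0) return(system)
  d <- sqrt(rowSums(sweep(system$positions, 2, spat$position)^2))
  sel <- which(system$lobe_label == lobe &
                 d <= spat$influence_radius_mm & !system$fixed)
  if (length(sel) == 0L) return(system)
  w <- 1 - d[sel] / spat$influence_radius_mm
  base <- system$positions[sel, , drop = FALSE]
  was_fixed <- system$fixed
  system$fixed[sel] <- TRUE               # moving constraints
  for (k in seq_len(n_steps)) {
    pull <- (amount_mm * k / n_steps) * w
    tgt <- base + pull %o% spat$direction
    system$positions[sel, ] <- tgt
    system$prev_positions[sel, ] <- tgt
    system <- step_system(system, n_steps = 1L)
  }
  system$fixed <- was_fixed
  attr(system, "pulled") <- sel
  system
}

#' Rebuild lobe meshes from a (deformed) system
#'
#' @param system a `mass_spring_system`.
#' @param brain_frontal,brain_temporal the original lobe meshes (faces are
#'   reused; vertex order matches [build_system()]).
#' @return List with deformed `brain_frontal` and `brain_temporal`.
#' @export
system_to_meshes <- function(system, brain_frontal, brain_temporal) {
  nf <- nrow(brain_frontal$vertices)
  brain_frontal$vertices <- system$positions[seq_len(nf), , drop = FALSE]
  brain_temporal$vertices <-
    system$positions[nf + seq_len(nrow(brain_temporal$vertices)), ,
                     drop = FALSE]
  list(brain_frontal = brain_frontal, brain_temporal = brain_temporal)
}
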