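#' Microscope view
#'
#' @param eye camera position, mm.
#' @param look_at fixation point, mm (must differ from `eye`).
#' @param fov_deg field of view in degrees, in (0, 180).
#' @return A `microscope_view`.
#' @export
microscope_view <- function(eye, look_at, fov_deg = 40) {
  eye <- as.numeric(eye)
  look_at <- as.numeric(look_at)
  if (length(eye) != 3L || length(look_at) != 3L ||
      !all(is.finite(c(eye, look_at)))) {
    stop("eye and look_at must be finite 3-vectors", call. = FALSE)
  }
  if (sqrt(sum((eye - look_at)^2)) < 1e-9) {
    stop("degenerate view: eye coincides with look_at", call. = FALSE)
  }
  if (!is.finite(fov_deg) || fov_deg <= 0 || fov_deg >= 180) {
    stop("fov_deg must lie in (0, 180)", call. = FALSE)
  }
  structure(list(eye = eye, look_at = look_at, fov_deg = fov_deg),
            class = "microscope_view")
}

#' Evaluate target exposure through the craniotomy
#'
#' Quantitative proxy for the surgeon's microscopic self-assessment of
#' hole position, size and trajectory: rays are cast from
#' stratified-random points on a small sphere around the target (the
#' target sphere, default radius 2 mm) toward the eye, and the fraction
#' not blocked by the cut skull is reported, together with the smallest
#' clearance between the eye-target segment and the hole boundary.
#'
#' Sampling uses a Fibonacci lattice with seeded jitter, so results are
#' deterministic for a fixed seed, and enlarging the hole (removing more
#' faces) can only turn blocked rays into visible ones.
#'
#' @param cut_skull the excised skull (`triangle_mesh`), the only occluder.
#' @param target a `landmark` (e.g. from [place_target()]).
#' @param view a [microscope_view()].
#' @param n_rays number of rays (>= 1).
#' @param seed RNG seed for the jitter.
#' @param target_radius_mm radius of the target sampling sphere, mm.
#' @param region optional `craniotomy_region` used to report the hole
#'   area; `NA` if omitted.
#' @return An `exposure_report`: `visible_fraction` in `[0, 1]`,
#'   `min_clearance_mm` (distance from the eye-target segment to the
#'   nearest hole-boundary edge; `Inf` when the mesh has no boundary),
#'   `hole_area_mm2`, `n_rays`, `seed`.
#' @export
evaluate_exposure <- function(cut_skull, target, view, n_rays = 500,
                              seed = 1L, target_radius_mm = 2,
                              region = NULL) {
  stopifnot(inherits(view, "microscope_view"))
  if (!is.numeric(n_rays) || n_rays < 1) {
    stop("n_rays must be >= 1", call. = FALSE)
  }
  n_rays <- as.integer(n_rays)
  tp <- if (inherits(target, "landmark")) target$position
        else as.numeric(target)
  origins <- sphere_sample(n_rays, seed) * target_radius_mm +
    matrix(tp, n_rays, 3, byrow = TRUE)
  visible <- logical(n_rays)
  has_occluder <- !is.null(cut_skull) && nrow(cut_skull$faces) > 0L
  for (i in seq_len(n_rays)) {
    visible[i] <- !has_occluder ||
      !segment_hits_mesh(cut_skull, origins[i, ], view$eye)
  }
  clearance <- Inf
  if (has_occluder) {
    et <- mesh_edge_table(cut_skull)
    be <- boundary_edges(cut_skull, et)
    if (length(be)) {
      ed <- et$edges[be, , drop = FALSE]
      clearance <- min(vapply(seq_len(nrow(ed)), function(k) {
        segment_segment_distance(view$eye, tp,
                                 cut_skull$vertices[ed[k, 1], ],
                                 cut_skull$vertices[ed[k, 2], ])
      }, numeric(1)))
    }
  }
  structure(
    list(visible_fraction = mean(visible),
         min_clearance_mm = clearance,
         hole_area_mm2 = if (!is.null(region)) region$area_mm2 else NA_real_,
         n_rays = n_rays, seed = as.integer(seed)),
    class = "exposure_report"
  )
}

#' @export
print.exposure_report <- function(x, ...) {
  cat(sprintf(paste0("exposure_report: visible fraction %.3f ",
                     "(%d rays), clearance %.2f mm, hole %.1f mm^2\n"),
              x$visible_fraction, x$n_rays, x$min_clearance_mm,
              x$hole_area_mm2))
  invisible(x)
}

# Stratified-random directions on the unit sphere: Fibonacci lattice in
# (z, azimuth) with per-point jitter inside each z band and a global
# random azimuth offset.
sphere_sample <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  i <- seq_len(n)
  z <- 1 - 2 * (i - stats::runif(n)) / n
  phi <- 2 * pi * ((i * (sqrt(5) - 1) / 2) %% 1) + stats::runif(1) * 2 * pi
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(phi), rho * sin(phi), z)
}
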