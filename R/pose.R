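#' Head pose with clamped two-axis inclination
#'
#' The head can be inclined longitudinally (about the left-right x axis)
#' up to +/-90 degrees and transversally (about the anterior-posterior z
#' axis) up to +/-30 degrees; any request outside those limits saturates.
#' The limits are stated as magnitudes; the symmetric reading is adopted.
#'
#' @param longitudinal_deg requested longitudinal inclination, degrees.
#' @param transversal_deg requested transversal inclination, degrees.
#' @param pivot rotation centre, mm (the head-fixation point; defaults to
#'   the scene skull centroid when applied).
#' @return A `head_pose` with both angles clamped to `[-90, 90]` and
#'   `[-30, 30]`.
#' @export
clamp_pose <- function(longitudinal_deg, transversal_deg,
                       pivot = c(0, 0, 0)) {
  if (!is.finite(longitudinal_deg) || !is.finite(transversal_deg)) {
    stop("pose angles must be finite", call. = FALSE)
  }
  structure(
    list(
      longitudinal_deg = min(max(longitudinal_deg, -90), 90),
      transversal_deg = min(max(transversal_deg, -30), 30),
      pivot = as.numeric(pivot)
    ),
    class = "head_pose"
  )
}

#' @export
print.head_pose <- function(x, ...) {
  cat(sprintf("head_pose: longitudinal %+.1f deg, transversal %+.1f deg\n",
              x$longitudinal_deg, x$transversal_deg))
  invisible(x)
}

#' Rotation matrix of a head pose
#'
#' Axes are head-fixed (intrinsic): the longitudinal rotation about the
#' left-right axis (+x) is applied first, then the transversal rotation
#' about the head's anterior-posterior axis. In world coordinates the
#' composite is `R = R_long %*% R_trans`.
#'
#' @param pose a `head_pose`.
#' @return A 3 x 3 rotation matrix.
#' @export
pose_rotation <- function(pose) {
  rotation_about_axis(c(1, 0, 0), pose$longitudinal_deg) %*%
    rotation_about_axis(c(0, 0, 1), pose$transversal_deg)
}

#' Apply a head pose rigidly to a whole scene
#'
#' Rotates all meshes, contours and landmarks about the pivot (default:
#' centroid of the skull vertices). Rigid, so all pairwise distances, edge
#' lengths and face areas are preserved.
#'
#' @param scene a `phantom_scene`.
#' @param pose a `head_pose`.
#' @return The transformed scene.
#' @export
apply_pose <- function(scene, pose) {
  stopifnot(inherits(pose, "head_pose"))
  pivot <- if (all(pose$pivot == 0) && !is.null(scene$skull)) {
    colMeans(scene$skull$vertices)
  } else {
    pose$pivot
  }
  R <- pose_rotation(pose)
  tp <- function(pts) {
    sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot, `+`)
  }
  for (nm in c("skull", "brain_frontal", "brain_temporal")) {
    if (!is.null(scene[[nm]])) scene[[nm]]$vertices <- tp(scene[[nm]]$vertices)
  }
  if (!is.null(scene$vessel)) scene$vessel$points <- tp(scene$vessel$points)
  scene$templates <- lapply(scene$templates, function(ct) {
    ct$points <- tp(ct$points)
    ct
  })
  scene$landmarks <- lapply(scene$landmarks, function(l) {
    l$position <- drop(tp(matrix(l$position, 1, 3)))
    l
  })
  if (!is.null(scene$fissure)) {
    scene$fissure$point <- drop(tp(matrix(scene$fissure$point, 1, 3)))
    scene$fissure$normal <- drop(scene$fissure$normal %*% t(R))
  }
  attr(scene, "pose") <- pose
  scene
}

#' Rotate a pose incrementally, saturating at the limits
#'
#' Models stepwise hand rotation of the head: deltas are added to the
#' current angles and the result re-clamped, so repeated increments
#' saturate at the +/-90 / +/-30 degree limits.
#'
#' @param pose a `head_pose`.
#' @param d_long,d_trans angle increments, degrees.
#' @return The updated `head_pose`.
#' @export
incremental_rotate <- function(pose, d_long, d_trans) {
  if (!is.finite(d_long) || !is.finite(d_trans)) {
    stop("pose increments must be finite", call. = FALSE)
  }
  clamp_pose(pose$longitudinal_deg + d_long,
             pose$transversal_deg + d_trans, pivot = pose$pivot)
}
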