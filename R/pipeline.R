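#' Build a fully materialized run configuration
#'
#' Every stage parameter is given its default here, so the persisted
#' config of a run is complete and re-running it reproduces the run.
#'
#' @param scene_dir directory containing a scene written by
#'   [write_scene()].
#' @param out_dir run output directory.
#' @param seed integer seed used for every stochastic stage.
#' @param pose list: `longitudinal_deg`, `transversal_deg`.
#' @param craniotomy list: `template` (index of the template traced as the
#'   drawn contour when no `contour_file` is given), `contour_file`,
#'   `snap_tol_mm`, `leak_fraction`.
#' @param exposure list: `target_fraction` (arc-length position of the
#'   target on the vessel), `n_rays`, `eye_distance_mm`, `fov_deg`,
#'   `target_radius_mm`.
#' @param retraction list: `lobe`, `amount_mm`, `n_steps`,
#'   `influence_radius_mm`, plus the [build_system()] constants.
#' @param metrics list: `tolerance_mm`, `step_mm`.
#' @return A `run_config` list.
#' @export
run_config <- function(scene_dir, out_dir, seed = 1L,
                       pose = list(), craniotomy = list(),
                       exposure = list(), retraction = list(),
                       metrics = list()) {
  merge_defaults <- function(user, defaults) {
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    scene_dir = scene_dir,
    out_dir = out_dir,
    seed = as.integer(seed),
    pose = merge_defaults(pose, list(longitudinal_deg = 20,
                                     transversal_deg = 10)),
    craniotomy = merge_defaults(craniotomy, list(
      template = 1L, contour_file = NULL, snap_tol_mm = 0.5,
      leak_fraction = 0.5)),
    exposure = merge_defaults(exposure, list(
      target_fraction = 0.5, n_rays = 400L, eye_distance_mm = 400,
      fov_deg = 40, target_radius_mm = 2)),
    retraction = merge_defaults(retraction, list(
      lobe = "frontal", amount_mm = 8, n_steps = 150L,
      influence_radius_mm = 25, stiffness = 1, damping = 0.02,
      dt = 0.005, mass = 0.001, fixation_depth_mm = 15)),
    metrics = merge_defaults(metrics, list(tolerance_mm = 1,
                                           step_mm = 0.5))
  )
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Missing fields take their defaults via [run_config()], and the
#' materialized config is what gets persisted with the run.
#'
#' @param path YAML file with at least `scene_dir` and `out_dir`.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$scene_dir) || is.null(y$out_dir)) {
    stop("config must name scene_dir and out_dir", call. = FALSE)
  }
  run_config(y$scene_dir, y$out_dir,
             seed = if (is.null(y$seed)) 1L else y$seed,
             pose = if (is.null(y$pose)) list() else y$pose,
             craniotomy = if (is.null(y$craniotomy)) list()
                          else y$craniotomy,
             exposure = if (is.null(y$exposure)) list() else y$exposure,
             retraction = if (is.null(y$retraction)) list()
                          else y$retraction,
             metrics = if (is.null(y$metrics)) list() else y$metrics)
}

#' Run the full craniotomy-planning workflow
#'
#' Executes the four workflow stages on a stored scene in order --
#' head positioning, craniotomy (projection, region growing, excision),
#' microscopic exposure evaluation, fissure opening by retraction -- and
#' then the contour-precision metrics, writing each stage's artifacts and
#' a manifest with parameters, seed and content hashes. Re-running the
#' same config reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$scene_dir)) {
    stop("scene input missing: scene_dir '", config$scene_dir,
         "' does not exist", call. = FALSE)
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  scene <- read_scene(config$scene_dir)
  artifacts <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # 1. head positioning
  posed <- stage("pose", {
    pose <- clamp_pose(config$pose$longitudinal_deg,
                       config$pose$transversal_deg)
    s <- apply_pose(scene, pose)
    jsonlite::write_json(list(longitudinal_deg = pose$longitudinal_deg,
                              transversal_deg = pose$transversal_deg),
                         file.path(out, "pose.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(out, "pose.json"))
    s
  })

  # 2. craniotomy
  cr <- stage("craniotomy", {
    drawn <- if (!is.null(config$craniotomy$contour_file)) {
      load_contour(config$craniotomy$contour_file)
    } else {
      posed$templates[[config$craniotomy$template]]
    }
    proj <- project_contour(posed$skull, drawn,
                            snap_tol_mm = config$craniotomy$snap_tol_mm)
    # contour centroid lies under the dome; its projection onto the outer
    # table is a point in the middle of the enclosed region
    seed_pt <- nearest_point_on_mesh(
      posed$skull, colMeans(proj$contour$points),
      face_subset = outer_surface_faces(posed$skull))$points[1, ]
    region <- region_grow(posed$skull, proj, seed_pt,
                          leak_fraction = config$craniotomy$leak_fraction)
    cut <- excise(posed$skull, region)
    save_mesh(cut, file.path(out, "skull_cut.stl"))
    jsonlite::write_json(list(face_ids = region$face_ids,
                              area_mm2 = region$area_mm2),
                         file.path(out, "region.json"), digits = NA,
                         auto_unbox = TRUE)
    artifacts <- c(artifacts, file.path(out, c("skull_cut.stl",
                                                "region.json")))
    list(drawn = drawn, region = region, cut = cut)
  })

  # 3. microscopic exposure
  expo <- stage("exposure", {
    with_target <- place_target(posed, config$exposure$target_fraction)
    target <- attr(with_target, "target")
    hole_dir <- normalize3(colMeans(cr$drawn$points) -
                             colMeans(posed$skull$vertices))
    view <- microscope_view(
      eye = target$position + hole_dir * config$exposure$eye_distance_mm,
      look_at = target$position, fov_deg = config$exposure$fov_deg)
    # full-thickness opening: the occluder is the cut outer table (the
    # inner table under the patch leaves with the bone flap)
    occluder <- submesh(cr$cut, outer_surface_faces(cr$cut))
    rep <- evaluate_exposure(occluder, target, view,
                             n_rays = config$exposure$n_rays,
                             seed = config$seed,
                             target_radius_mm =
                               config$exposure$target_radius_mm,
                             region = cr$region)
    jsonlite::write_json(unclass(rep)[c("visible_fraction",
                                        "min_clearance_mm",
                                        "hole_area_mm2", "n_rays")],
                         file.path(out, "exposure.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(out, "exposure.json"))
    list(report = rep, target = target)
  })

  # 4. fissure opening (retraction)
  retr <- stage("retraction", {
    p <- config$retraction
    sys <- build_system(posed$brain_frontal, posed$brain_temporal,
                        posed$fissure, stiffness = p$stiffness,
                        damping = p$damping, dt = p$dt, mass = p$mass,
                        fixation_depth_mm = p$fixation_depth_mm)
    spat <- spatula(posed$fissure$point,
                    if (p$lobe == "frontal") posed$fissure$normal
                    else -posed$fissure$normal,
                    influence_radius_mm = p$influence_radius_mm)
    sys2 <- retract_lobe(sys, spat, p$lobe, p$amount_mm,
                         n_steps = p$n_steps)
    disp <- sqrt(rowSums((sys2$positions - sys$positions)^2))
    meshes <- system_to_meshes(sys2, posed$brain_frontal,
                               posed$brain_temporal)
    save_mesh(meshes$brain_frontal,
              file.path(out, "brain_frontal_retracted.stl"))
    save_mesh(meshes$brain_temporal,
              file.path(out, "brain_temporal_retracted.stl"))
    utils::write.csv(
      data.frame(particle = seq_along(disp), lobe = sys$lobe_label,
                 displacement_mm = disp),
      file.path(out, "displacement.csv"), row.names = FALSE)
    artifacts <- c(artifacts,
                    file.path(out, c("brain_frontal_retracted.stl",
                                     "brain_temporal_retracted.stl",
                                     "displacement.csv")))
    list(max_displacement_mm = max(disp))
  })

  # 5. contour-precision metrics
  met <- stage("metrics", {
    tab <- evaluate_against_templates(
      cr$drawn, posed, tolerance_mm = config$metrics$tolerance_mm,
      step_mm = config$metrics$step_mm)
    utils::write.csv(tab, file.path(out, "metrics.csv"),
                     row.names = FALSE)
    artifacts <- c(artifacts, file.path(out, "metrics.csv"))
    tab
  })

  manifest <- list(
    stages = c("pose", "craniotomy", "exposure", "retraction", "metrics"),
    seed = config$seed,
    parameters = config[c("pose", "craniotomy", "exposure", "retraction",
                          "metrics")],
    inputs = list(scene_dir = config$scene_dir),
    hashes = as.list(tools::md5sum(sort(unique(artifacts)))),
    summary = list(
      hole_area_mm2 = cr$region$area_mm2,
      visible_fraction = expo$report$visible_fraction,
      min_clearance_mm = expo$report$min_clearance_mm,
      max_retraction_mm = retr$max_displacement_mm,
      # precision against the template the drawing traces (best match)
      surface_dsc = max(met$surface_dsc),
      hausdorff_mm = met$hausdorff_mm[which.max(met$surface_dsc)]
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
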