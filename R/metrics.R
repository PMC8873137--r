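#' Resample a contour at uniform arc length
#'
#' Places points at uniform spacing no larger than `step_mm` along the
#' polyline (closed contours wrap through the closing segment). Original
#' vertices are not necessarily retained. An open contour of length L
#' yields `ceiling(L/step) + 1` points including both endpoints; a closed
#' one yields `ceiling(L/step)` points.
#'
#' @param contour a `surface_contour`.
#' @param step_mm maximal spacing between consecutive samples, mm.
#' @return The resampled `surface_contour`.
#' @export
resample_contour <- function(contour, step_mm) {
  if (!is.finite(step_mm) || step_mm <= 0) {
    stop("step_mm must be positive", call. = FALSE)
  }
  total <- contour_length(contour)
  if (total <= 0) stop("zero-length contour", call. = FALSE)
  n <- ceiling(total / step_mm)
  s <- if (contour$closed) {
    total * (seq_len(n) - 1L) / n
  } else {
    total * (0:n) / n
  }
  p <- contour$points
  if (contour$closed) p <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                         p[-nrow(p), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(seg))
  t <- ifelse(seg[i] > 0, (s - cum[i]) / seg[i], 0)
  pts <- p[i, , drop = FALSE] +
    (p[i + 1L, , drop = FALSE] - p[i, , drop = FALSE]) * t
  out <- contour
  out$points <- pts
  out
}

# Exact distances from each point in an n x 3 matrix to the other contour.
points_to_contour_distances <- function(pts, contour) {
  seg <- contour_segments(contour)
  vapply(seq_len(nrow(pts)), function(k) {
    min(point_segment_distances(pts[k, ], seg$a, seg$b))
  }, numeric(1))
}

#' Surface Dice similarity coefficient between two contours
#'
#' Tolerance-based overlap of two curves: both contours are resampled at
#' `step_mm`; a drawn sample within `tolerance_mm` of the template
#' polyline counts as a true positive (TP), the remaining drawn samples
#' as false positives (FP), and template samples beyond `tolerance_mm` of
#' the drawn polyline as false negatives (FN). The coefficient is
#' `2*TP / (2*TP + FP + FN)`. Distances are exact point-to-segment
#' minimizations against the other polyline, so the value does not depend
#' on the other contour's sampling density.
#'
#' @param drawn,template `surface_contour`s.
#' @param tolerance_mm matching tolerance tau, mm (> 0; default 1).
#' @param step_mm resampling step, mm (default 0.5).
#' @return A `metrics_report` with `surface_dsc`, the match counts, sample
#'   sizes and parameters (`hausdorff_mm` is `NA` here).
#' @export
surface_dsc <- function(drawn, template, tolerance_mm = 1, step_mm = 0.5) {
  if (!is.finite(tolerance_mm) || tolerance_mm <= 0) {
    stop("tolerance_mm must be positive", call. = FALSE)
  }
  a <- resample_contour(drawn, step_mm)
  b <- resample_contour(template, step_mm)
  d_ab <- points_to_contour_distances(a$points, template)
  d_ba <- points_to_contour_distances(b$points, drawn)
  tp <- sum(d_ab <= tolerance_mm)
  fp <- nrow(a$points) - tp
  fn <- sum(d_ba > tolerance_mm)
  metrics_report(
    surface_dsc = 2 * tp / (2 * tp + fp + fn),
    hausdorff_mm = NA_real_,
    counts = c(TP = tp, FP = fp, FN = fn),
    n_samples_drawn = nrow(a$points),
    n_samples_template = nrow(b$points),
    tolerance_mm = tolerance_mm, step_mm = step_mm
  )
}

#' Symmetric Hausdorff distance between two contours
#'
#' `H(A, B) = max(h(A, B), h(B, A))` with
#' `h(A, B) = max over resampled points a of the exact minimum distance
#' from a to polyline B`. Discretization error is bounded by the
#' resampling step.
#'
#' @inheritParams surface_dsc
#' @return Hausdorff distance in mm.
#' @export
hausdorff_distance <- function(drawn, template, step_mm = 0.5) {
  a <- resample_contour(drawn, step_mm)
  b <- resample_contour(template, step_mm)
  max(max(points_to_contour_distances(a$points, template)),
      max(points_to_contour_distances(b$points, drawn)))
}

metrics_report <- function(surface_dsc, hausdorff_mm, counts,
                           n_samples_drawn, n_samples_template,
                           tolerance_mm, step_mm) {
  structure(
    list(surface_dsc = surface_dsc, hausdorff_mm = hausdorff_mm,
         counts = counts, n_samples_drawn = n_samples_drawn,
         n_samples_template = n_samples_template,
         tolerance_mm = tolerance_mm, step_mm = step_mm,
         discretization_error_mm = step_mm),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics_report: surface DSC %.3f (tau %.2g mm), ",
                     "Hausdorff %.2f mm (step %.2g mm)\n"),
              x$surface_dsc, x$tolerance_mm, x$hausdorff_mm, x$step_mm))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(surface_dsc = x$surface_dsc, hausdorff_mm = x$hausdorff_mm,
             TP = unname(x$counts["TP"]), FP = unname(x$counts["FP"]),
             FN = unname(x$counts["FN"]),
             n_samples_drawn = x$n_samples_drawn,
             n_samples_template = x$n_samples_template,
             tolerance_mm = x$tolerance_mm, step_mm = x$step_mm)
}

#' Evaluate a traced drawing against a template
#'
#' Bundles the surface Dice similarity coefficient and the Hausdorff
#' distance, the two contour-precision measures of the tracing task, into
#' one report.
#'
#' @inheritParams surface_dsc
#' @return A `metrics_report` with both metrics and the parameters used.
#' @export
evaluate_drawing <- function(drawn, template, tolerance_mm = 1,
                             step_mm = 0.5) {
  rep <- surface_dsc(drawn, template, tolerance_mm, step_mm)
  rep$hausdorff_mm <- hausdorff_distance(drawn, template, step_mm)
  rep
}

#' Evaluate a drawing against all four phantom templates
#'
#' Batch form of [evaluate_drawing()] over the scene's template contours,
#' one row per template (the per-location layout of the tracing task).
#'
#' @param drawn a `surface_contour`.
#' @param scene a `phantom_scene`.
#' @inheritParams surface_dsc
#' @return A data frame with template name, line width and both metrics.
#' @export
evaluate_against_templates <- function(drawn, scene, tolerance_mm = 1,
                                       step_mm = 0.5) {
  do.call(rbind, lapply(scene$templates, function(tpl) {
    r <- evaluate_drawing(drawn, tpl, tolerance_mm, step_mm)
    cbind(data.frame(template = tpl$name,
                     line_width_mm = tpl$line_width_mm),
          as.data.frame(r))
  }))
}
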