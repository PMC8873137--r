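seg_contour <- function(p1, p2) surface_contour(rbind(p1, p2))

circle_contour <- function(r, n = 90, center = c(0, 0, 0)) {
  az <- 2 * pi * (seq_len(n) - 1) / n
  surface_contour(cbind(center[1] + r * cos(az),
                        center[2] + r * sin(az),
                        center[3] + 0 * az), closed = TRUE)
}

test_that("resampling respects spacing, counts and total length", {
  seg <- seg_contour(c(0, 0, 0), c(10, 0, 0))
  rs <- resample_contour(seg, 1)
  expect_equal(nrow(rs$points), 11L)
  expect_equal(rs$points[, 1], 0:10)

  sq <- surface_contour(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0),
                              c(0, 10, 0)), closed = TRUE)
  rs2 <- resample_contour(sq, 1)
  expect_equal(nrow(rs2$points), 40L)
  # spacing along the polyline never exceeds the step
  d <- sqrt(rowSums(diff(rbind(rs2$points, rs2$points[1, ]))^2))
  expect_lte(max(d), 1 + 1e-9)

  # resampled length equals the original within one step on smooth curves
  smooth <- surface_contour(cbind(seq(0, 60, by = 2),
                                  10 * sin(seq(0, 60, by = 2) / 10),
                                  0))
  for (step in c(2, 0.7)) {
    rs3 <- resample_contour(smooth, step)
    expect_lt(abs(contour_length(rs3) - contour_length(smooth)), step)
  }
  rs4 <- resample_contour(circle_contour(20), 0.5)
  expect_lt(abs(contour_length(rs4) - contour_length(circle_contour(20))),
            0.5)
  expect_error(resample_contour(seg, 0), "positive")
})

test_that("surface DSC is 1 on identical and 0 on distant contours", {
  c1 <- circle_contour(20)
  expect_equal(surface_dsc(c1, c1)$surface_dsc, 1)
  far <- circle_contour(20, center = c(500, 0, 0))
  expect_equal(surface_dsc(c1, far)$surface_dsc, 0)
  expect_error(surface_dsc(c1, far, tolerance_mm = 0), "positive")
})

test_that("concentric-circle DSC matches the exhaustive counting oracle", {
  a <- circle_contour(20)
  b <- circle_contour(22)
  for (tol in c(1, 2.5)) {
    got <- surface_dsc(a, b, tolerance_mm = tol, step_mm = 0.5)
    want <- oracle_surface_dsc(a, b, tol, 0.5)
    expect_equal(got$surface_dsc, want, tolerance = 1e-12,
                 info = paste("tol", tol))
  }
  # radial gap 2: everything matches at tol 2.5, nothing at tol 1
  expect_equal(surface_dsc(a, b, tolerance_mm = 2.5)$surface_dsc, 1)
  expect_equal(surface_dsc(a, b, tolerance_mm = 1)$surface_dsc, 0,
               tolerance = 0.05)   # chordal shortcuts graze the tolerance
})

test_that("Hausdorff distance handles canonical configurations", {
  c1 <- circle_contour(20)
  expect_equal(hausdorff_distance(c1, c1), 0)
  s1 <- seg_contour(c(0, 0, 0), c(100, 0, 0))
  s2 <- seg_contour(c(0, 5, 0), c(100, 5, 0))
  expect_equal(hausdorff_distance(s1, s2), 5, tolerance = 1e-9)
  # symmetric by construction
  expect_equal(hausdorff_distance(s2, s1), hausdorff_distance(s1, s2))
})

test_that("metrics match brute-force oracles on random polylines", {
  set.seed(77)
  for (k in 1:6) {
    A <- random_polyline(8, scale = 25)
    B <- random_polyline(8, scale = 25)
    step <- 1
    expect_equal(hausdorff_distance(A, B, step_mm = step),
                 oracle_hausdorff(A, B, step), tolerance = 1e-9)
    tol <- runif(1, 2, 10)
    expect_equal(surface_dsc(A, B, tolerance_mm = tol,
                             step_mm = step)$surface_dsc,
                 oracle_surface_dsc(A, B, tol, step), tolerance = 1e-12)
  }
})

test_that("a drawing offset by half the tolerance keeps DSC 1", {
  tpl <- seg_contour(c(0, 0, 0), c(100, 0, 0))
  drawn <- seg_contour(c(0, 0.5, 0), c(100, 0.5, 0))
  rep <- evaluate_drawing(drawn, tpl, tolerance_mm = 1, step_mm = 0.5)
  expect_equal(rep$surface_dsc, 1)
  expect_equal(rep$hausdorff_mm, 0.5, tolerance = 1e-9)
})

test_that("evaluate_drawing bundles both metrics and is symmetric in H", {
  set.seed(13)
  A <- random_polyline(10)
  B <- random_polyline(10)
  r1 <- evaluate_drawing(A, B)
  r2 <- evaluate_drawing(B, A)
  expect_equal(r1$hausdorff_mm, r2$hausdorff_mm, tolerance = 1e-12)
  same <- evaluate_drawing(A, A)
  expect_equal(same$surface_dsc, 1)
  expect_equal(same$hausdorff_mm, 0)
  df <- as.data.frame(r1)
  expect_true(all(c("surface_dsc", "hausdorff_mm", "TP", "FP", "FN")
                  %in% names(df)))
})

test_that("metric axioms hold on generated contour families", {
  set.seed(55)
  for (k in 1:5) {
    A <- random_polyline(7)
    B <- random_polyline(7)
    C <- random_polyline(7)
    step <- 1
    hab <- hausdorff_distance(A, B, step)
    hbc <- hausdorff_distance(B, C, step)
    hac <- hausdorff_distance(A, C, step)
    # symmetry and triangle-like bound up to discretization
    expect_equal(hab, hausdorff_distance(B, A, step), tolerance = 1e-12)
    expect_lte(hac, hab + hbc + step)
    # DSC bounded and non-decreasing in the tolerance
    prev <- -1
    for (tol in c(0.5, 1, 2, 5, 20)) {
      v <- surface_dsc(A, B, tolerance_mm = tol, step_mm = step)$surface_dsc
      expect_gte(v, 0); expect_lte(v, 1)
      expect_gte(v, prev)
      prev <- v
    }
  }
})

test_that("metrics are invariant under a joint rigid transform", {
  set.seed(66)
  A <- random_polyline(9)
  B <- random_polyline(9)
  R <- random_rotation()
  shift <- c(5, -12, 30)
  move <- function(ct) {
    ct$points <- sweep(ct$points %*% t(R), 2, shift, `+`)
    ct
  }
  expect_equal(hausdorff_distance(move(A), move(B)),
               hausdorff_distance(A, B), tolerance = 1e-9)
  expect_equal(surface_dsc(move(A), move(B))$surface_dsc,
               surface_dsc(A, B)$surface_dsc, tolerance = 1e-12)
})

test_that("halving the step changes both metrics by less than the step", {
  set.seed(88)
  A <- random_polyline(10)
  B <- random_polyline(10)
  h1 <- hausdorff_distance(A, B, step_mm = 1)
  h2 <- hausdorff_distance(A, B, step_mm = 0.5)
  expect_lt(abs(h1 - h2), 1)
  d1 <- surface_dsc(A, B, step_mm = 1)$surface_dsc
  d2 <- surface_dsc(A, B, step_mm = 0.5)$surface_dsc
  expect_lt(abs(d1 - d2), 0.2)
})
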