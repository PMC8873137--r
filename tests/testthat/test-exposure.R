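test_that("extreme occlusion cases give 0 and 1", {
  tgt <- landmark("target", c(0, 0, 0))
  view <- microscope_view(c(0, 0, 400), c(0, 0, 0))
  # intact sphere around the target blocks everything
  shell <- icosphere(40, 2)
  r0 <- evaluate_exposure(shell, tgt, view, n_rays = 100, seed = 2)
  expect_equal(r0$visible_fraction, 0)
  expect_equal(r0$min_clearance_mm, Inf)    # closed mesh: no hole boundary
  # no occluder at all
  r1 <- evaluate_exposure(NULL, tgt, view, n_rays = 100, seed = 2)
  expect_equal(r1$visible_fraction, 1)
  # occluder far off to the side
  off <- icosphere(10, 1, center = c(200, 0, 0))
  r2 <- evaluate_exposure(off, tgt, view, n_rays = 100, seed = 2)
  expect_equal(r2$visible_fraction, 1)
})

test_that("degenerate views and ray counts are rejected", {
  expect_error(microscope_view(c(0, 0, 0), c(0, 0, 0)), "degenerate")
  expect_error(microscope_view(c(0, 0, 1), c(0, 0, 0), fov_deg = 200),
               "fov")
  tgt <- landmark("target", c(0, 0, 0))
  view <- microscope_view(c(0, 0, 400), c(0, 0, 0))
  expect_error(evaluate_exposure(NULL, tgt, view, n_rays = 0), "n_rays")
})

test_that("a point target sees exactly through the hole axis", {
  tgt <- landmark("target", c(0, 0, 0))
  occ <- plane_with_hole(z0 = 40, hole_half = 6)
  # eye behind the hole: the single ray passes through it
  v_in <- microscope_view(c(0, 0, 400), c(0, 0, 0))
  r_in <- evaluate_exposure(occ, tgt, v_in, n_rays = 50, seed = 1,
                            target_radius_mm = 0)
  expect_equal(r_in$visible_fraction, 1)
  # eye far off-axis: the ray hits the plane outside the hole
  v_out <- microscope_view(c(300, 0, 400), c(0, 0, 0))
  r_out <- evaluate_exposure(occ, tgt, v_out, n_rays = 50, seed = 1,
                             target_radius_mm = 0)
  expect_equal(r_out$visible_fraction, 0)
})

test_that("target-sphere visibility matches an analytic ray oracle", {
  # exact square hole in a plane, so no faceting error; the oracle
  # recomputes visibility per ray from closed-form ray-plane geometry
  h <- 6
  z0 <- 40
  occ <- plane_with_hole(z0 = z0, hole_half = h)
  eye <- c(0, 0, 400)
  tgt <- landmark("target", c(0, 0, 0))
  view <- microscope_view(eye, tgt$position)
  rad <- 10
  r <- evaluate_exposure(occ, tgt, view, n_rays = 2000, seed = 5,
                         target_radius_mm = rad)
  oracle_fraction <- function(n, seed) {
    set.seed(seed)
    # plain uniform sphere sampling, independent of the implementation
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    rho <- sqrt(1 - z^2)
    p <- rad * cbind(rho * cos(phi), rho * sin(phi), z)
    t <- (z0 - p[, 3]) / (eye[3] - p[, 3])
    x <- p[, 1] + t * (eye[1] - p[, 1])
    y <- p[, 2] + t * (eye[2] - p[, 2])
    mean(abs(x) < h & abs(y) < h)
  }
  expected <- oracle_fraction(20000, 99)
  se <- sqrt(expected * (1 - expected) * (1 / 2000 + 1 / 20000))
  expect_lt(abs(r$visible_fraction - expected), 3 * se + 0.01)
})

test_that("enlarging the hole never decreases the visible fraction", {
  set.seed(31)
  sph <- icosphere(40, 3)
  tgt <- landmark("target", c(0, 0, 0))
  view <- microscope_view(c(0, 0, 400), c(0, 0, 0))
  cen <- face_centroids(sph)
  ang <- acos(pmin(cen[, 3] / sqrt(rowSums(cen^2)), 1))
  hole1 <- which(ang < 0.12)
  hole2 <- which(ang < 0.25)              # superset of hole1
  expect_true(all(hole1 %in% hole2))
  cut1 <- submesh(sph, setdiff(seq_len(nrow(sph$faces)), hole1))
  cut2 <- submesh(sph, setdiff(seq_len(nrow(sph$faces)), hole2))
  for (s in c(1, 7, 42)) {
    v1 <- evaluate_exposure(cut1, tgt, view, n_rays = 400, seed = s,
                            target_radius_mm = 6)$visible_fraction
    v2 <- evaluate_exposure(cut2, tgt, view, n_rays = 400, seed = s,
                            target_radius_mm = 6)$visible_fraction
    expect_gte(v2, v1)
  }
  # and determinism for a fixed seed
  va <- evaluate_exposure(cut1, tgt, view, n_rays = 400, seed = 7,
                          target_radius_mm = 6)$visible_fraction
  vb <- evaluate_exposure(cut1, tgt, view, n_rays = 400, seed = 7,
                          target_radius_mm = 6)$visible_fraction
  expect_identical(va, vb)
})

test_that("visibility is invariant under a joint rigid transform", {
  set.seed(17)
  sph <- icosphere(40, 2)
  cen <- face_centroids(sph)
  hole <- which(acos(pmin(cen[, 3] / sqrt(rowSums(cen^2)), 1)) < 0.3)
  cut <- submesh(sph, setdiff(seq_len(nrow(sph$faces)), hole))
  tgt0 <- c(0, 0, 0)
  eye0 <- c(0, 0, 400)
  base <- evaluate_exposure(cut, landmark("target", tgt0),
                            microscope_view(eye0, tgt0), n_rays = 300,
                            seed = 9, target_radius_mm = 6)
  R <- random_rotation()
  shift <- c(12, -30, 5)
  cut_r <- cut
  cut_r$vertices <- sweep(cut$vertices %*% t(R), 2, shift, `+`)
  # same seed: sample-sphere offsets rotate with nothing, but visibility
  # counts are invariant because the whole configuration moved rigidly
  # only when the samples move too; so compare against a transformed
  # sampling by rotating the target frame jointly via the eye position
  moved <- evaluate_exposure(cut_r, landmark("target",
                                             drop(R %*% tgt0) + shift),
                             microscope_view(drop(R %*% eye0) + shift,
                                             drop(R %*% tgt0) + shift),
                             n_rays = 300, seed = 9,
                             target_radius_mm = 6)
  # the sampling pattern is seed-fixed in world axes, so allow the small
  # binomial wobble from re-orienting the pattern on the sphere
  expect_lt(abs(base$visible_fraction - moved$visible_fraction), 0.05)
})

test_that("clearance measures the distance from the sight line to the rim", {
  occ <- plane_with_hole(z0 = 40, hole_half = 6)
  tgt <- landmark("target", c(0, 0, 0))
  view <- microscope_view(c(0, 0, 400), c(0, 0, 0))
  r <- evaluate_exposure(occ, tgt, view, n_rays = 10, seed = 1)
  # sight line is the z axis; nearest rim point is the inner-square edge
  # midpoint at distance 6 in x or y
  expect_equal(r$min_clearance_mm, 6, tolerance = 1e-9)
})
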