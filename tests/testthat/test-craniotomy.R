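test_that("projection is a fixed point for points already on the surface", {
  sph <- icosphere(40, 2)
  cen <- face_centroids(sph)[c(3, 50, 200), ]
  raw <- surface_contour(cen, closed = TRUE)
  proj <- project_contour(sph, raw, snap_tol_mm = 0.5)
  # the three input points appear unchanged in the dense path
  for (i in 1:3) {
    d <- min(sqrt(rowSums(sweep(proj$contour$points, 2, cen[i, ])^2)))
    expect_lt(d, 1e-9)
  }
})

test_that("an off-surface point projects radially onto the sphere", {
  sph <- icosphere(85, 4)
  dir <- c(0.36, 0.48, 0.8)
  nm <- nearest_point_on_mesh(sph, 90 * dir)
  # nearest point sits at the faceted-sphere radius along the same ray
  expect_lt(sqrt(sum((nm$points[1, ] - 85 * dir)^2)), 0.2)
  r <- sqrt(sum(nm$points[1, ]^2))
  expect_gt(r, 85 - 0.12)                 # within faceting sag of 85
  expect_lte(r, 85 + 1e-9)
  expect_equal(nm$distances[1], 90 - r, tolerance = 1e-3)
  # far points are rejected during contour projection
  far <- surface_contour(rbind(c(0, 0, 200), c(10, 0, 200),
                               c(0, 10, 200)), closed = TRUE)
  expect_error(project_contour(sph, far, snap_tol_mm = 0.5),
               "from the skull surface")
})

test_that("nearest-point queries match a dense sampling oracle", {
  set.seed(11)
  v <- rbind(c(0, 0, 0), c(12, 0, 0), c(4, 10, 0), c(5, 4, 9))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4))
  tet <- triangle_mesh(v, f)
  # barycentric grid sampling of every triangle, spacing ~edge/150
  k <- 150
  grid <- expand.grid(a = 0:k, b = 0:k)
  grid <- grid[grid$a + grid$b <= k, ]
  w <- cbind(grid$a, grid$b, k - grid$a - grid$b) / k
  samples <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
    w %*% v[f[i, ], ]
  }))
  queries <- matrix(runif(3 * 50, -5, 15), ncol = 3)
  nm <- nearest_point_on_mesh(tet, queries)
  for (i in seq_len(nrow(queries))) {
    oracle <- min(sqrt(rowSums(sweep(samples, 2, queries[i, ])^2)))
    expect_lte(nm$distances[i], oracle + 1e-9)
    expect_lt(oracle - nm$distances[i], 0.12)   # grid resolution bound
  }
})

test_that("region growing matches an independent flood fill", {
  set.seed(21)
  sph <- icosphere(40, 3)
  outer <- outer_surface_faces(sph)
  for (k in 1:3) {
    axis <- random_unit_vector()
    raw <- latitude_contour(axis, 40, runif(1, 0.6, 1.1))
    proj <- project_contour(sph, raw, snap_tol_mm = 0.5)
    expect_true(proj$closed)
    seed_pt <- nearest_point_on_mesh(sph, 40 * axis)$points[1, ]
    reg <- region_grow(sph, proj, seed_pt)
    oracle <- oracle_flood_fill(sph, reg$seed_face, proj$barrier_edges,
                                outer)
    expect_setequal(reg$face_ids, oracle)
    # area matches an independent accumulation over selected triangles
    a <- sph$vertices[sph$faces[reg$face_ids, 1], , drop = FALSE]
    b <- sph$vertices[sph$faces[reg$face_ids, 2], , drop = FALSE]
    cc <- sph$vertices[sph$faces[reg$face_ids, 3], , drop = FALSE]
    cr <- cbind((b - a)[, 2] * (cc - a)[, 3] - (b - a)[, 3] * (cc - a)[, 2],
                (b - a)[, 3] * (cc - a)[, 1] - (b - a)[, 1] * (cc - a)[, 3],
                (b - a)[, 1] * (cc - a)[, 2] - (b - a)[, 2] * (cc - a)[, 1])
    expect_equal(reg$area_mm2, sum(0.5 * sqrt(rowSums(cr^2))),
                 tolerance = 1e-9)
  }
})

test_that("region growing is seed-independent and partitions the surface", {
  sph <- icosphere(40, 3)
  outer <- outer_surface_faces(sph)
  raw <- latitude_contour(c(0, 0, 1), 40, 0.8)
  proj <- project_contour(sph, raw, snap_tol_mm = 0.5)
  reg1 <- region_grow(sph, proj, c(0, 0, 40))
  # a different interior seed yields the same region
  inside_face <- setdiff(reg1$face_ids, proj$path_faces)[1]
  seed2 <- face_centroids(sph)[inside_face, ]
  reg2 <- region_grow(sph, proj, seed2)
  expect_setequal(reg1$face_ids, reg2$face_ids)
  # inside + outside regions partition the faces (barrier-strip faces
  # belong to whichever side their seed face lies on)
  reg_out <- region_grow(sph, proj, c(0, 0, -40), leak_fraction = 0.95)
  expect_length(intersect(reg1$face_ids, reg_out$face_ids), 0L)
  expect_setequal(union(reg1$face_ids, reg_out$face_ids), outer)
})

test_that("open contours and barrier gaps are rejected as leaks", {
  sph <- icosphere(40, 3)
  raw <- latitude_contour(c(0, 0, 1), 40, 0.8)
  proj <- project_contour(sph, raw, snap_tol_mm = 0.5)
  # open contour refuses to grow
  open_proj <- proj
  open_proj$closed <- FALSE
  expect_error(region_grow(sph, open_proj, c(0, 0, 40)),
               class = "craniotome_open_contour_error")
  # a single missing barrier edge lets growth leak over the sphere
  gappy <- proj
  gappy$barrier_edges <- gappy$barrier_edges[-1]
  expect_error(region_grow(sph, gappy, c(0, 0, 40)),
               class = "craniotome_leak_error")
  # a seed on a barrier edge is invalid
  edge <- proj$edge_table$edges[proj$barrier_edges[1], ]
  on_edge <- (sph$vertices[edge[1], ] + sph$vertices[edge[2], ]) / 2
  expect_error(region_grow(sph, proj, on_edge),
               class = "craniotome_seed_error")
})

test_that("a contour tightly around one face selects exactly that face", {
  ico <- icosphere(30, 0)              # icosahedron: 20 large faces
  et <- mesh_edge_table(ico)
  face <- 7L
  tri <- ico$faces[face, ]
  cen <- colMeans(ico$vertices[tri, ])
  # pierce each edge of the face: points just beyond each edge midpoint
  mids <- (ico$vertices[tri, ] + ico$vertices[tri[c(2, 3, 1)], ]) / 2
  pts <- mids + 0.35 * (mids - matrix(cen, 3, 3, byrow = TRUE))
  raw <- surface_contour(pts, closed = TRUE)
  proj <- project_contour(ico, raw, snap_tol_mm = 1.5)
  reg <- region_grow(ico, proj, cen)
  expect_equal(reg$face_ids, face)
})

test_that("excision removes exactly the region and opens one loop", {
  sph <- icosphere(40, 3)
  raw <- latitude_contour(c(0.2, 0.4, 0.89), 40, 0.7)
  proj <- project_contour(sph, raw, snap_tol_mm = 0.5)
  seed_pt <- 40 * c(0.2, 0.4, 0.89) / sqrt(sum(c(0.2, 0.4, 0.89)^2))
  reg <- region_grow(sph, proj, seed_pt)
  cut <- excise(sph, reg)
  expect_equal(nrow(cut$faces), nrow(sph$faces) - length(reg$face_ids))
  # new boundary equals the region rim found by an independent scan:
  # edges with exactly one incident face inside the region
  f <- sph$faces
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  all_keys <- c(ekey(f[, 1], f[, 2]), ekey(f[, 2], f[, 3]),
                ekey(f[, 3], f[, 1]))
  in_reg <- rep(seq_len(nrow(f)) %in% reg$face_ids, 3)
  rim <- names(which(tapply(in_reg, all_keys, function(x) {
    length(x) == 2 && sum(x) == 1
  })))
  cet <- mesh_edge_table(cut)
  bnd <- cet$edges[boundary_edges(cut, cet), , drop = FALSE]
  # compare geometrically (vertex indices change after excision)
  bnd_mid <- (cut$vertices[bnd[, 1], ] + cut$vertices[bnd[, 2], ]) / 2
  rim_pairs <- do.call(rbind, strsplit(rim, " "))
  rim_mid <- (sph$vertices[as.integer(rim_pairs[, 1]), ] +
                sph$vertices[as.integer(rim_pairs[, 2]), ]) / 2
  expect_equal(nrow(bnd_mid), nrow(rim_mid))
  o1 <- order(bnd_mid[, 1], bnd_mid[, 2], bnd_mid[, 3])
  o2 <- order(rim_mid[, 1], rim_mid[, 2], rim_mid[, 3])
  expect_equal(bnd_mid[o1, ], rim_mid[o2, ], tolerance = 1e-9)
  # the rim is one connected loop: every boundary vertex has degree 2
  expect_true(all(table(as.vector(bnd)) == 2))
  # rim edges are a subset of the crossed-edge barrier
  barrier_keys <- apply(proj$edge_table$edges[reg$barrier_edges, ,
                                              drop = FALSE], 1,
                        function(e) paste(e[1], e[2]))
  expect_true(all(rim %in% barrier_keys))
  # empty region is the identity; stale regions are rejected
  empty <- structure(list(face_ids = integer(0)),
                     class = "craniotomy_region")
  expect_identical(excise(sph, empty), sph)
  bad <- structure(list(face_ids = nrow(sph$faces) + 1L),
                   class = "craniotomy_region")
  expect_error(excise(sph, bad), "absent")
})

test_that("self-intersecting drawings are rejected", {
  ico <- icosphere(30, 0)                 # large flat faces
  tri <- ico$vertices[ico$faces[4, ], ]
  uv <- function(u, v) tri[1, ] + u * (tri[2, ] - tri[1, ]) +
    v * (tri[3, ] - tri[1, ])
  # bow-tie inside one face: the two diagonals cross
  bow <- surface_contour(rbind(uv(0.1, 0.1), uv(0.5, 0.1),
                               uv(0.1, 0.3), uv(0.5, 0.3)),
                         closed = TRUE)
  expect_error(project_contour(ico, bow, snap_tol_mm = 0.5),
               "intersects itself")
  # the simple rectangle through the same corners is fine
  rect <- surface_contour(rbind(uv(0.1, 0.1), uv(0.5, 0.1),
                                uv(0.5, 0.3), uv(0.1, 0.3)),
                          closed = TRUE)
  expect_s3_class(project_contour(ico, rect, snap_tol_mm = 0.5),
                  "projected_contour")
})
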