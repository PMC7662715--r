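# Cloud preprocessing: RANSAC ground plane, alignment, ground removal,
# simplification, radius filtering, PCA tilt, component isolation, I/O.

test_that("RANSAC recovers a known ground plane and is seed-deterministic", {
  sc <- blob_scene(n_ground = 1000, n_plant = 200, seed = 3)
  pl <- fit_ground_plane(sc$cloud, distance_threshold = 0.01, seed = 42)
  ang <- phenovid:::vector_angle_deg(pl$normal, c(0, 0, 1))
  expect_lt(min(ang, 180 - ang), 0.5)
  expect_gte(pl$inlier_count, 990)
  expect_gt(sum(pl$normal * c(0, 0, 1)), 0)   # oriented toward the plant side

  pl2 <- fit_ground_plane(sc$cloud, distance_threshold = 0.01, seed = 42)
  expect_identical(pl$normal, pl2$normal)
  expect_identical(pl$offset, pl2$offset)

  expect_error(fit_ground_plane(point_cloud(matrix(1:6, 2, 3))), "3 points")
})

test_that("a perfectly planar cloud is fit with every point as inlier", {
  set.seed(7)
  u <- runif(300); v <- runif(300)
  pts <- cbind(u, v, 1 - u - v)               # x + y + z = 1
  pl <- fit_ground_plane(point_cloud(pts), distance_threshold = 1e-6, seed = 1)
  expect_equal(pl$inlier_count, 300)
  expect_lt(max(abs(pts %*% pl$normal + pl$offset)), 1e-9)
})

test_that("align_to_ground is rigid and places the fitted plane at z = 0", {
  sc <- blob_scene(seed = 5)
  pl <- fit_ground_plane(sc$cloud, distance_threshold = 0.01, seed = 2)
  al <- align_to_ground(sc$cloud, pl)
  expect_equal(al$points, sc$cloud$points, tolerance = 1e-9)  # already aligned

  tilted <- make_plant_scene(plant_spec(seed = 6), scene_tilt_deg = 20)
  pt <- fit_ground_plane(tilted$cloud, seed = 4)
  alt <- align_to_ground(tilted$cloud, pt)
  # rigidity: pairwise distances preserved on a sample
  idx <- seq(1, nrow(alt$points), length.out = 60)
  d0 <- stats::dist(tilted$cloud$points[idx, ])
  d1 <- stats::dist(alt$points[idx, ])
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  # ground inliers end up inside the |z| <= threshold band
  gi <- which(tilted$truth$labels == 0)
  infit <- abs(tilted$cloud$points %*% pt$normal + pt$offset) <= pt$inlier_threshold
  expect_true(all(abs(alt$points[gi[infit[gi]], 3]) <= pt$inlier_threshold + 1e-9))
})

test_that("remove_ground keeps exactly the generator's plant points", {
  sc <- blob_scene(n_ground = 5000, n_plant = 3000, seed = 8,
                   ground_noise = 0.02)
  pl <- fit_ground_plane(sc$cloud, distance_threshold = 0.1, seed = 3)
  al <- align_to_ground(sc$cloud, pl)
  plant <- remove_ground(al, margin = 0.5)    # plant z in [1, 5], ground < 0.1
  expect_equal(nrow(plant$points), 3000)
  expect_true(all(plant$points[, 3] > 0.5))

  # huge negative margin: identity
  all_in <- remove_ground(al, margin = -1e9)
  expect_equal(nrow(all_in$points), nrow(al$points))

  ground_only <- point_cloud(al$points[sc$ground_idx, ])
  expect_error(remove_ground(ground_only, margin = 0.5), "no plant")
})

test_that("simplify_cloud hits the target range and respects the voxel contract", {
  small <- point_cloud(matrix(runif(8000 * 3), ncol = 3))
  expect_identical(simplify_cloud(small, c(10000, 30000)), small)

  set.seed(12)
  big <- point_cloud(matrix(runif(150000 * 3), ncol = 3))
  ds <- simplify_cloud(big, c(10000, 30000))
  expect_gte(nrow(ds$points), 10000)
  expect_lte(nrow(ds$points), 30000)
  # each output point is a voxel centroid: within half a voxel diagonal of
  # an input point is implied; check within one diagonal conservatively
  idx <- sample(nrow(ds$points), 50)
  for (i in idx) {
    d2 <- rowSums((big$points - matrix(ds$points[i, ], nrow(big$points), 3,
                                       byrow = TRUE))^2)
    expect_lt(sqrt(min(d2)), sqrt(3) * 1 / 10)  # voxel edge << 0.1 here
  }
})

test_that("radius_outlier_filter agrees exactly with the O(N^2) oracle", {
  lat <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:10))
  pts <- rbind(lat, c(100, 100, 100))
  cl <- point_cloud(pts)
  filt <- radius_outlier_filter(cl, radius = 1.5, min_neighbors = 3)
  oracle <- neighbor_count_oracle(pts, 1.5)
  expect_equal(nrow(filt$points), sum(oracle >= 3))
  expect_false(any(filt$points[, 1] == 100))       # isolated point removed
  # interior lattice points have 6+ neighbours at r = 1.5
  expect_gte(nrow(filt$points), 8 * 8 * 8)

  # huge radius: everything kept
  keep_all <- radius_outlier_filter(cl, radius = 1000, min_neighbors = 3)
  expect_equal(nrow(keep_all$points), nrow(pts))

  # second pass output is a subset of the first pass output
  set.seed(31)
  rnd <- point_cloud(matrix(rnorm(900), ncol = 3))
  p1 <- radius_outlier_filter(rnd, radius = 0.4, min_neighbors = 3)
  p2 <- radius_outlier_filter(p1, radius = 0.4, min_neighbors = 3)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(p2$points) %in% key(p1$points)))
})

test_that("grid and brute-force neighbour counting agree on larger clouds", {
  set.seed(44)
  pts <- matrix(runif(3000 * 3, 0, 5), ncol = 3)   # forces the grid path
  r <- 0.35
  expect_identical(phenovid:::radius_neighbor_counts(pts, r),
                   neighbor_count_oracle(pts, r))
})

test_that("principal_axis_tilt recovers closed-form and noisy tilts", {
  zline <- point_cloud(cbind(0, 0, seq(0, 10, 0.1)))
  expect_equal(principal_axis_tilt(zline), 90)

  t45 <- point_cloud(cbind(seq(0, 10, 0.1), 0, seq(0, 10, 0.1)))
  expect_equal(principal_axis_tilt(t45), 45, tolerance = 1e-9)

  set.seed(9)
  s <- seq(0, 10, length.out = 400)
  tube <- cbind(s * cos(phenovid:::deg2rad(60)) * 0,
                s * cos(phenovid:::deg2rad(60)),
                s * sin(phenovid:::deg2rad(60))) +
    matrix(rnorm(1200, 0, 0.1), ncol = 3)
  expect_equal(principal_axis_tilt(point_cloud(tube)), 60, tolerance = 3)

  expect_error(principal_axis_tilt(point_cloud(matrix(1, 5, 3))), "degenerate")
})

test_that("select_plant_component drops detached objects", {
  sc <- column_cloud(list(c(0, 0)), n_layers = 10, seed = 6)
  blob <- matrix(rnorm(150, 0, 0.05), ncol = 3) +
    matrix(c(10, 10, 2), 50, 3, byrow = TRUE)
  both <- point_cloud(rbind(sc$cloud$points, blob))
  main <- select_plant_component(both, voxel = 0.5)
  expect_equal(nrow(main$points), nrow(sc$cloud$points))
})

test_that("PLY and PCD round-trip coordinates, colours and labels", {
  set.seed(2)
  cl <- point_cloud(matrix(rnorm(90), ncol = 3),
                    colors = matrix(sample(0:255, 90, TRUE), ncol = 3),
                    labels = sample(c(-1L, 1L, 2L), 30, TRUE))
  f <- tempfile(fileext = ".ply")
  write_ply(cl, f)
  back <- read_ply(f)
  expect_equal(back$points, cl$points, tolerance = 1e-6)
  expect_identical(back$colors[, 1], cl$colors[, 1])
  expect_identical(back$labels, cl$labels)

  # binary little-endian PLY written independently here
  fb <- tempfile(fileext = ".ply")
  con <- file(fb, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               "end_header"), con)
  pts <- matrix(c(1.5, 2, 3, -1, 0, 0.25, 10, 20, 30), 3, 3, byrow = TRUE)
  cols <- matrix(c(255L, 0L, 0L, 0L, 255L, 0L, 0L, 0L, 255L), 3, 3, byrow = TRUE)
  for (i in 1:3) {
    writeBin(as.numeric(pts[i, ]), con, size = 4, endian = "little")
    writeBin(as.raw(cols[i, ]), con)
  }
  close(con)
  bb <- read_ply(fb)
  expect_equal(bb$points, `colnames<-`(pts, c("x", "y", "z")), tolerance = 1e-6)
  expect_equal(bb$colors[2, 2], 255L)

  fp <- tempfile(fileext = ".pcd")
  write_pcd(cl, fp)
  bp <- read_pcd(fp)
  expect_equal(bp$points, cl$points, tolerance = 1e-6)
  expect_identical(bp$labels, cl$labels)
})

test_that("the reconstruction adapter stub demands an existing cloud", {
  expect_error(reconstruction_adapter("frames", tempfile()), "adapter required")
})
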