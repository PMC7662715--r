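# Skeletonisation: slicing, in-layer clustering, inter-layer linking,
# pruning, spline smoothing and seeded segmentation.

test_that("slice_cloud follows the half-open layer convention", {
  cl <- point_cloud(cbind(0, 0, c(0.1, 1.1, 2.1)))
  layers <- slice_cloud(cl, 1)
  expect_length(layers, 3)
  expect_equal(lengths(layers), c(1, 1, 1))

  # a point exactly at z = dh belongs to layer 1 (second list element)
  cl2 <- point_cloud(cbind(0, 0, c(0.5, 1.0)))
  l2 <- slice_cloud(cl2, 1)
  expect_equal(l2[[1]], 1L)
  expect_equal(l2[[2]], 2L)

  # layer count equals ceil(zmax / dh) away from exact multiples
  set.seed(10)
  z <- runif(200, 0, 7.3)
  expect_length(slice_cloud(point_cloud(cbind(0, 0, z)), 0.4),
                ceiling(max(z) / 0.4))
  expect_error(slice_cloud(cl, 0), "dh")
})

test_that("cluster_layer reproduces single-linkage connected components", {
  set.seed(6)
  eps <- 0.3
  b1 <- matrix(rnorm(60, 0, 0.05), ncol = 3)
  b2 <- matrix(rnorm(60, 0, 0.05), ncol = 3) +
    matrix(c(10 * eps, 0, 0), 20, 3, byrow = TRUE)
  pts <- rbind(b1, b2)
  cls <- cluster_layer(pts, eps)
  expect_length(cls, 2)
  cents <- do.call(rbind, lapply(cls, `[[`, "centroid"))
  means <- rbind(colMeans(b1), colMeans(b2))
  expect_true(all(apply(cents, 1, function(ct)
    min(sqrt(rowSums((means - matrix(ct, 2, 3, byrow = TRUE))^2))) < eps)))

  # agreement with the BFS oracle on cluster membership counts
  oracle <- components_oracle(pts, eps)
  expect_equal(sort(lengths(lapply(cls, `[[`, "indices"))),
               sort(as.vector(table(oracle))))

  # chain within eps: one cluster
  chain <- cbind(seq(0, 2, by = 0.1), 0, 0)
  expect_length(cluster_layer(chain, 0.15), 1)

  single <- matrix(c(1, 2, 3), 1, 3)
  one <- cluster_layer(single, 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$centroid, c(1, 2, 3))
  expect_length(cluster_layer(matrix(numeric(0), 0, 3), 1), 0)
})

test_that("link_layers builds one branch per well-separated column", {
  two <- column_cloud(list(c(0, 0), c(5, 0)), n_layers = 12, seed = 2)
  layers <- slice_cloud(two$cloud, 0.5)
  cls <- lapply(layers, function(idx)
    cluster_layer(two$cloud$points[idx, , drop = FALSE], 0.5, indices = idx))
  sk <- link_layers(cls, link_dist = 1, dh = 0.5)
  expect_length(sk$branches, 2)
  expect_equal(sort(vapply(sk$branches, function(b) nrow(b$positions), 1L)),
               c(12L, 12L))
  # layers strictly increase along each branch
  for (b in sk$branches) expect_true(all(diff(b$layers) > 0))

  one <- column_cloud(list(c(0, 0)), n_layers = 8, seed = 3)
  l1 <- slice_cloud(one$cloud, 0.5)
  c1 <- lapply(l1, function(idx)
    cluster_layer(one$cloud$points[idx, , drop = FALSE], 0.5, indices = idx))
  expect_length(link_layers(c1, 1, dh = 0.5)$branches, 1)
})

test_that("a Y-shaped cloud forks into two branches at the junction height", {
  # stem up to z = 3, then two arms diverging
  set.seed(4)
  dz <- 0.25
  stem <- cbind(rnorm(300, 0, 0.05), rnorm(300, 0, 0.05), runif(300, 0, 3))
  arm <- function(dir) {
    s <- runif(300, 0, 3)
    cbind(dir * s * 2 + rnorm(300, 0, 0.05), rnorm(300, 0, 0.05),
          3 + s + rnorm(300, 0, 0.02))
  }
  cl <- point_cloud(rbind(stem, arm(1), arm(-1)))
  layers <- slice_cloud(cl, dz)
  cls <- lapply(layers, function(idx)
    cluster_layer(cl$points[idx, , drop = FALSE], 0.5, indices = idx))
  sk <- link_layers(cls, link_dist = 3 * dz, dh = dz)
  sk <- prune_branches(sk, 3)
  expect_gte(length(sk$branches), 2)
  # the non-continuing branch starts within 2 dh of the fork at z = 3
  starts <- vapply(sk$branches, function(b) b$positions[1, 3], numeric(1))
  expect_true(any(abs(starts - 3) <= 2 * dz + 0.1))
})

test_that("prune_branches applies the node-count threshold", {
  mk_branch <- function(n) list(positions = cbind(0, 0, seq_len(n)),
                                layers = seq_len(n),
                                members = as.list(seq_len(n)),
                                spline = NULL, label = 1L)
  sk <- structure(list(branches = lapply(c(12, 2, 9), mk_branch),
                       dh = 1, params = list()), class = "plant_skeleton")
  expect_length(prune_branches(sk, 3)$branches, 2)
  expect_length(prune_branches(sk, 1)$branches, 3)
  expect_error(prune_branches(sk, 13), "pruned")
})

test_that("spline smoothing preserves lines, denoises arcs, and bounds endpoints", {
  # collinear nodes: the spline is the same straight segment
  line <- list(positions = cbind(seq(0, 5, 0.5), 0, seq(0, 10, 1)),
               layers = 1:11, members = as.list(1:11), spline = NULL, label = 1L)
  sk <- structure(list(branches = list(line), dh = 1, params = list()),
                  class = "plant_skeleton")
  sm <- smooth_branches(sk)
  b <- sm$branches[[1]]
  fit <- phenovid:::eval_branch_spline(b$spline, b$spline$t)
  expect_lt(max(abs(fit - line$positions)), 1e-6)

  # noisy quadratic arc: spline RMS deviation below raw node RMS deviation
  set.seed(15)
  t <- seq(0, 1, length.out = 40)
  true_arc <- cbind(t * 8, 0, 12 * t - 6 * t^2)
  jit <- true_arc + matrix(rnorm(120, 0, 0.15), ncol = 3)
  arc_b <- list(positions = jit, layers = 1:40, members = as.list(1:40),
                spline = NULL, label = 1L)
  ska <- smooth_branches(structure(list(branches = list(arc_b), dh = 0.3,
                                        params = list()),
                                   class = "plant_skeleton"))
  sp <- ska$branches[[1]]$spline
  fit <- phenovid:::eval_branch_spline(sp, sp$t)
  rms <- function(m) sqrt(mean(rowSums((m - true_arc)^2)))
  expect_lt(rms(fit), rms(jit))
  # endpoints stay within dh of the first/last node
  ends <- phenovid:::eval_branch_spline(sp, c(0, 1))
  expect_lt(sqrt(sum((ends[1, ] - jit[1, ])^2)), 0.3)
  expect_lt(sqrt(sum((ends[2, ] - jit[40, ])^2)), 0.3)

  # metric property: arc length is at least the endpoint distance
  al <- phenovid:::branch_arc_length(ska$branches[[1]])
  expect_gte(al, sqrt(sum((fit[nrow(fit), ] - fit[1, ])^2)) - 1e-9)
})

test_that("segment_cloud labels partition the cloud and match generator truth", {
  two <- column_cloud(list(c(0, 0), c(5, 0)), n_layers = 12, seed = 8)
  layers <- slice_cloud(two$cloud, 0.5)
  cls <- lapply(layers, function(idx)
    cluster_layer(two$cloud$points[idx, , drop = FALSE], 0.5, indices = idx))
  sk <- smooth_branches(link_layers(cls, 1, dh = 0.5))
  seg <- segment_cloud(two$cloud, sk)
  expect_length(seg$labels, nrow(two$cloud$points))
  expect_true(all(seg$labels %in% c(1L, 2L)))
  # branch labels may be in either discovery order; compare as a partition
  agree <- max(mean(seg$labels == two$labels), mean(seg$labels == 3L - two$labels))
  expect_gte(agree, 0.95)

  single <- column_cloud(list(c(0, 0)), n_layers = 8, seed = 1)
  l1 <- slice_cloud(single$cloud, 0.5)
  c1 <- lapply(l1, function(idx)
    cluster_layer(single$cloud$points[idx, , drop = FALSE], 0.5, indices = idx))
  s1 <- link_layers(c1, 1, dh = 0.5)
  expect_true(all(segment_cloud(single$cloud, s1)$labels == 1L))
})

test_that("noise-free non-overlapping plants yield one branch per leaf", {
  # dense sampling: the noise-free ideal is a well-resolved surface, where
  # slice strips cannot break on random sampling gaps
  sc <- make_plant_scene(plant_spec(seed = 20, n_leaves = 4,
                                    noise_sigma_cm = 0,
                                    points_per_leaf = 4000),
                         n_cubes = 0, ground_points = 0)
  plant <- remove_ground(sc$cloud, margin = 0.01)
  sk <- extract_skeleton(plant)
  expect_equal(length(sk$branches), 4)
  # node membership sets are pairwise disjoint
  memb <- unlist(lapply(sk$branches, function(b) unlist(b$members)))
  expect_equal(anyDuplicated(memb), 0)
})

test_that("skeletons round-trip through JSON and export to OBJ", {
  sc <- column_cloud(list(c(0, 0), c(4, 0)), n_layers = 10, seed = 12)
  layers <- slice_cloud(sc$cloud, 0.5)
  cls <- lapply(layers, function(idx)
    cluster_layer(sc$cloud$points[idx, , drop = FALSE], 0.5, indices = idx))
  sk <- smooth_branches(link_layers(cls, 1, dh = 0.5))
  f <- tempfile(fileext = ".json")
  write_skeleton_json(sk, f)
  back <- read_skeleton_json(f)
  expect_length(back$branches, length(sk$branches))
  for (i in seq_along(sk$branches)) {
    expect_equal(back$branches[[i]]$positions, sk$branches[[i]]$positions,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(back$branches[[i]]$layers, sk$branches[[i]]$layers)
  }
  fo <- tempfile(fileext = ".obj")
  write_skeleton_obj(sk, fo)
  obj <- readLines(fo)
  expect_equal(sum(grepl("^v ", obj)), sum(vapply(sk$branches,
                                                  function(b) nrow(b$positions), 1L)))
  expect_equal(sum(grepl("^l ", obj)), length(sk$branches))
})
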