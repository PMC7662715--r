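# Trait extraction: calibration, height, leaf count/length/angle, metrics.

test_that("scale_factor follows k = L_real / L_virtual, averaging two cubes", {
  expect_equal(scale_factor(56, 0.28)$k, 200)
  expect_equal(scale_factor(5, 5)$k, 1)
  expect_equal(scale_factor(56, c(56 / 199, 56 / 201))$k, 200)
  expect_error(scale_factor(56, -1), "positive")
  expect_error(scale_factor(0, 1), "positive")
})

test_that("cube_edge_from_cloud measures parallel-face separation", {
  make_cube <- function(a, npf, sigma = 0, seed = 1) {
    set.seed(seed)
    f <- do.call(rbind, lapply(1:6, function(fc) {
      uu <- runif(npf, -a / 2, a / 2); vv <- runif(npf, -a / 2, a / 2)
      fx <- a / 2 * (if (fc %% 2 == 0) 1 else -1)
      switch((fc - 1) %/% 2 + 1,
             cbind(fx, uu, vv), cbind(uu, fx, vv), cbind(uu, vv, fx))
    }))
    if (sigma > 0) f <- f + rnorm(length(f), 0, sigma)
    point_cloud(f)
  }
  # noise-free axis-aligned cube: exact to 1e-6
  exact <- cube_edge_from_cloud(make_cube(0.28, 400), seed = 5)
  expect_lt(abs(exact - 0.28), 1e-6)

  # light noise: within 1%
  noisy <- cube_edge_from_cloud(make_cube(0.28, 400, sigma = 0.001, seed = 2),
                                seed = 9)
  expect_lt(abs(noisy - 0.28) / 0.28, 0.01)

  # two parallel planes only: their separation
  set.seed(3)
  pl <- rbind(cbind(runif(400), runif(400), 0),
              cbind(runif(400), runif(400), 0.7))
  expect_lt(abs(cube_edge_from_cloud(point_cloud(pl), seed = 4) - 0.7), 1e-6)

  # a single plane cannot calibrate
  one <- point_cloud(cbind(runif(300), runif(300), 0))
  expect_error(cube_edge_from_cloud(one, seed = 1), "calibration error")
})

test_that("plant_height applies the scale and tilt correction", {
  cl <- point_cloud(cbind(0, 0, c(1, 4, 9)))        # zmax - zmin = 8
  expect_equal(plant_height(cl, 90, 1), 8)
  expect_equal(plant_height(cl, 30, 1), 16)
  expect_equal(plant_height(cl, 90, 2.5), 20)
  expect_error(plant_height(cl, 0), "theta")

  sc <- make_plant_scene(plant_spec(seed = 30))
  pl <- fit_ground_plane(sc$cloud, seed = 2)
  plant <- select_plant_component(
    remove_ground(align_to_ground(sc$cloud, pl), pl))
  h <- plant_height(plant, 90, sc$truth$k_mm_per_unit / 10)
  expect_lt(abs(h - sc$truth$height_cm) / sc$truth$height_cm, 0.02)
})

test_that("leaf_count equals the surviving branch count", {
  mk <- function(n) list(positions = cbind(0, 0, seq_len(n)), layers = seq_len(n),
                         members = as.list(seq_len(n)), spline = NULL, label = 1L)
  sk <- structure(list(branches = lapply(c(5, 6, 7, 2), mk), dh = 1,
                       params = list()), class = "plant_skeleton")
  expect_equal(leaf_count(sk), 4)
  expect_equal(leaf_count(prune_branches(sk, 3)), 3)
  empty <- structure(list(branches = list(), dh = 1, params = list()),
                     class = "plant_skeleton")
  expect_error(leaf_count(empty), "empty")
})

test_that("leaf_length sums consecutive node distances, scaled by k", {
  br <- list(positions = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1)),
             layers = 1:3, members = as.list(1:3), spline = NULL, label = 1L)
  expect_equal(leaf_length(br, k = 1, use_spline = FALSE), 2)
  expect_equal(leaf_length(br, k = 10, use_spline = FALSE), 20)

  straight <- list(positions = cbind(0, seq(0, 3, 0.5), seq(0, 6, 1)),
                   layers = 1:7, members = as.list(1:7), spline = NULL, label = 1L)
  expect_equal(leaf_length(straight, use_spline = FALSE),
               sqrt(3^2 + 6^2))

  one <- list(positions = matrix(0, 1, 3), layers = 1L, members = list(1L),
              spline = NULL, label = 1L)
  expect_error(leaf_length(one), "fewer than 2")

  # curved synthetic leaf: skeleton branch length within 5% of the true arc
  sc <- make_plant_scene(plant_spec(seed = 31, n_leaves = 1,
                                    leaf_lengths_cm = 20,
                                    leaf_elevations_deg = 65,
                                    leaf_azimuths_deg = 0,
                                    noise_sigma_cm = 0.15,
                                    points_per_leaf = 3000),
                         n_cubes = 0, ground_points = 0)
  plant <- remove_ground(sc$cloud, margin = 0.02)
  sk <- extract_skeleton(plant)
  expect_length(sk$branches, 1)
  lb <- leaf_length(sk$branches[[1]], k = sc$truth$k_mm_per_unit / 10)
  expect_lt(abs(lb - sc$truth$leaf_lengths_cm) / sc$truth$leaf_lengths_cm, 0.05)
})

test_that("leaf_angle follows the arccos formula with tip-ward orientation", {
  expect_equal(leaf_angle(c(0, 0, 1)), 0)
  expect_equal(leaf_angle(c(1, 0, 1) / sqrt(2)), 45, tolerance = 1e-9)
  expect_equal(leaf_angle(c(1, 0, 0)), 90)
  expect_error(leaf_angle(c(0, 0, 0)), "zero")

  # orientation sensitivity: gamma and -gamma are complementary to 180
  set.seed(18)
  for (i in 1:20) {
    g <- rnorm(3)
    expect_equal(leaf_angle(g) + leaf_angle(-g), 180, tolerance = 1e-9)
  }
})

test_that("rmse and mape match direct evaluation and their worked examples", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(3, 1), 2)
  expect_equal(rmse(c(2, 4), c(1, 2)), sqrt(2.5))
  expect_error(rmse(1:3, 1:2), "mismatch")

  expect_equal(mape(c(5, 7), c(5, 7)), 0)
  expect_equal(mape(3, 2), 50)
  expect_equal(mape(c(110, 90), c(100, 100)), 10)
  expect_error(mape(1, 0), "nonzero")

  # brute-force per-element agreement on random vectors
  set.seed(23)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    xs <- rnorm(n, 10); xm <- rnorm(n, 10)
    acc_r <- 0; acc_m <- 0
    for (j in seq_len(n)) {
      acc_r <- acc_r + (xs[j] - xm[j])^2
      acc_m <- acc_m + abs(xs[j] - xm[j]) / abs(xm[j])
    }
    expect_equal(rmse(xs, xm), sqrt(acc_r / n), tolerance = 1e-12)
    expect_equal(mape(xs, xm), acc_m / n * 100, tolerance = 1e-12)
  }
})

test_that("accuracy is 100 minus MAPE at one-decimal rounding", {
  expect_equal(accuracy_from_mape(17.78), 82.2)
  expect_equal(accuracy_from_mape(12.61), 87.4)
  expect_equal(accuracy_from_mape(16.61), 83.4)
  expect_equal(accuracy_from_mape(0), 100)
  expect_error(accuracy_from_mape(120), "\\[0, 100\\]")
})

test_that("traits are invariant under a uniform virtual-unit rescale", {
  sc <- make_plant_scene(plant_spec(seed = 33, points_per_leaf = 1200),
                         n_cubes = 0, ground_points = 0)
  plant <- remove_ground(sc$cloud, margin = 0.02)
  measure <- function(cl, lv) {
    sk <- extract_skeleton(cl)
    measure_traits(cl, sk, scale_factor(56, lv))
  }
  lv <- sc$truth$cube_edge_virtual
  r1 <- measure(plant, lv)
  c_ <- 3.7
  r2 <- measure(point_cloud(plant$points * c_), lv * c_)
  expect_equal(r2$height_cm, r1$height_cm, tolerance = 1e-9)
  expect_equal(r2$leaf_count, r1$leaf_count)
  expect_equal(r2$leaf_lengths_cm, r1$leaf_lengths_cm, tolerance = 1e-9)
  expect_equal(r2$leaf_angles_deg, r1$leaf_angles_deg, tolerance = 1e-9)
})

test_that("measure_traits assembles a consistent report", {
  sc <- make_plant_scene(plant_spec(seed = 34, points_per_leaf = 1200),
                         n_cubes = 0, ground_points = 0)
  plant <- remove_ground(sc$cloud, margin = 0.02)
  sk <- extract_skeleton(plant)
  rep <- measure_traits(plant, sk, scale_factor(56, sc$truth$cube_edge_virtual))
  expect_s3_class(rep, "phenotype_report")
  expect_equal(rep$leaf_count, length(rep$leaf_lengths_cm))
  expect_equal(rep$leaf_count, length(rep$leaf_angles_deg))
  expect_true(all(rep$leaf_lengths_cm > 0))
  expect_gt(rep$height_cm, 0)
  expect_true(all(rep$leaf_angles_deg >= 0 & rep$leaf_angles_deg <= 180))
  expect_equal(rep$leaf_ground_angles_deg, 90 - rep$leaf_angles_deg)

  f <- tempfile(fileext = ".csv")
  write_report(rep, csv_path = f)
  df <- utils::read.csv(f)
  expect_equal(df$leaf_count, rep$leaf_count)
})

test_that("evaluate_traits reports rmse/mape/accuracy per shared trait", {
  pred <- data.frame(height_cm = c(21, 19), leaf_count = c(6, 7))
  truth <- data.frame(height_cm = c(20, 20), leaf_count = c(6, 6))
  ev <- evaluate_traits(pred, truth)
  expect_setequal(ev$trait, c("height_cm", "leaf_count"))
  h <- ev[ev$trait == "height_cm", ]
  expect_equal(h$rmse, 1)
  expect_equal(h$mape_pct, 5)
  expect_equal(h$accuracy_pct, 95)
  expect_error(evaluate_traits(pred, data.frame(x = 1)), "shared")
})
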