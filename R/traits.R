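# Trait extraction: metric scale calibration from reference cubes, plant
# height, leaf number, leaf length, leaf angle, and the evaluation metrics
# (RMSE, MAPE, accuracy = 100 - MAPE).

#' Metric scale factor from a reference cube
#'
#' Relates virtual reconstruction units to the real world through a cube of
#' known edge length placed in the scene: k = L_real / L_virtual (mm per
#' virtual unit). With measurements from two cubes, the two factors are
#' averaged.
#'
#' @param l_real real cube edge in mm (the reference cubes used here are
#'   56 mm).
#' @param l_virtual measured cube edge(s) in virtual units; may have length 2
#'   when two cubes were reconstructed.
#' @return an object of class `scale_calibration` with fields `l_real`,
#'   `l_virtual` and `k` (mm per virtual unit).
#' @export
scale_factor <- function(l_real = 56, l_virtual) {
  if (any(l_real <= 0) || any(l_virtual <= 0))
    stopf("cube edge lengths must be positive")
  ks <- rep(l_real, length.out = length(l_virtual)) / l_virtual
  structure(list(l_real = l_real, l_virtual = l_virtual, k = mean(ks)),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("scale_calibration: k = %.6g mm per virtual unit (cube edge %g mm; virtual %s)\n",
              x$k, x$l_real[1], paste(signif(x$l_virtual, 6), collapse = ", ")))
  invisible(x)
}

#' Measure the cube edge from its point cloud
#'
#' Fits planes to the cube cloud by sequential RANSAC, finds the two largest
#' near-parallel planes (normals within 5 degrees) and returns the distance
#' between them along the mean normal: an operator-free virtual edge
#' measurement for calibration.
#'
#' @param cube_cloud [point_cloud()] containing one cube (at least two
#'   opposite faces).
#' @param distance_threshold RANSAC inlier distance; `NULL` (auto) uses
#'   0.01 x the cube bounding-box diagonal.
#' @param seed integer seed.
#' @param max_planes number of planes to extract before searching for a
#'   parallel pair.
#' @return the virtual edge length (distance between the parallel faces).
#' @export
cube_edge_from_cloud <- function(cube_cloud, distance_threshold = NULL,
                                 seed = NULL, max_planes = 6) {
  if (is.null(distance_threshold))
    distance_threshold <- 0.01 * bbox_diagonal(cube_cloud)
  remaining <- cube_cloud
  planes <- list()
  for (p in seq_len(max_planes)) {
    if (n_points(remaining) < 30) break
    pl <- tryCatch(
      fit_ground_plane(remaining, distance_threshold = distance_threshold,
                       max_iterations = 500, seed = derive_seed(seed, p)),
      error = function(e) NULL)
    if (is.null(pl) || pl$inlier_count < 20) break
    # tighten: refit on a shrinking band so strips of perpendicular faces
    # caught in the initial inlier band cannot tilt the plane
    face <- remaining$points[pl$inliers, , drop = FALSE]
    nrm <- pl$normal; off <- pl$offset
    for (band in distance_threshold * c(0.5, 0.2)) {
      sel <- abs(face %*% nrm + off) <= band
      if (sum(sel) < 10) break
      fit <- fit_plane_lsq(face[sel, , drop = FALSE])
      nrm <- fit$normal; off <- fit$offset
    }
    planes[[length(planes) + 1]] <- list(normal = nrm, offset = off,
                                         count = pl$inlier_count, pts = face)
    remaining <- subset_cloud(remaining, setdiff(seq_len(n_points(remaining)),
                                                 pl$inliers))
  }
  if (length(planes) < 2)
    stopf("calibration error: fewer than two planes found in the cube cloud")
  best <- NULL; best_size <- -1
  for (a in seq_along(planes)) for (b in seq_along(planes)) {
    if (b <= a) next
    cosang <- abs(sum(planes[[a]]$normal * planes[[b]]$normal))
    if (cosang >= cos(deg2rad(5))) {
      size <- min(planes[[a]]$count, planes[[b]]$count)
      if (size > best_size) { best_size <- size; best <- c(a, b) }
    }
  }
  if (is.null(best))
    stopf("calibration error: no near-parallel plane pair found in the cube cloud")
  pa <- planes[[best[1]]]; pb <- planes[[best[2]]]
  nbar <- pa$normal + pb$normal * sign(sum(pa$normal * pb$normal))
  nbar <- nbar / sqrt(sum(nbar^2))
  # median projections are robust to the thin strips of perpendicular-face
  # points that fall inside each face's inlier band
  abs(stats::median(pa$pts %*% nbar) - stats::median(pb$pts %*% nbar))
}

#' Plant height from the aligned cloud
#'
#' H = k |zmax - zmin| / sin(theta): the Z extent of the plant cloud, scaled
#' to real units and corrected for a plant growing at angle `theta_deg` to
#' the ground. With the default theta = 90 (plant perpendicular to the
#' ground) the correction is the identity.
#'
#' @param cloud ground-aligned plant [point_cloud()].
#' @param theta_deg plant-to-ground angle in (0, 90]; typically from
#'   [principal_axis_tilt()].
#' @param k scale factor: real-world length per virtual unit, in the unit the
#'   answer should carry (pass a `scale_calibration` `k` / 10 for cm).
#' @return the plant height in the units of `k` x virtual units.
#' @export
plant_height <- function(cloud, theta_deg = 90, k = 1) {
  if (theta_deg <= 0 || theta_deg > 90) stopf("theta_deg must be in (0, 90]")
  if (n_points(cloud) == 0) stopf("empty cloud")
  z <- cloud$points[, 3]
  k * abs(max(z) - min(z)) / sin(deg2rad(theta_deg))
}

#' Leaf count of a pruned skeleton
#'
#' For rosette-forming leafy vegetables with no clear stem/leaf boundary,
#' each surviving skeleton branch corresponds to one leaf, so the leaf
#' number is the branch count.
#'
#' @param skeleton a pruned `plant_skeleton`.
#' @return integer number of branches.
#' @export
leaf_count <- function(skeleton) {
  if (length(skeleton$branches) == 0) stopf("empty skeleton")
  length(skeleton$branches)
}

#' Leaf length from a skeleton branch
#'
#' The branch length is the summed distance between consecutive branch
#' points, L = sum |v_i v_{i+1}|, evaluated on the fitted spline (resampled
#' densely; default) or on the raw nodes, scaled by `k`.
#'
#' @param branch one element of `skeleton$branches`.
#' @param k scale factor (real length per virtual unit).
#' @param use_spline measure along the fitted B-spline when available
#'   (default) rather than the raw node polyline.
#' @return the leaf length in the units of `k` x virtual units.
#' @export
leaf_length <- function(branch, k = 1, use_spline = TRUE) {
  if (nrow(branch$positions) < 2) stopf("branch has fewer than 2 nodes")
  k * branch_arc_length(branch, use_spline = use_spline)
}

# Tip-ward tangent at the basal end of a branch. Evaluated as the chord over
# the basal 15% of the fitted spline (or the corresponding node span): single
# node-to-node directions are dominated by centroid jitter, while the short
# basal chord averages it out at a negligible curvature bias.
basal_tangent <- function(branch, window = 0.15) {
  if (!is.null(branch$spline)) {
    p <- eval_branch_spline(branch$spline, c(0, window))
    g <- p[2, ] - p[1, ]
  } else {
    p <- branch$positions
    k <- min(nrow(p), max(2, ceiling(window * nrow(p))))
    g <- p[k, ] - p[1, ]
  }
  if (sqrt(sum(g^2)) < 1e-12) stopf("zero basal tangent")
  g
}

#' Leaf angle from the ground normal
#'
#' theta = arccos( (alpha . gamma) / (|alpha| |gamma|) ), where alpha is the
#' ground normal ((0,0,1) after alignment) and gamma is the branch tangent
#' at the basal end, oriented tip-ward. The angle is measured from the
#' normal: a vertical leaf gives 0, a horizontal leaf 90. The complementary
#' angle with the ground itself is 90 - theta (reported as a secondary
#' column by [measure_traits()], since field protocols often quote the
#' leaf-to-ground angle).
#'
#' @param branch a skeleton branch, or directly a 3-vector tangent.
#' @param ground_normal the ground normal vector (default c(0, 0, 1)).
#' @return the angle in degrees, in [0, 180].
#' @export
leaf_angle <- function(branch, ground_normal = c(0, 0, 1)) {
  gamma <- if (is.numeric(branch) && length(branch) == 3) branch else
    basal_tangent(branch)
  vector_angle_deg(ground_normal, gamma)
}

#' Root-mean-square error
#'
#' RMSE = sqrt(mean((x_s - x_m)^2)) between system and manual measurements.
#'
#' @param system,manual equal-length numeric vectors.
#' @return a non-negative number.
#' @export
rmse <- function(system, manual) {
  if (length(system) != length(manual)) stopf("length mismatch")
  if (length(system) == 0) stopf("empty input")
  sqrt(mean((system - manual)^2))
}

#' Mean absolute percentage error
#'
#' MAPE = mean(|x_s - x_m| / x_m) x 100, in percent.
#'
#' @inheritParams rmse
#' @return a percentage.
#' @export
mape <- function(system, manual) {
  if (length(system) != length(manual)) stopf("length mismatch")
  if (length(system) == 0) stopf("empty input")
  if (any(manual == 0)) stopf("manual values must be nonzero for MAPE")
  mean(abs(system - manual) / abs(manual)) * 100
}

#' Accuracy from a MAPE value
#'
#' accuracy = 100 - MAPE, rounded to one decimal: e.g. a 17.78% MAPE in leaf
#' number corresponds to 82.2% accuracy.
#'
#' @param mape_percent MAPE in [0, 100].
#' @return accuracy in percent, one decimal.
#' @export
accuracy_from_mape <- function(mape_percent) {
  if (any(mape_percent < 0 | mape_percent > 100))
    stopf("mape must be in [0, 100]")
  round(100 - mape_percent, 1)
}

#' Measure all phenotypic traits of one plant
#'
#' Assembles the full per-plant report: plant height, leaf number, per-leaf
#' lengths and angles, all in real-world units via the cube calibration.
#' Internally all geometry is in virtual units; `calibration$k` carries mm
#' per virtual unit and is converted to cm at report time.
#'
#' @param cloud ground-aligned, ground-removed plant [point_cloud()].
#' @param skeleton pruned, smoothed `plant_skeleton` of that cloud.
#' @param calibration a `scale_calibration` from [scale_factor()].
#' @param tilt `"off"` (theta = 90) or `"pca"` (use
#'   [principal_axis_tilt()] to correct the height of a leaning plant).
#' @param use_spline measure leaf lengths on splines (default) or raw nodes.
#' @return an object of class `phenotype_report`: `height_cm`, `leaf_count`,
#'   `leaf_lengths_cm`, `leaf_angles_deg` (from the ground normal),
#'   `leaf_ground_angles_deg` (= 90 - angle), `theta_deg`, `calibration`,
#'   `provenance`.
#' @export
measure_traits <- function(cloud, skeleton, calibration,
                           tilt = c("off", "pca"), use_spline = TRUE) {
  tilt <- match.arg(tilt)
  theta <- if (tilt == "pca") principal_axis_tilt(cloud) else 90
  k_cm <- calibration$k / 10                      # mm per unit -> cm per unit
  lengths <- vapply(skeleton$branches, leaf_length, numeric(1),
                    k = k_cm, use_spline = use_spline)
  angles <- vapply(skeleton$branches, leaf_angle, numeric(1))
  structure(list(height_cm = plant_height(cloud, theta, k_cm),
                 leaf_count = leaf_count(skeleton),
                 leaf_lengths_cm = lengths,
                 leaf_angles_deg = angles,
                 leaf_ground_angles_deg = 90 - angles,
                 theta_deg = theta,
                 calibration = calibration,
                 provenance = list(n_points = n_points(cloud),
                                   n_branches = length(skeleton$branches),
                                   dh = skeleton$dh,
                                   tilt = tilt,
                                   use_spline = use_spline,
                                   cloud_hash = object_hash(cloud$points))),
            class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("phenotype_report\n")
  cat(sprintf("  plant height: %.2f cm (theta = %.1f deg)\n", x$height_cm, x$theta_deg))
  cat(sprintf("  leaf number:  %d\n", x$leaf_count))
  cat(sprintf("  leaf length:  %s cm\n",
              paste(sprintf("%.1f", x$leaf_lengths_cm), collapse = ", ")))
  cat(sprintf("  leaf angle:   %s deg (from ground normal)\n",
              paste(sprintf("%.1f", x$leaf_angles_deg), collapse = ", ")))
  cat(sprintf("  scale: k = %.4g mm per virtual unit\n", x$calibration$k))
  invisible(x)
}

#' Write a phenotype report as JSON and/or CSV
#'
#' JSON carries the full report including provenance; CSV is one row per
#' plant with height, leaf count and comma-joined per-leaf columns.
#'
#' @param report a `phenotype_report`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    plain <- unclass(report)
    plain$calibration <- unclass(plain$calibration)
    jsonlite::write_json(plain, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    df <- data.frame(height_cm = report$height_cm,
                     leaf_count = report$leaf_count,
                     mean_leaf_length_cm = mean(report$leaf_lengths_cm),
                     leaf_lengths_cm = paste(signif(report$leaf_lengths_cm, 6),
                                             collapse = ";"),
                     leaf_angles_deg = paste(signif(report$leaf_angles_deg, 6),
                                             collapse = ";"),
                     theta_deg = report$theta_deg,
                     k_mm_per_unit = report$calibration$k)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(report)
}

#' Evaluate predicted traits against manual measurements
#'
#' For each shared numeric column of the two tables, computes RMSE, MAPE and
#' accuracy (100 - MAPE).
#'
#' @param pred,truth data.frames with matching rows (one per plant) and
#'   shared numeric columns.
#' @return data.frame with one row per trait: `trait`, `rmse`, `mape_pct`,
#'   `accuracy_pct`.
#' @export
evaluate_traits <- function(pred, truth) {
  common <- intersect(names(pred), names(truth))
  common <- common[vapply(common, function(cn)
    is.numeric(pred[[cn]]) && is.numeric(truth[[cn]]), logical(1))]
  if (length(common) == 0) stopf("no shared numeric trait columns")
  if (nrow(pred) != nrow(truth)) stopf("pred and truth must have matching rows")
  do.call(rbind, lapply(common, function(cn) {
    data.frame(trait = cn,
               rmse = rmse(pred[[cn]], truth[[cn]]),
               mape_pct = mape(pred[[cn]], truth[[cn]]),
               accuracy_pct = accuracy_from_mape(
                 min(100, mape(pred[[cn]], truth[[cn]]))))
  }))
}
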