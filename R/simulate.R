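# Seeded synthetic fixtures with known ground truth: rosette-plant point
# cloud scenes (plant + ground + reference cubes) and rotating-plant frame
# sequences with controlled motion blur. These stand in for field recordings
# so that every pipeline stage can be tested against exact truth.

#' Specify a synthetic rosette plant
#'
#' Defaults emulate a mature leaf-beet-like rosette: ~28 cm tall, 6 fairly
#' upright leaves (basal elevations 50-75 degrees above the ground) radiating
#' at equal azimuths, each leaf a drooping quadratic Bezier midrib carrying a
#' point tube plus an elliptical blade patch near the tip. Coordinate noise
#' defaults to 1% of plant size.
#'
#' @param height_cm nominal plant height; the realised height (max z of the
#'   noise-free geometry) is recorded in the scene truth.
#' @param n_leaves number of leaves.
#' @param leaf_lengths_cm per-leaf midrib arc lengths; default spreads
#'   0.65-0.95 x `height_cm`.
#' @param leaf_elevations_deg basal elevation of each midrib above the ground
#'   plane, in (0, 90]; default spreads 75 down to 50.
#' @param leaf_azimuths_deg leaf directions; default equally spaced (or
#'   squeezed into 100 degrees when `overlap = TRUE`).
#' @param points_per_leaf points sampled per leaf.
#' @param crown_radius_cm radius of the basal crown: each leaf attaches at
#'   this distance from the axis in its own azimuth, as on a real rosette.
#' @param noise_sigma_cm isotropic Gaussian coordinate noise (cm).
#' @param overlap squeeze azimuths so that neighbouring leaves overlap (the
#'   known hard case for slice clustering).
#' @param seed integer seed; the scene is fully deterministic given the spec.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(height_cm = 28, n_leaves = 6, leaf_lengths_cm = NULL,
                       leaf_elevations_deg = NULL, leaf_azimuths_deg = NULL,
                       points_per_leaf = 2500, crown_radius_cm = 2.5,
                       noise_sigma_cm = 0.28, overlap = FALSE, seed = 1) {
  if (n_leaves < 1) stopf("n_leaves must be >= 1")
  if (height_cm <= 0 || noise_sigma_cm < 0) stopf("invalid plant_spec sizes")
  if (is.null(leaf_lengths_cm))
    leaf_lengths_cm <- seq(0.70, 0.95, length.out = n_leaves) * height_cm
  if (is.null(leaf_elevations_deg))
    leaf_elevations_deg <- seq(50, 75, length.out = n_leaves)
  if (is.null(leaf_azimuths_deg)) {
    span <- if (overlap) 100 else 360 * (n_leaves - 1) / n_leaves
    leaf_azimuths_deg <- seq(0, span, length.out = n_leaves)
  }
  if (length(leaf_lengths_cm) != n_leaves ||
      length(leaf_elevations_deg) != n_leaves ||
      length(leaf_azimuths_deg) != n_leaves)
    stopf("per-leaf vectors must have length n_leaves")
  if (any(leaf_elevations_deg <= 0 | leaf_elevations_deg > 90))
    stopf("leaf elevations must be in (0, 90] degrees")
  if (any(leaf_lengths_cm <= 0)) stopf("leaf lengths must be positive")
  structure(list(height_cm = height_cm, n_leaves = n_leaves,
                 leaf_lengths_cm = leaf_lengths_cm,
                 leaf_elevations_deg = leaf_elevations_deg,
                 leaf_azimuths_deg = leaf_azimuths_deg,
                 points_per_leaf = points_per_leaf,
                 crown_radius_cm = crown_radius_cm,
                 noise_sigma_cm = noise_sigma_cm,
                 overlap = overlap, seed = seed),
            class = "plant_spec")
}

# Quadratic Bezier midrib with basal elevation `elev`, azimuth `azim` and
# exact arc length L (cm): control points chosen so the tangent droops by
# `droop` degrees from base to tip, then scaled to the requested length.
leaf_midrib <- function(L, elev, azim, droop = 15) {
  e0 <- deg2rad(elev); e1 <- deg2rad(max(elev - droop, 5))
  d0 <- c(cos(e0), sin(e0)); d1 <- c(cos(e1), sin(e1))
  P1 <- d0; P2 <- d0 + d1                       # planar (horiz, vert), unit scale
  tt <- seq(0, 1, length.out = 2001)
  bez2 <- function(t, a, b) (1 - t)^2 * 0 + 2 * t * (1 - t) * a + t^2 * b
  h <- bez2(tt, P1[1], P2[1]); v <- bez2(tt, P1[2], P2[2])
  len1 <- sum(sqrt(diff(h)^2 + diff(v)^2))
  s <- L / len1
  az <- deg2rad(azim)
  list(point = function(t) {
    h <- s * (2 * t * (1 - t) * P1[1] + t^2 * P2[1])
    v <- s * (2 * t * (1 - t) * P1[2] + t^2 * P2[2])
    cbind(h * cos(az), h * sin(az), v)
  },
  tangent = function(t) {
    dh <- s * 2 * ((1 - 2 * t) * P1[1] + t * P2[1])
    dv <- s * 2 * ((1 - 2 * t) * P1[2] + t * P2[2])
    cbind(dh * cos(az), dh * sin(az), dv)
  },
  arc_length = L, azimuth_rad = az)
}

#' Generate a synthetic plant scene with ground truth
#'
#' Builds a full scene in virtual units: a rough brown ground disc at z ~ 0,
#' `n_leaves` green leaves (point tube of radius `tube_radius_cm` around each
#' midrib plus a wider blade patch near the tip), one or two reference-cube
#' surfaces of known edge, optional uniform outliers, isotropic Gaussian
#' noise, and an optional rigid tilt of the whole scene. Every point carries
#' a truth label.
#'
#' @param spec a [plant_spec()].
#' @param n_cubes number of reference cubes (0-2).
#' @param cube_edge_mm real cube edge (default 56 mm).
#' @param scale_mm_per_unit virtual-unit size: mm of real world per virtual
#'   unit (default 20, i.e. the true scale factor k is 20).
#' @param ground_points,cube_points,n_outliers point budgets.
#' @param tube_radius_cm midrib tube radius.
#' @param scene_tilt_deg rigid rotation of the whole scene about the x axis
#'   (tests ground-plane recovery); 0 keeps the ground at z = 0.
#' @return list with `cloud` (a [point_cloud()] in virtual units) and `truth`
#'   (class `scene_truth`): per-point `labels` (0 = ground, 1..n = leaf,
#'   100+c = cube c, -1 = outlier), `component` strings, the true `plane`,
#'   `cube_edge_virtual`, `k_mm_per_unit`, realised `height_cm`, the per-leaf
#'   truth vectors and the echoed spec.
#' @export
make_plant_scene <- function(spec = plant_spec(), n_cubes = 2,
                             cube_edge_mm = 56, scale_mm_per_unit = 20,
                             ground_points = 6000, cube_points = 1200,
                             n_outliers = 0, tube_radius_cm = 0.2,
                             scene_tilt_deg = 0) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    pts <- list(); labs <- list(); comp <- list(); cols <- list()

    # --- leaves
    midribs <- lapply(seq_len(spec$n_leaves), function(i)
      leaf_midrib(spec$leaf_lengths_cm[i], spec$leaf_elevations_deg[i],
                  spec$leaf_azimuths_deg[i]))
    for (i in seq_len(spec$n_leaves)) {
      mr <- midribs[[i]]
      np <- spec$points_per_leaf
      t <- stats::runif(np)
      P <- mr$point(t)
      Tg <- mr$tangent(t)
      Tg <- Tg / sqrt(rowSums(Tg^2))
      lat <- cbind(-sin(mr$azimuth_rad), cos(mr$azimuth_rad), 0)[rep(1, np), ]
      nor <- cbind(Tg[, 2] * lat[, 3] - Tg[, 3] * lat[, 2],
                   Tg[, 3] * lat[, 1] - Tg[, 1] * lat[, 3],
                   Tg[, 1] * lat[, 2] - Tg[, 2] * lat[, 1])
      blade <- t > 0.55 & t < 0.95
      bump <- ifelse(blade, sin(pi * (t - 0.55) / 0.4), 0)
      halfw <- tube_radius_cm + 0.08 * mr$arc_length * bump
      # tube: uniform disc; blade: uniform in the widened flat cross-section
      phi <- stats::runif(np, 0, 2 * pi)
      rad <- tube_radius_cm * sqrt(stats::runif(np))
      u <- ifelse(blade, stats::runif(np, -1, 1) * halfw, rad * cos(phi))
      v <- ifelse(blade, stats::runif(np, -1, 1) * tube_radius_cm, rad * sin(phi))
      base_off <- spec$crown_radius_cm *
        c(cos(mr$azimuth_rad), sin(mr$azimuth_rad), 0)
      pts[[length(pts) + 1]] <- sweep(P + u * lat + v * nor, 2, base_off, "+")
      labs[[length(labs) + 1]] <- rep(i, np)
      comp[[length(comp) + 1]] <- ifelse(blade, "blade", "tube")
      cols[[length(cols) + 1]] <- cbind(pmax(0, stats::rnorm(np, 60, 15)),
                                        pmax(0, stats::rnorm(np, 150, 25)),
                                        pmax(0, stats::rnorm(np, 55, 12)))
    }
    # one uniform rescale so the noise-free canopy top sits exactly at
    # height_cm; leaf-length truth scales with it
    plant_mat <- do.call(rbind, pts)
    s_h <- spec$height_cm / max(plant_mat[, 3])
    pts <- lapply(pts, function(p) p * s_h)
    plant_mat <- plant_mat * s_h
    leaf_lengths_true <- spec$leaf_lengths_cm * s_h
    height_real <- max(plant_mat[, 3])
    horiz_extent <- max(sqrt(plant_mat[, 1]^2 + plant_mat[, 2]^2))

    # --- ground disc
    Rg <- horiz_extent * 1.3 + 8
    rg <- Rg * sqrt(stats::runif(ground_points))
    ag <- stats::runif(ground_points, 0, 2 * pi)
    pts[[length(pts) + 1]] <- cbind(rg * cos(ag), rg * sin(ag),
                                    stats::rnorm(ground_points, 0, 0.05))
    labs[[length(labs) + 1]] <- rep(0L, ground_points)
    comp[[length(comp) + 1]] <- rep("ground", ground_points)
    cols[[length(cols) + 1]] <- cbind(pmax(0, stats::rnorm(ground_points, 132, 18)),
                                      pmax(0, stats::rnorm(ground_points, 92, 14)),
                                      pmax(0, stats::rnorm(ground_points, 58, 10)))

    # --- reference cubes
    a <- cube_edge_mm / 10                       # cm
    if (n_cubes > 0) for (ci in seq_len(n_cubes)) {
      az <- deg2rad(ifelse(ci == 1, 30, 210) +
                      360 / max(1, spec$n_leaves) / 2)
      ctr <- c((horiz_extent + 6) * cos(az), (horiz_extent + 6) * sin(az), a / 2)
      npf <- max(20L, cube_points %/% 6L)
      fpts <- list()
      for (f in 1:6) {
        uu <- stats::runif(npf, -a / 2, a / 2); vv <- stats::runif(npf, -a / 2, a / 2)
        fixed <- a / 2 * (if (f %% 2 == 0) 1 else -1)
        fp <- switch(((f - 1) %/% 2) + 1,
                     cbind(fixed, uu, vv), cbind(uu, fixed, vv), cbind(uu, vv, fixed))
        fpts[[f]] <- fp
      }
      fp <- sweep(do.call(rbind, fpts), 2, ctr, "+")
      pts[[length(pts) + 1]] <- fp
      labs[[length(labs) + 1]] <- rep(100L + ci, nrow(fp))
      comp[[length(comp) + 1]] <- rep("cube", nrow(fp))
      cols[[length(cols) + 1]] <- matrix(pmax(0, stats::rnorm(3 * nrow(fp), 205, 15)),
                                         ncol = 3)
    }

    P <- do.call(rbind, pts)
    labels <- unlist(labs)
    component <- unlist(comp)
    colors <- do.call(rbind, cols)
    colors[colors > 255] <- 255

    # --- outliers
    if (n_outliers > 0) {
      lo <- apply(P, 2, min); hi <- apply(P, 2, max)
      span <- hi - lo
      O <- sapply(1:3, function(j)
        stats::runif(n_outliers, lo[j] - 0.1 * span[j], hi[j] + 0.1 * span[j]))
      P <- rbind(P, O)
      labels <- c(labels, rep(-1L, n_outliers))
      component <- c(component, rep("outlier", n_outliers))
      colors <- rbind(colors, matrix(stats::runif(3 * n_outliers, 0, 255), ncol = 3))
    }

    # --- coordinate noise, tilt, unit conversion
    if (spec$noise_sigma_cm > 0)
      P <- P + matrix(stats::rnorm(length(P), 0, spec$noise_sigma_cm), ncol = 3)
    plane_normal <- c(0, 0, 1); plane_offset <- 0
    if (scene_tilt_deg != 0) {
      ct <- cos(deg2rad(scene_tilt_deg)); st <- sin(deg2rad(scene_tilt_deg))
      R <- matrix(c(1, 0, 0, 0, ct, st, 0, -st, ct), 3, 3)
      P <- P %*% t(R)
      plane_normal <- as.vector(R %*% c(0, 0, 1))
    }
    cm_per_unit <- scale_mm_per_unit / 10
    P <- P / cm_per_unit

    # dense midrib polylines (virtual units, incl. crown offset + tilt) as
    # the geometric truth for tube/skeleton comparisons
    midrib_polys <- lapply(seq_len(spec$n_leaves), function(i) {
      mp <- midribs[[i]]$point(seq(0, 1, length.out = 200)) * s_h
      mp <- sweep(mp, 2, spec$crown_radius_cm * s_h *
                    c(cos(midribs[[i]]$azimuth_rad),
                      sin(midribs[[i]]$azimuth_rad), 0), "+")
      if (scene_tilt_deg != 0) {
        ct <- cos(deg2rad(scene_tilt_deg)); st <- sin(deg2rad(scene_tilt_deg))
        mp <- mp %*% t(matrix(c(1, 0, 0, 0, ct, st, 0, -st, ct), 3, 3))
      }
      mp / cm_per_unit
    })

    cloud <- point_cloud(P, colors = round(colors))
    truth <- structure(list(labels = labels, component = component,
                            plane = list(normal = plane_normal,
                                         offset = plane_offset),
                            cube_edge_virtual = a / cm_per_unit,
                            k_mm_per_unit = scale_mm_per_unit,
                            height_cm = height_real,
                            leaf_lengths_cm = leaf_lengths_true,
                            leaf_elevations_deg = spec$leaf_elevations_deg,
                            leaf_azimuths_deg = spec$leaf_azimuths_deg,
                            leaf_angles_from_normal_deg = 90 - spec$leaf_elevations_deg,
                            tube_radius_cm = tube_radius_cm * s_h,
                            midribs = midrib_polys,
                            scene_tilt_deg = scene_tilt_deg,
                            spec = spec),
                       class = "scene_truth")
    list(cloud = cloud, truth = truth)
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("scene_truth: %d leaves, realised height %.1f cm, k = %g mm/unit, tilt %g deg\n",
              x$spec$n_leaves, x$height_cm, x$k_mm_per_unit, x$scene_tilt_deg))
  invisible(x)
}

# Rotate coordinates and sample a texture matrix (toroidal indexing).
sample_texture <- function(tex, r, c) {
  nr <- nrow(tex); nc <- ncol(tex)
  bilinear_interp(tex, (r - 1) %% (nr - 1) + 1, (c - 1) %% (nc - 1) + 1)
}

#' Generate a synthetic rotating-plant frame sequence
#'
#' Frames show a textured green rosette-star polygon (the plant) slowly
#' rotating over a static brown textured background, emulating a camera
#' circling a crop. The frames listed in `blur_frame_indices` are replaced by
#' Gaussian-blurred copies, and the truth table records the sharp/blurred
#' status of every frame. Deterministic per seed.
#'
#' @param n_frames number of frames.
#' @param width,height frame size in pixels (desk-scale default 128 x 96).
#' @param blur_frame_indices 1-based indices of frames to blur.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param total_rotation_deg plant rotation across the whole sequence.
#' @param seed integer seed.
#' @return an object of class `frame_sequence`: `frames` (list of H x W x 3
#'   arrays in [0, 1]), `truth` (data.frame index, blurred), and the
#'   generation parameters.
#' @export
make_video <- function(n_frames = 300, width = 128, height = 96,
                       blur_frame_indices = integer(0), blur_sigma = 2.5,
                       total_rotation_deg = 90, seed = 1) {
  if (length(blur_frame_indices) > 0 &&
      (min(blur_frame_indices) < 1 || max(blur_frame_indices) > n_frames))
    stopf("blur_frame_indices out of range")
  with_seed(seed, {
    texP <- gaussian_smooth(matrix(stats::runif(160 * 160), 160, 160), 1.0)
    texP <- (texP - min(texP)) / (max(texP) - min(texP))
    # second plant texture modulating the red/green ratio: the vegetation
    # index sees chromaticity, so saliency structure needs ratio variation
    texQ <- gaussian_smooth(matrix(stats::runif(160 * 160), 160, 160), 1.6)
    texQ <- (texQ - min(texQ)) / (max(texQ) - min(texQ))
    texB <- gaussian_smooth(matrix(stats::runif(height * width), height, width), 1.2)
    texB <- (texB - min(texB)) / (max(texB) - min(texB))

    cy <- (height + 1) / 2; cx <- (width + 1) / 2
    yy <- matrix(seq_len(height), height, width) - cy
    xx <- matrix(seq_len(width), height, width, byrow = TRUE) - cx
    rr <- sqrt(xx^2 + yy^2)
    phi <- atan2(yy, xx)
    R0 <- 0.38 * min(width, height)

    frames <- vector("list", n_frames)
    blurred <- rep(FALSE, n_frames)
    for (f in seq_len(n_frames)) {
      rot <- deg2rad(total_rotation_deg) * (f - 1) / max(1, n_frames - 1)
      mask <- rr <= R0 * (0.6 + 0.4 * abs(cos(3 * (phi - rot))))
      # plant texture rotates rigidly with the plant
      cr <- cos(rot); sr <- sin(rot)
      tr <- yy * cr - xx * sr + 80; tc <- xx * cr + yy * sr + 80
      tp <- matrix(sample_texture(texP, as.vector(tr), as.vector(tc)),
                   height, width)
      tq <- matrix(sample_texture(texQ, as.vector(tr), as.vector(tc)),
                   height, width)
      img <- array(0, c(height, width, 3))
      img[, , 1] <- 0.52 + 0.18 * texB; img[, , 2] <- 0.36 + 0.14 * texB
      img[, , 3] <- 0.22 + 0.10 * texB
      g <- 0.45 + 0.4 * tp
      rfrac <- 0.08 + 0.5 * tq                   # chromaticity structure
      img[, , 1][mask] <- (rfrac * g)[mask]
      img[, , 2][mask] <- g[mask]
      img[, , 3][mask] <- 0.2 * g[mask]
      if (f %in% blur_frame_indices) {
        img <- blur_rgb(img, blur_sigma)
        blurred[f] <- TRUE
      }
      img[img < 0] <- 0; img[img > 1] <- 1
      frames[[f]] <- img
    }
    structure(list(frames = frames,
                   truth = data.frame(index = seq_len(n_frames),
                                      blurred = blurred),
                   width = width, height = height,
                   blur_sigma = blur_sigma, seed = seed),
              class = "frame_sequence")
  })
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frames %dx%d, %d blurred (sigma %.1f), seed %d\n",
              length(x$frames), x$width, x$height, sum(x$truth$blurred),
              x$blur_sigma, x$seed))
  invisible(x)
}

#' Write a frame sequence as PNGs plus a truth sidecar
#'
#' @param video a `frame_sequence`.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_frames <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(video$frames))
    png::writePNG(video$frames[[f]], file.path(dir, sprintf("frame_%06d.png", f)))
  jsonlite::write_json(video$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
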