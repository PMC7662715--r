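# Point-cloud preprocessing: RANSAC ground plane, Z-axis alignment, ground
# removal, voxel simplification and radius outlier filtering.
#
# The SfM/MVS reconstruction itself is out of scope: any external tool that
# maps an ordered image directory to a PLY file can act as the adapter (see
# `reconstruction_adapter()`); this module consumes its output.

# Least-squares plane through a point set: unit normal + offset (n.x + d = 0).
fit_plane_lsq <- function(pts) {
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  list(normal = normal, offset = -sum(normal * ctr))
}

#' Fit the ground plane with RANSAC
#'
#' Random sample consensus: repeatedly fits a plane to 3 random points and
#' keeps the hypothesis with the most points within `distance_threshold`;
#' the winner is refined by a least-squares fit to its inliers. The normal
#' is oriented so that the plant side (the centroid of the non-inlier
#' points) has positive signed distance.
#'
#' @param cloud a [point_cloud()] of the full scene (ground + plant).
#' @param distance_threshold inlier distance in virtual units; `NULL` (auto)
#'   uses 0.005 x the bounding-box diagonal.
#' @param max_iterations number of random minimal samples (default 1000).
#' @param seed integer seed making the fit reproducible.
#' @return an object of class `ground_plane`: unit `normal`, `offset` (d in
#'   n.x + d = 0), `inlier_count`, `inlier_threshold`, `inliers` (indices).
#' @export
fit_ground_plane <- function(cloud, distance_threshold = NULL,
                             max_iterations = 1000, seed = NULL) {
  pts <- cloud$points
  n <- nrow(pts)
  if (n < 3) stopf("need at least 3 points to fit a plane")
  if (is.null(distance_threshold))
    distance_threshold <- 0.005 * bbox_diagonal(cloud)
  if (distance_threshold <= 0) stopf("distance_threshold must be positive")

  best <- NULL; best_count <- -1L
  with_seed(seed, {
    for (it in seq_len(max_iterations)) {
      s <- sample.int(n, 3)
      p1 <- pts[s[1], ]; p2 <- pts[s[2], ]; p3 <- pts[s[3], ]
      nv <- crossprod3(p2 - p1, p3 - p1)
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) next                      # collinear sample
      nv <- nv / nn
      d <- -sum(nv * p1)
      cnt <- sum(abs(pts %*% nv + d) <= distance_threshold)
      if (cnt > best_count) {
        best_count <- cnt
        best <- list(normal = nv, offset = d)
      }
    }
  })
  if (is.null(best)) stopf("RANSAC failed: all samples degenerate (collinear points?)")

  # refine on inliers, then recompute the inlier set
  inl <- which(abs(pts %*% best$normal + best$offset) <= distance_threshold)
  if (length(inl) >= 3) best <- fit_plane_lsq(pts[inl, , drop = FALSE])
  inl <- which(abs(pts %*% best$normal + best$offset) <= distance_threshold)

  normal <- best$normal; offset <- best$offset
  out <- setdiff(seq_len(n), inl)
  ref <- if (length(out) > 0) colMeans(pts[out, , drop = FALSE]) else
    colMeans(pts) + c(0, 0, 1)                  # degenerate: all points planar
  if (sum(normal * ref) + offset < 0) { normal <- -normal; offset <- -offset }

  structure(list(normal = normal, offset = offset,
                 inlier_count = length(inl), inlier_threshold = distance_threshold,
                 inliers = inl),
            class = "ground_plane")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.ground_plane <- function(x, ...) {
  cat(sprintf("ground_plane: normal (%.4f, %.4f, %.4f), offset %.4g\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  cat(sprintf("  %d inliers at threshold %.4g\n", x$inlier_count,
              x$inlier_threshold))
  invisible(x)
}

#' Align a scene so the ground plane becomes z = 0
#'
#' Applies the rigid transform (rotation + translation) that maps the fitted
#' ground normal onto (0, 0, 1) and places the plane at z = 0, defining the
#' Z axis as the direction perpendicular to the ground. Pairwise distances
#' are preserved exactly.
#'
#' @param cloud a [point_cloud()].
#' @param plane a `ground_plane` from [fit_ground_plane()].
#' @return the transformed [point_cloud()].
#' @export
align_to_ground <- function(cloud, plane) {
  R <- rotation_between(plane$normal, c(0, 0, 1))
  pts <- cloud$points %*% t(R)
  p0 <- -plane$offset * plane$normal           # a point on the plane
  z0 <- sum(R[3, ] * p0)
  pts[, 3] <- pts[, 3] - z0
  point_cloud(pts, colors = cloud$colors, labels = cloud$labels)
}

#' Remove the ground from an aligned scene
#'
#' Keeps the points strictly above the ground band: z > margin. The margin
#' defaults to the RANSAC inlier threshold, i.e. the ground's own thickness.
#'
#' @param cloud ground-aligned [point_cloud()].
#' @param plane optional `ground_plane` supplying the default margin.
#' @param margin height below which points are discarded (virtual units).
#' @return the plant [point_cloud()].
#' @export
remove_ground <- function(cloud, plane = NULL, margin = NULL) {
  if (is.null(margin)) {
    if (is.null(plane)) stopf("give either a plane or an explicit margin")
    margin <- plane$inlier_threshold
  }
  keep <- cloud$points[, 3] > margin
  if (!any(keep)) stopf("no plant above ground: every point is within the ground band")
  subset_cloud(cloud, which(keep))
}

# Voxel-grid downsampling at a fixed edge: one centroid per occupied voxel.
voxel_downsample <- function(cloud, edge) {
  pts <- cloud$points
  mins <- apply(pts, 2, min)
  key <- floor(sweep(pts, 2, mins) / edge)
  id <- key[, 1] + 1e6 * key[, 2] + 1e12 * key[, 3]   # collision-free for sane grids
  grp <- match(id, unique(id))
  xs <- rowsum(pts, grp); cnt <- as.vector(rowsum(rep(1, nrow(pts)), grp))
  out <- xs / cnt
  cols <- if (!is.null(cloud$colors))
    matrix(as.integer(round(rowsum(cloud$colors + 0, grp) / cnt)), ncol = 3)
  labs <- if (!is.null(cloud$labels)) {
    # majority label per voxel
    as.integer(tapply(cloud$labels, grp, function(v)
      as.integer(names(sort(table(v), decreasing = TRUE))[1])))
  }
  point_cloud(out, colors = cols, labels = labs)
}

#' Simplify a cloud to a target point-count range
#'
#' Voxel-grid downsampling (one centroid per occupied voxel) with the voxel
#' edge binary-searched so that the output size lands inside
#' `target_count_range` (default 10,000-30,000 points, the density at which
#' skeletonisation is accurate but cheap). Clouds already at or below the
#' upper bound are returned unchanged.
#'
#' @param cloud a [point_cloud()].
#' @param target_count_range length-2 integer vector (lower, upper).
#' @param max_iter bisection iterations.
#' @return the simplified [point_cloud()].
#' @export
simplify_cloud <- function(cloud, target_count_range = c(10000, 30000),
                           max_iter = 40) {
  lo_t <- target_count_range[1]; hi_t <- target_count_range[2]
  n <- n_points(cloud)
  if (n == 0) stopf("empty cloud")
  if (n <= hi_t) return(cloud)
  diag <- bbox_diagonal(cloud)
  e_lo <- diag * 1e-6                            # ~ no reduction
  e_hi <- diag                                   # collapses to a handful
  best <- NULL
  for (it in seq_len(max_iter)) {
    e <- sqrt(e_lo * e_hi)
    ds <- voxel_downsample(cloud, e)
    m <- n_points(ds)
    if (m >= lo_t && m <= hi_t) return(ds)
    if (is.null(best) || abs(log(m / sqrt(lo_t * hi_t))) <
        abs(log(n_points(best) / sqrt(lo_t * hi_t)))) best <- ds
    if (m > hi_t) e_lo <- e else e_hi <- e
  }
  warning(sprintf("voxel search could not reach [%d, %d] points; returning %d",
                  lo_t, hi_t, n_points(best)), call. = FALSE)
  best
}

# Neighbour counts within `radius` (excluding self). Brute force for small N,
# uniform-grid cell lists for large N; both give exact counts.
radius_neighbor_counts <- function(pts, radius) {
  n <- nrow(pts)
  if (n <= 2000) {
    d <- as.matrix(stats::dist(pts))
    return(as.integer(rowSums(d <= radius) - 1L))
  }
  mins <- apply(pts, 2, min)
  key <- floor(sweep(pts, 2, mins) / radius)
  id <- paste(key[, 1], key[, 2], key[, 3])
  cells <- split(seq_len(n), id)
  cell_of_key <- function(k) paste(k[1], k[2], k[3])
  counts <- integer(n)
  keymat <- key
  for (cell_id in names(cells)) {
    members <- cells[[cell_id]]
    k0 <- keymat[members[1], ]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      nb <- cells[[cell_of_key(k0 + c(dx, dy, dz))]]
      if (!is.null(nb)) cand <- c(cand, nb)
    }
    A <- pts[members, , drop = FALSE]; B <- pts[cand, , drop = FALSE]
    d2 <- matrix(rowSums(A^2), length(members), length(cand)) +
      matrix(rowSums(B^2), length(members), length(cand), byrow = TRUE) -
      2 * A %*% t(B)
    counts[members] <- as.integer(rowSums(d2 <= radius^2 + 1e-12) - 1L)
  }
  counts
}

# Median nearest-neighbour distance, estimated on a subsample for large N.
median_nn_distance <- function(pts, max_sample = 1500, seed = 1) {
  n <- nrow(pts)
  idx <- if (n > max_sample) with_seed(seed, sample.int(n, max_sample)) else seq_len(n)
  sub <- pts[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(sub))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

#' Radius outlier filter
#'
#' Keeps exactly the points that have at least `min_neighbors` other points
#' within `radius`: isolated reconstruction noise loses its support and is
#' dropped, dense plant surfaces are retained. Single pass (removals do not
#' cascade).
#'
#' @param cloud a [point_cloud()].
#' @param radius neighbourhood radius; `NULL` (auto) uses 4 x the median
#'   nearest-neighbour distance.
#' @param min_neighbors minimum neighbour count (default 5).
#' @return the filtered [point_cloud()].
#' @export
radius_outlier_filter <- function(cloud, radius = NULL, min_neighbors = 5) {
  if (min_neighbors < 1) stopf("min_neighbors must be >= 1")
  pts <- cloud$points
  if (nrow(pts) == 0) return(cloud)
  if (is.null(radius)) radius <- 4 * median_nn_distance(pts)
  if (radius <= 0) stopf("radius must be positive")
  counts <- radius_neighbor_counts(pts, radius)
  keep <- which(counts >= min_neighbors)
  if (length(keep) == 0) stopf("radius filter removed every point; radius too small?")
  subset_cloud(cloud, keep)
}

#' Tilt of the plant's principal direction over the ground
#'
#' PCA of the centered coordinates; the angle between the first principal
#' component and the ground plane (90 deg minus its angle to the Z axis),
#' folded into [0, 90]. Used to correct plant height when the plant grows at
#' an angle to the ground: H = |zmax - zmin| / sin(theta).
#'
#' @param cloud ground-removed plant [point_cloud()], N >= 3.
#' @return the tilt angle theta in degrees.
#' @export
principal_axis_tilt <- function(cloud) {
  pts <- cloud$points
  if (nrow(pts) < 3) stopf("need at least 3 points")
  cen <- sweep(pts, 2, colMeans(pts))
  if (max(abs(cen)) < 1e-12) stopf("degenerate cloud: all points identical")
  v <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)$vectors[, 1]
  rad2deg(asin(min(1, abs(v[3]) / sqrt(sum(v^2)))))
}

#' Isolate the plant as the largest connected component
#'
#' After ground removal the scene may still hold detached objects (reference
#' cubes, debris). Points are binned into voxels and the connected component
#' of occupied voxels (26-connectivity) holding the most points is kept: the
#' automated stand-in for interactive scene cleanup. An explicit exclusion
#' index list is also honoured.
#'
#' @param cloud ground-removed [point_cloud()].
#' @param voxel connectivity voxel edge; `NULL` (auto) uses 2% of the
#'   bounding-box diagonal.
#' @param exclude optional integer point indices to drop beforehand.
#' @return the plant [point_cloud()].
#' @export
select_plant_component <- function(cloud, voxel = NULL, exclude = NULL) {
  if (!is.null(exclude) && length(exclude) > 0)
    cloud <- subset_cloud(cloud, setdiff(seq_len(n_points(cloud)), exclude))
  n <- n_points(cloud)
  if (n == 0) stopf("empty cloud")
  if (is.null(voxel)) voxel <- 0.02 * bbox_diagonal(cloud)
  if (voxel <= 0) return(cloud)
  key <- floor(sweep(cloud$points, 2, apply(cloud$points, 2, min)) / voxel)
  id <- paste(key[, 1], key[, 2], key[, 3])
  uid <- unique(id)
  vox <- match(id, uid)
  km <- key[!duplicated(id), , drop = FALSE]
  lookup <- new.env(parent = emptyenv(), size = length(uid))
  for (i in seq_along(uid)) assign(uid[i], i, envir = lookup)
  # union of occupied voxels via BFS over the 26-neighbourhood
  comp <- integer(length(uid)); cur <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (s in seq_along(uid)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      nb_keys <- sweep(offs, 2, as.numeric(km[v, ]), "+")
      nb_ids <- paste(nb_keys[, 1], nb_keys[, 2], nb_keys[, 3])
      for (nid in nb_ids) {
        j <- lookup[[nid]]
        if (!is.null(j) && comp[j] == 0L) { comp[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  pt_comp <- comp[vox]
  main <- which.max(tabulate(pt_comp))
  subset_cloud(cloud, which(pt_comp == main))
}

#' Reconstruction adapter contract (stub)
#'
#' The dense reconstruction step (SfM + multi-view stereo) is performed by
#' external software; this package consumes its PLY output. The adapter is
#' any function or command mapping an ordered key-frame image directory to a
#' PLY path. Published settings that work well for single plants: alignment
#' accuracy "high", feature-point cap 40,000, tie-point cap 10,000, dense
#' quality "high" with a slight depth filter. This stub only validates that
#' an externally produced PLY exists and loads it.
#'
#' @param image_dir directory of selected key frames (unused by the stub).
#' @param ply_path path to the externally reconstructed PLY.
#' @return the scene [point_cloud()].
#' @export
reconstruction_adapter <- function(image_dir, ply_path) {
  if (!file.exists(ply_path))
    stopf(paste("reconstruction adapter required: no point cloud at '%s';",
                "run your SfM/MVS tool on the key frames first"), ply_path)
  read_ply(ply_path)
}
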