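# Skeleton extraction by Z-slice clustering: slice -> per-slice Euclidean
# clustering -> inter-layer linking -> number-threshold pruning -> cubic
# B-spline smoothing -> seeded segmentation of the full cloud.

#' Slice a ground-aligned cloud along Z
#'
#' Layer j (0-based) holds the points with z in [j*dh, (j+1)*dh), a half-open
#' convention: a point exactly at a slice boundary belongs to the upper
#' layer. Points below z = 0 (ground residue) are not sliced.
#'
#' @param cloud ground-aligned [point_cloud()].
#' @param dh slice height in virtual units (> 0).
#' @return list of integer vectors of point indices, one per layer from z = 0
#'   upward (possibly empty layers in between).
#' @export
slice_cloud <- function(cloud, dh) {
  if (dh <= 0) stopf("dh must be positive")
  z <- cloud$points[, 3]
  ok <- which(z >= 0)
  if (length(ok) == 0) return(list())
  lay <- floor(z[ok] / dh)
  n_layers <- max(lay) + 1L
  out <- vector("list", n_layers)
  grp <- split(ok, lay)
  for (nm in names(grp)) out[[as.integer(nm) + 1L]] <- grp[[nm]]
  for (j in seq_len(n_layers)) if (is.null(out[[j]])) out[[j]] <- integer(0)
  out
}

#' Cluster the points of one slice
#'
#' Single-linkage Euclidean clustering: two points are connected when within
#' `eps`; clusters are the connected components, each summarised by the
#' arithmetic-mean centroid (the candidate skeleton node for that slice).
#'
#' @param points k x 3 coordinate matrix of one layer.
#' @param eps connection distance (> 0).
#' @param indices optional original point indices carried through (defaults
#'   to 1..k).
#' @return list of clusters, each `list(indices, centroid)`.
#' @export
cluster_layer <- function(points, eps, indices = NULL) {
  if (eps <= 0) stopf("eps must be positive")
  points <- as.matrix(points)
  k <- nrow(points)
  if (is.null(indices)) indices <- seq_len(k)
  if (k == 0) return(list())
  if (k == 1) return(list(list(indices = indices, centroid = points[1, ])))
  memb <- stats::cutree(stats::hclust(stats::dist(points), method = "single"),
                        h = eps)
  lapply(unique(memb), function(g) {
    sel <- memb == g
    list(indices = indices[sel],
         centroid = colMeans(points[sel, , drop = FALSE]))
  })
}

#' Link per-layer clusters into a raw skeleton
#'
#' Each cluster in layer j+1 links to the nearest cluster centroid of layer j
#' when the centroid distance is at most `link_dist`; unlinked clusters start
#' new branches. A cluster receiving two or more children becomes a junction:
#' the child most collinear with the incoming branch direction continues that
#' branch, the others start their own branches at the junction. Branches are
#' returned ordered base to tip (strictly increasing layers).
#'
#' @param layer_clusters list over layers of cluster lists as produced by
#'   [cluster_layer()] (with global `indices`).
#' @param link_dist maximum inter-layer linking distance.
#' @param dh slice height, stored on the result.
#' @return an object of class `plant_skeleton` (un-pruned, no splines).
#' @export
link_layers <- function(layer_clusters, link_dist, dh = NA_real_) {
  nonempty <- which(vapply(layer_clusters, length, 1L) > 0)
  if (length(nonempty) == 0) stopf("no non-empty layers")

  pos <- list(); layer <- integer(0); members <- list(); parent <- integer(0)
  prev_ids <- integer(0)
  for (j in seq_along(layer_clusters)) {
    cl <- layer_clusters[[j]]
    cur_ids <- integer(0)
    for (c_ in cl) {
      id <- length(pos) + 1L
      pos[[id]] <- c_$centroid
      layer[id] <- j
      members[[id]] <- c_$indices
      parent[id] <- NA_integer_
      if (length(prev_ids) > 0) {
        pp <- do.call(rbind, pos[prev_ids])
        d <- sqrt(colSums((t(pp) - c_$centroid)^2))
        b <- which.min(d)
        if (d[b] <= link_dist) parent[id] <- prev_ids[b]
      }
      cur_ids <- c(cur_ids, id)
    }
    prev_ids <- cur_ids
  }

  nnode <- length(pos)
  posm <- do.call(rbind, pos)
  children <- vector("list", nnode)
  for (id in seq_len(nnode)) if (!is.na(parent[id]))
    children[[parent[id]]] <- c(children[[parent[id]]], id)

  # at junctions, the most collinear child inherits the parent's chain
  continuing <- rep(NA_integer_, nnode)
  for (id in seq_len(nnode)) {
    ch <- children[[id]]
    if (length(ch) == 0) next
    if (length(ch) == 1) { continuing[id] <- ch; next }
    dir_in <- if (!is.na(parent[id])) posm[id, ] - posm[parent[id], ] else c(0, 0, 1)
    nin <- sqrt(sum(dir_in^2)); if (nin > 0) dir_in <- dir_in / nin
    sc <- vapply(ch, function(c2) {
      v <- posm[c2, ] - posm[id, ]
      nv <- sqrt(sum(v^2)); if (nv == 0) return(-1)
      sum(v * dir_in) / nv
    }, numeric(1))
    continuing[id] <- ch[which.max(sc)]
  }

  is_start <- vapply(seq_len(nnode), function(id) {
    if (is.na(parent[id])) return(TRUE)
    continuing[parent[id]] != id
  }, logical(1))

  branches <- list()
  for (s in which(is_start)) {
    chain <- s
    cur <- s
    while (!is.na(continuing[cur])) { cur <- continuing[cur]; chain <- c(chain, cur) }
    branches[[length(branches) + 1]] <- list(
      positions = posm[chain, , drop = FALSE],
      layers = layer[chain],
      members = members[chain],
      spline = NULL,
      label = length(branches) + 1L)
  }
  structure(list(branches = branches, dh = dh, params = list(link_dist = link_dist)),
            class = "plant_skeleton")
}

#' Prune short skeleton branches
#'
#' Clustering artefacts surface as branches with very few nodes; branches
#' with fewer than `min_nodes` nodes are removed and their member points
#' become unassigned.
#'
#' @param skeleton a `plant_skeleton`.
#' @param min_nodes minimum node count to survive (default 3).
#' @return the pruned `plant_skeleton` (labels renumbered 1..B).
#' @export
prune_branches <- function(skeleton, min_nodes = 3) {
  if (min_nodes < 1) stopf("min_nodes must be >= 1")
  keep <- vapply(skeleton$branches, function(b) nrow(b$positions) >= min_nodes,
                 logical(1))
  if (!any(keep)) stopf("all branches pruned (min_nodes = %d)", min_nodes)
  skeleton$branches <- skeleton$branches[keep]
  for (i in seq_along(skeleton$branches)) skeleton$branches[[i]]$label <- i
  skeleton$params$min_nodes <- min_nodes
  skeleton
}

# Least-squares cubic B-spline through node positions, chord-length
# parameterised. Returns NULL for degenerate inputs.
fit_branch_spline <- function(positions) {
  n <- nrow(positions)
  if (n < 4) return(NULL)
  seg <- sqrt(rowSums(diff(positions)^2))
  t <- c(0, cumsum(seg))
  if (t[n] == 0) return(NULL)
  t <- t / t[n]
  df <- max(4, min(n - 1, ceiling(n / 3) + 2))
  basis <- splines::bs(t, df = df, degree = 3, intercept = TRUE)
  coef <- qr.coef(qr(basis), positions)
  coef[is.na(coef)] <- 0
  list(basis = basis, coef = coef, t = t)
}

eval_branch_spline <- function(spline, tnew) {
  B <- stats::predict(spline$basis, pmin(pmax(tnew, 0), 1))
  B %*% spline$coef
}

#' Smooth skeleton branches with cubic B-splines
#'
#' Fits a least-squares cubic B-spline per branch (chord-length
#' parameterised) so that the skeleton becomes a continuous smooth curve and
#' node jitter is averaged out. Branches with fewer than 4 nodes keep their
#' polyline.
#'
#' @param skeleton a `plant_skeleton`.
#' @return the skeleton with `spline` filled in per branch.
#' @export
smooth_branches <- function(skeleton) {
  skeleton$branches <- lapply(skeleton$branches, function(b) {
    b$spline <- fit_branch_spline(b$positions)
    b
  })
  skeleton
}

# Resample one branch at ~`step` spacing along its (spline or polyline) arc.
# Returns a matrix of points, base first.
resample_branch <- function(branch, step) {
  pts <- if (!is.null(branch$spline)) {
    nd <- max(50L, 8L * nrow(branch$positions))
    eval_branch_spline(branch$spline, seq(0, 1, length.out = nd))
  } else branch$positions
  if (nrow(pts) == 1) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L == 0) return(pts[1, , drop = FALSE])
  svals <- unique(c(seq(0, L, by = step), L))
  apply(pts, 2, function(col) stats::approx(s, col, xout = svals, ties = "ordered")$y)
}

# Arc length of a branch (spline if fitted, else node polyline).
branch_arc_length <- function(branch, use_spline = TRUE, step = NULL) {
  if (use_spline && !is.null(branch$spline)) {
    pts <- eval_branch_spline(branch$spline,
                              seq(0, 1, length.out = max(200L, 10L * nrow(branch$positions))))
  } else pts <- branch$positions
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Segment the cloud by skeleton seeds
#'
#' Up-samples each branch curve at `sample_step` spacing and assigns every
#' cloud point the branch label of its nearest resampled skeleton point; the
#' per-node point sets are thereby merged into per-branch segments that
#' partition the cloud.
#'
#' @param cloud the plant [point_cloud()].
#' @param skeleton a pruned (ideally smoothed) `plant_skeleton`.
#' @param sample_step resampling step; default `dh / 2`.
#' @return the cloud with `labels` set to branch labels.
#' @export
segment_cloud <- function(cloud, skeleton, sample_step = NULL) {
  if (length(skeleton$branches) == 0) stopf("empty skeleton")
  if (is.null(sample_step)) {
    if (is.na(skeleton$dh)) stopf("sample_step required when skeleton has no dh")
    sample_step <- skeleton$dh / 2
  }
  if (sample_step <= 0) stopf("sample_step must be positive")
  seeds <- list(); seed_lab <- integer(0)
  for (b in skeleton$branches) {
    rs <- resample_branch(b, sample_step)
    seeds[[length(seeds) + 1]] <- rs
    seed_lab <- c(seed_lab, rep(b$label, nrow(rs)))
  }
  S <- do.call(rbind, seeds)
  pts <- cloud$points
  n <- nrow(pts)
  labs <- integer(n)
  ss <- rowSums(S^2)
  chunk <- 4000L
  for (from in seq(1, n, by = chunk)) {
    to <- min(from + chunk - 1L, n)
    P <- pts[from:to, , drop = FALSE]
    d2 <- matrix(rowSums(P^2), to - from + 1L, nrow(S)) +
      matrix(ss, to - from + 1L, nrow(S), byrow = TRUE) - 2 * P %*% t(S)
    labs[from:to] <- seed_lab[max.col(-d2, ties.method = "first")]
  }
  cloud$labels <- labs
  cloud
}

#' Extract a pruned, smoothed skeleton from a plant cloud
#'
#' Convenience composition of [slice_cloud()], [cluster_layer()],
#' [link_layers()], [prune_branches()] and [smooth_branches()] with the
#' package defaults: `dh` = height/50 (clamped so a slice averages at least
#' 20 points), in-slice `eps` = 3 x median nearest-neighbour distance,
#' `link_dist` = 2 dh.
#'
#' @param cloud ground-aligned, ground-removed plant [point_cloud()].
#' @param dh slice height; `NULL` for the default above.
#' @param eps in-slice clustering distance; `NULL` (default) uses
#'   `max(3 x median NN distance, 1.5 dh)` - the NN term tracks point
#'   density while the dh floor keeps a slice-wide blade strip connected
#'   when sparse sampling opens random gaps wider than a few NN spacings.
#' @param link_dist inter-layer linking distance; `NULL` for 3 dh (a chain
#'   climbing at elevation e steps dh/tan(e) horizontally per layer, so the
#'   limit must cover drooping blades down to ~20 degrees plus centroid
#'   jitter).
#' @param min_nodes pruning threshold; `NULL` (default) adapts to the slicing
#'   resolution as `max(3, ceiling(0.12 x layer count))` - at the default ~50
#'   slices per plant, clustering artefacts persist for a handful of layers
#'   while true leaves span tens, so the threshold scales with resolution.
#' @param smooth fit B-splines after pruning (default TRUE).
#' @return a `plant_skeleton`.
#' @export
extract_skeleton <- function(cloud, dh = NULL, eps = NULL, link_dist = NULL,
                             min_nodes = NULL, smooth = TRUE) {
  z <- cloud$points[, 3]
  if (n_points(cloud) == 0) stopf("empty cloud")
  span <- max(z) - min(0, min(z))
  if (is.null(dh)) {
    dh <- span / 50
    dh <- max(dh, span * 20 / n_points(cloud))   # keep >= 20 points per slice
    # relative pad so the top point sits strictly inside the last slice
    # rather than exactly on its boundary (where fp rounding is unstable)
    dh <- dh * (1 + 1e-9)
  }
  if (is.null(eps)) eps <- max(3 * median_nn_distance(cloud$points), 1.5 * dh)
  if (is.null(link_dist)) link_dist <- 3 * dh
  layers <- slice_cloud(cloud, dh)
  if (is.null(min_nodes)) min_nodes <- max(3, ceiling(0.12 * length(layers)))
  cl <- lapply(layers, function(idx)
    cluster_layer(cloud$points[idx, , drop = FALSE], eps, indices = idx))
  sk <- link_layers(cl, link_dist, dh = dh)
  sk$params <- utils::modifyList(sk$params, list(dh = dh, eps = eps))
  sk <- prune_branches(sk, min_nodes)
  if (smooth) sk <- smooth_branches(sk)
  sk
}

#' @export
print.plant_skeleton <- function(x, ...) {
  nb <- length(x$branches)
  nn <- vapply(x$branches, function(b) nrow(b$positions), 1L)
  cat(sprintf("plant_skeleton: %d branch%s, %d nodes (dh = %.4g)\n",
              nb, if (nb == 1) "" else "es", sum(nn), x$dh))
  cat("  nodes per branch:", paste(nn, collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.plant_skeleton <- function(x, which = "xz", cloud = NULL, ...) {
  ax <- strsplit(which, "")[[1]]
  cols <- c("x" = 1, "y" = 2, "z" = 3)
  all_pos <- do.call(rbind, lapply(x$branches, `[[`, "positions"))
  graphics::plot(all_pos[, cols[ax[1]]], all_pos[, cols[ax[2]]], type = "n",
                 xlab = ax[1], ylab = ax[2], asp = 1, ...)
  if (!is.null(cloud))
    graphics::points(cloud$points[, cols[ax[1]]], cloud$points[, cols[ax[2]]],
                     col = "grey80", pch = 16, cex = 0.15)
  for (b in x$branches) {
    rs <- resample_branch(b, if (is.na(x$dh)) branch_arc_length(b) / 50 else x$dh / 2)
    graphics::lines(rs[, cols[ax[1]]], rs[, cols[ax[2]]], col = b$label + 1, lwd = 2)
    graphics::points(b$positions[, cols[ax[1]]], b$positions[, cols[ax[2]]],
                     pch = 16, cex = 0.5, col = b$label + 1)
  }
  invisible(x)
}

#' Serialise a skeleton to JSON
#'
#' Branches are written as node coordinate lists with layers, member point
#' indices and (when fitted) the B-spline parameters, so the skeleton
#' round-trips losslessly through [read_skeleton_json()].
#'
#' @param skeleton a `plant_skeleton`.
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
write_skeleton_json <- function(skeleton, path) {
  br <- lapply(skeleton$branches, function(b) {
    sp <- if (!is.null(b$spline))
      list(knots = attr(b$spline$basis, "knots"),
           boundary = attr(b$spline$basis, "Boundary.knots"),
           degree = attr(b$spline$basis, "degree"),
           coef = b$spline$coef, t = b$spline$t)
    list(label = b$label, positions = b$positions, layers = b$layers,
         members = b$members, spline = sp)
  })
  jsonlite::write_json(list(dh = skeleton$dh, params = skeleton$params,
                            branches = br),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a skeleton written by [write_skeleton_json()]
#'
#' @param path JSON file.
#' @return a `plant_skeleton`.
#' @export
read_skeleton_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  branches <- lapply(seq_len(length(j$branches$label)), function(i) {
    pos <- matrix(unlist(j$branches$positions[[i]]),
                  ncol = 3,
                  dimnames = NULL)
    b <- list(positions = pos,
              layers = as.integer(j$branches$layers[[i]]),
              members = lapply(j$branches$members[[i]], as.integer),
              spline = NULL,
              label = as.integer(j$branches$label[[i]]))
    b$spline <- fit_branch_spline(b$positions)
    b
  })
  structure(list(branches = branches, dh = j$dh, params = as.list(j$params)),
            class = "plant_skeleton")
}

#' Export skeleton polylines as a Wavefront OBJ for visual inspection
#'
#' @param skeleton a `plant_skeleton`.
#' @param path output OBJ file.
#' @return invisibly, `path`.
#' @export
write_skeleton_obj <- function(skeleton, path) {
  lines <- character(0)
  offset <- 0L
  for (b in skeleton$branches) {
    p <- b$positions
    lines <- c(lines, sprintf("v %.8g %.8g %.8g", p[, 1], p[, 2], p[, 3]))
    idx <- offset + seq_len(nrow(p))
    lines <- c(lines, paste("l", paste(idx, collapse = " ")))
    offset <- offset + nrow(p)
  }
  writeLines(lines, path)
  invisible(path)
}
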