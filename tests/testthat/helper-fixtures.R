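# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no binary fixtures.

# Structured single-channel test image: a field of Gaussian blobs on zero
# background; enough texture for keypoint detection.
blob_image <- function(nr = 96, nc = 128, n_blobs = 25, seed = 11) {
  set.seed(seed)
  img <- matrix(0, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(n_blobs)) {
    r0 <- runif(1, 15, nr - 15); c0 <- runif(1, 15, nc - 15)
    s <- runif(1, 2, 5); a <- runif(1, 0.5, 1)
    img <- img + a * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * s^2))
  }
  img
}

# Random RGB frame (values in [0, 1]).
random_rgb <- function(nr = 20, nc = 24, seed = 5) {
  set.seed(seed)
  array(runif(nr * nc * 3), c(nr, nc, 3))
}

# Independent oracle: explicit pixel-by-pixel convolution of the 3x3
# 4-neighbour Laplacian with replicate padding.
laplacian_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  at <- function(r, c) m[min(max(r, 1), nr), min(max(c, 1), nc)]
  for (r in seq_len(nr)) for (c in seq_len(nc))
    out[r, c] <- at(r - 1, c) + at(r + 1, c) + at(r, c - 1) + at(r, c + 1) -
      4 * at(r, c)
  out
}

# Independent oracle: per-point O(N^2) radius neighbour counting.
neighbor_count_oracle <- function(pts, radius) {
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- rowSums((pts - matrix(pts[i, ], nrow(pts), 3, byrow = TRUE))^2)
    sum(d2 <= radius^2) - 1L
  }, integer(1))
}

# Independent oracle: single-linkage connected components by BFS over the
# eps-neighbourhood graph.
components_oracle <- function(pts, eps) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts)) <= eps
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(d[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Small ground + plant-blob scene with exact labels.
blob_scene <- function(n_ground = 1000, n_plant = 200, seed = 3,
                       ground_noise = 0) {
  set.seed(seed)
  g <- cbind(runif(n_ground, -5, 5), runif(n_ground, -5, 5),
             if (ground_noise > 0) rnorm(n_ground, 0, ground_noise) else rep(0, n_ground))
  p <- cbind(runif(n_plant, -1, 1), runif(n_plant, -1, 1), runif(n_plant, 1, 5))
  list(cloud = point_cloud(rbind(g, p)),
       ground_idx = seq_len(n_ground),
       plant_idx = n_ground + seq_len(n_plant))
}

# Vertical column of stacked point rings (one obvious branch per column).
column_cloud <- function(centers, n_layers = 12, pts_per_layer = 30,
                         dz = 0.5, radius = 0.1, seed = 2) {
  set.seed(seed)
  out <- list(); lab <- list()
  for (ci in seq_along(centers)) {
    for (l in seq_len(n_layers)) {
      a <- runif(pts_per_layer, 0, 2 * pi)
      r <- radius * sqrt(runif(pts_per_layer))
      out[[length(out) + 1]] <- cbind(centers[[ci]][1] + r * cos(a),
                                      centers[[ci]][2] + r * sin(a),
                                      (l - 0.5) * dz)
      lab[[length(lab) + 1]] <- rep(ci, pts_per_layer)
    }
  }
  list(cloud = point_cloud(do.call(rbind, out)), labels = unlist(lab))
}
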