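# Scale/rotation-invariant local features for saliency-map matching.
#
# A compact SIFT-style detector implemented on plain matrices: keypoints are
# extrema of a single-octave difference-of-Gaussians stack, each keypoint is
# assigned a dominant gradient orientation, and described by the classic
# 4 x 4 spatial grid of 8-bin gradient-orientation histograms (128-D),
# computed on a grid rotated into the keypoint frame (so descriptors are
# rotation invariant) and scaled with the detection scale (scale invariant
# within the octave). Matching is nearest-neighbour with Lowe's ratio test
# plus a mutual-nearest-neighbour cross check.

# Bilinear interpolation of matrix m at fractional (row, col) positions,
# coordinates clamped to the valid domain. r, c: equal-length numerics.
bilinear_interp <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v00 <- m[i00];        v10 <- m[i00 + 1]
  v01 <- m[i00 + nr];   v11 <- m[i00 + nr + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Row-wise accumulation of weights `w` (n x s matrix) into `nbin` bins given
# per-entry bin indices `bin` (n x s, values 0..nbin-1). Returns n x nbin.
accumulate_bins <- function(w, bin, nbin) {
  n <- nrow(w)
  lin <- as.vector(bin) * n + rep(seq_len(n), times = ncol(bin))
  out <- numeric(n * nbin)
  s <- rowsum(as.vector(w), group = lin)
  out[as.integer(rownames(s))] <- s
  matrix(out, n, nbin)
}

#' Detect scale/rotation-invariant keypoints and descriptors
#'
#' Difference-of-Gaussians keypoint detection with orientation-normalised
#' 128-D gradient descriptors, suitable for matching crop saliency maps
#' between video frames.
#'
#' @param map single-channel matrix (e.g. a [saliency_map()]); values on any
#'   non-negative scale.
#' @param n_keypoints keep at most this many strongest keypoints.
#' @param peak_thresh minimum absolute difference-of-Gaussians response, as a
#'   fraction of the map's dynamic range.
#' @param base_sigma smallest pyramid smoothing scale in pixels.
#' @return list with `keypoints` (data.frame: row, col, sigma, angle,
#'   strength) and `descriptors` (matrix, one L2-normalised row per keypoint).
#' @export
sift_features <- function(map, n_keypoints = 150, peak_thresh = 0.02,
                          base_sigma = 1.4) {
  if (length(map) == 0) stopf("empty map")
  m <- map
  rng <- max(m) - min(m)
  if (rng > 0) m <- (m - min(m)) / rng
  nsc <- 6L
  sig <- base_sigma * 2^((0:(nsc - 1)) / 3)
  G <- lapply(sig, function(s) gaussian_smooth(m, s))
  D <- lapply(seq_len(nsc - 1), function(k) G[[k + 1]] - G[[k]])

  kp <- list()
  nr <- nrow(m); nc <- ncol(m)
  for (l in 2:(nsc - 2)) {
    d <- D[[l]]
    # threshold first, then verify only the candidates against their 26
    # scale-space neighbours (a 2 px frame is excluded: replicate padding
    # makes border extrema unreliable)
    cand <- which(abs(d) > peak_thresh)
    if (length(cand) == 0) next
    cr <- (cand - 1L) %% nr + 1L; cc <- (cand - 1L) %/% nr + 1L
    keep <- cr > 2L & cr < nr - 1L & cc > 2L & cc < nc - 1L
    cand <- cand[keep]
    if (length(cand) == 0) next
    v <- d[cand]
    ok_max <- v > peak_thresh; ok_min <- v < -peak_thresh
    for (dd in -1:1) {
      layer <- D[[l + dd]]
      for (dr in -1:1) for (dc in -1:1) {
        if (dd == 0 && dr == 0 && dc == 0) next
        nb <- layer[cand + dr + dc * nr]
        ok_max <- ok_max & v >= nb
        ok_min <- ok_min & v <= nb
      }
      if (!any(ok_max | ok_min)) break
    }
    ext <- ok_max | ok_min
    if (!any(ext)) next
    kp[[length(kp) + 1]] <- data.frame(row = (cand[ext] - 1L) %% nr + 1L,
                                       col = (cand[ext] - 1L) %/% nr + 1L,
                                       layer = l, strength = abs(v[ext]))
  }
  if (length(kp) == 0)
    return(list(keypoints = data.frame(row = numeric(0), col = numeric(0),
                                       sigma = numeric(0), angle = numeric(0),
                                       strength = numeric(0)),
                descriptors = matrix(0, 0, 128)))
  kp <- do.call(rbind, kp)
  kp <- kp[order(-kp$strength), , drop = FALSE]
  if (nrow(kp) > n_keypoints) kp <- kp[seq_len(n_keypoints), , drop = FALSE]

  # gradients of the smoothed images actually referenced by keypoints
  layers <- sort(unique(kp$layer))
  grad <- list()
  for (l in layers) {
    g <- G[[l]]
    grad[[as.character(l)]] <- list(
      gx = (shift_mat(g, 0, -1) - shift_mat(g, 0, 1)) / 2,
      gy = (shift_mat(g, -1, 0) - shift_mat(g, 1, 0)) / 2)
  }

  kp$angle <- 0
  desc <- matrix(0, nrow(kp), 128)

  # fixed descriptor sample grid (18 x 18 so gradients can be taken on-grid)
  gi <- seq(-8.5, 8.5, by = 1)
  grid <- expand.grid(i = gi, j = gi)          # i: descriptor x, j: descriptor y
  ii <- matrix(seq_len(18), 18, 18)            # linear layout helpers
  interior <- as.vector(ii[2:17, 2:17] + 18 * (t(ii)[2:17, 2:17] - 1))
  int_i <- grid$i[interior]; int_j <- grid$j[interior]
  gw <- exp(-(int_i^2 + int_j^2) / (2 * 6^2))
  cell <- (floor((int_j + 8) / 4)) * 4 + floor((int_i + 8) / 4)  # 0..15

  for (l in layers) {
    sel <- which(kp$layer == l)
    if (length(sel) == 0) next
    s_kp <- sig[l]
    gx <- grad[[as.character(l)]]$gx
    gy <- grad[[as.character(l)]]$gy
    K <- length(sel)
    r0 <- kp$row[sel]; c0 <- kp$col[sel]

    # --- dominant orientation: gradient histogram in a circular window
    rr <- max(2L, as.integer(round(3 * s_kp)))
    off <- expand.grid(dr = -rr:rr, dc = -rr:rr)
    keep <- off$dr^2 + off$dc^2 <= rr^2
    off <- off[keep, ]
    S <- nrow(off)
    Rw <- outer(r0, off$dr, "+"); Cw <- outer(c0, off$dc, "+")
    vx <- matrix(bilinear_interp(gx, as.vector(Rw), as.vector(Cw)), K, S)
    vy <- matrix(bilinear_interp(gy, as.vector(Rw), as.vector(Cw)), K, S)
    mag <- sqrt(vx^2 + vy^2)
    wrad <- exp(-(off$dr^2 + off$dc^2) / (2 * (1.5 * s_kp)^2))
    wmat <- mag * matrix(wrad, K, S, byrow = TRUE)
    ang <- atan2(vy, vx) %% (2 * pi)
    bins <- pmin(floor(ang / (2 * pi) * 36), 35)
    H <- accumulate_bins(wmat, bins, 36L)
    for (it in 1:2)
      H <- (H + H[, c(36, 1:35), drop = FALSE] + H[, c(2:36, 1), drop = FALSE]) / 3
    theta <- (max.col(H, ties.method = "first") - 0.5) * (2 * pi / 36)
    kp$angle[sel] <- theta

    # --- descriptor: sample an 18x18 rotated, scale-spaced grid
    ct <- cos(theta); st <- sin(theta)
    # offsets in image coords: x -> columns, y -> rows
    dc_ <- outer(ct, grid$i * s_kp) - outer(st, grid$j * s_kp)
    dr_ <- outer(st, grid$i * s_kp) + outer(ct, grid$j * s_kp)
    Rs <- dr_ + r0; Cs <- dc_ + c0
    V <- matrix(bilinear_interp(G[[l]], as.vector(Rs), as.vector(Cs)), K, 324)
    # on-grid central differences = gradient already in the rotated frame
    dxv <- (V[, interior + 1, drop = FALSE] - V[, interior - 1, drop = FALSE]) / 2
    dyv <- (V[, interior + 18, drop = FALSE] - V[, interior - 18, drop = FALSE]) / 2
    magd <- sqrt(dxv^2 + dyv^2)
    angd <- atan2(dyv, dxv) %% (2 * pi)
    ob <- pmin(floor(angd / (2 * pi) * 8), 7)
    fbin <- matrix(cell, K, 256, byrow = TRUE) * 8 + ob
    wd <- magd * matrix(gw, K, 256, byrow = TRUE)
    Dm <- accumulate_bins(wd, fbin, 128L)
    nrm <- sqrt(rowSums(Dm^2)); nrm[nrm == 0] <- 1
    Dm <- Dm / nrm
    Dm[Dm > 0.2] <- 0.2
    nrm <- sqrt(rowSums(Dm^2)); nrm[nrm == 0] <- 1
    desc[sel, ] <- Dm / nrm
  }
  kp$sigma <- sig[kp$layer]
  list(keypoints = kp[, c("row", "col", "sigma", "angle", "strength")],
       descriptors = desc)
}

# Ratio-test + mutual-NN descriptor matching on squared Euclidean distances.
match_descriptors <- function(d1, d2, ratio = 0.75, mutual = TRUE) {
  k1 <- nrow(d1); k2 <- nrow(d2)
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (k1 == 0 || k2 == 0) return(empty)
  sq <- matrix(rowSums(d1^2), k1, k2) +
    matrix(rowSums(d2^2), k1, k2, byrow = TRUE) - 2 * d1 %*% t(d2)
  sq[sq < 0] <- 0
  best_j <- max.col(-sq, ties.method = "first")
  best_d <- sq[cbind(seq_len(k1), best_j)]
  if (k2 >= 2) {
    sq2 <- sq
    sq2[cbind(seq_len(k1), best_j)] <- Inf
    second_d <- sq2[cbind(seq_len(k1), max.col(-sq2, ties.method = "first"))]
    ok <- best_d <= ratio^2 * second_d
  } else ok <- rep(TRUE, k1)
  if (mutual) {
    best_i <- max.col(-t(sq), ties.method = "first")
    ok <- ok & best_i[best_j] == seq_len(k1)
  }
  data.frame(i = which(ok), j = best_j[ok], dist = sqrt(best_d[ok]))
}

#' Match two saliency maps by invariant features
#'
#' Detects keypoints and descriptors on both maps and counts descriptor
#' correspondences surviving Lowe's ratio test and a mutual-nearest-neighbour
#' cross check. The count is the matching score used to pick key frames.
#'
#' @param saliency_a,saliency_b single-channel matrices.
#' @param match_ratio Lowe ratio-test threshold in (0, 1).
#' @param n_keypoints per-map keypoint budget.
#' @return list with `count`, `matches` (data.frame i, j, dist) and the two
#'   feature sets (`features_a`, `features_b`).
#' @export
detect_and_match <- function(saliency_a, saliency_b, match_ratio = 0.75,
                             n_keypoints = 150) {
  if (length(saliency_a) == 0 || length(saliency_b) == 0) stopf("empty map")
  fa <- if (is.list(saliency_a) && !is.null(saliency_a$descriptors))
    saliency_a else sift_features(saliency_a, n_keypoints)
  fb <- if (is.list(saliency_b) && !is.null(saliency_b$descriptors))
    saliency_b else sift_features(saliency_b, n_keypoints)
  mm <- match_descriptors(fa$descriptors, fb$descriptors, ratio = match_ratio)
  list(count = nrow(mm), matches = mm, features_a = fa, features_b = fb)
}
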