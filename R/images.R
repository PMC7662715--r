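# Raster utilities: frames are H x W x 3 numeric arrays (8-bit 0..255 or
# normalised 0..1 doubles; all operations are scale-consistent) or H x W
# single-channel matrices.

# Rec.601 luminance of an RGB array; pass-through for matrices.
luminance <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stopf("expected an H x W x 3 RGB array or an H x W matrix")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Shift a matrix by (dr, dc) with replicate padding at the borders.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# 4-neighbour discrete Laplacian [[0,1,0],[1,-4,1],[0,1,0]], replicate borders.
laplacian4 <- function(m) {
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
    shift_mat(m, 0, 1) + shift_mat(m, 0, -1) - 4 * m
}

# Banded Toeplitz Gaussian convolution matrix, rows renormalised so borders
# behave like replicate padding. Cached per (n, sigma).
.gauss_cache <- new.env(parent = emptyenv())
gauss_band <- function(n, sigma) {
  key <- paste0(n, "_", signif(sigma, 8))
  hit <- .gauss_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (k in -r:r) {
    idx <- seq_len(n)
    j <- idx + k
    ok <- j >= 1 & j <= n
    M[cbind(idx[ok], j[ok])] <- M[cbind(idx[ok], j[ok])] + g[k + r + 1]
  }
  M <- M / rowSums(M)
  .gauss_cache[[key]] <- M
  M
}

# Separable Gaussian smoothing of a matrix (border-renormalised).
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  gauss_band(nrow(m), sigma) %*% m %*% t(gauss_band(ncol(m), sigma))
}

# Gaussian blur of an RGB array (used by the frame simulator).
blur_rgb <- function(image, sigma) {
  out <- image
  for (ch in 1:3) out[, , ch] <- gaussian_smooth(image[, , ch], sigma)
  out
}

# Box filter (mean over a (2r+1)^2 window, replicate borders).
box_smooth <- function(m, r = 1L) {
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -r:r) for (dc in -r:r) acc <- acc + shift_mat(m, dr, dc)
  acc / (2 * r + 1)^2
}

#' Laplacian blur score of a frame
#'
#' Scores image sharpness from the response of the 4-neighbour Laplacian
#' stencil: blurred frames carry less second-derivative energy. Two modes are
#' provided because the two published formulations differ: `sum_abs` is the
#' sum of absolute Laplacian responses, `variance` is the variance of the
#' response over all pixels. By default the `sum_abs` score is divided by the
#' pixel count so that scores are comparable across resolutions.
#'
#' @param image RGB array (H x W x 3) or grayscale matrix; converted to
#'   Rec.601 luminance internally.
#' @param mode `"sum_abs"` (default) or `"variance"`.
#' @param normalize divide the `sum_abs` score by the number of pixels
#'   (default `TRUE`; ignored for `mode = "variance"`).
#' @return a single non-negative number; 0 for a constant image.
#' @examples
#' img <- array(128, c(8, 8, 3))
#' blur_score(img)  # 0: a constant image has no edges
#' @export
blur_score <- function(image, mode = c("sum_abs", "variance"), normalize = TRUE) {
  mode <- match.arg(mode)
  if (length(image) == 0) stopf("empty image")
  g <- laplacian4(luminance(image))
  if (mode == "sum_abs") {
    s <- sum(abs(g))
    if (normalize) s / length(g) else s
  } else {
    stats::var(as.vector(g)) * (length(g) - 1) / length(g)
  }
}

#' Blur-rejection threshold from reference sharp frames
#'
#' The gate below which a frame is declared blurred: a fixed fraction
#' (default 3/4) of the mean blur score of visibly sharp reference frames.
#'
#' @param reference_scores numeric vector of blur scores of sharp frames.
#' @param fraction fraction of the mean used as threshold, in (0, 1].
#' @return the threshold score.
#' @export
blur_threshold <- function(reference_scores, fraction = 0.75) {
  if (length(reference_scores) == 0) stopf("no reference scores supplied")
  if (any(reference_scores < 0)) stopf("blur scores must be non-negative")
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  fraction * mean(reference_scores)
}

#' Chromaticity (normalised RGB) of a frame
#'
#' Per pixel, r = R/(R+G+B), g = G/(R+G+B), b = B/(R+G+B). Black pixels
#' (R+G+B = 0) map to (0, 0, 0) by convention so no NaN is produced.
#'
#' @param image RGB array, 8-bit or normalised.
#' @return H x W x 3 array of chromaticity coordinates summing to 1 at every
#'   non-black pixel.
#' @export
chromaticity <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3) stopf("expected an RGB array")
  s <- image[, , 1] + image[, , 2] + image[, , 3]
  s0 <- s
  s0[s0 == 0] <- 1
  out <- image[, , 1:3, drop = FALSE]
  for (ch in 1:3) {
    v <- image[, , ch] / s0
    v[s == 0] <- 0
    out[, , ch] <- v
  }
  out
}

#' Visible-band vegetation index raster
#'
#' Computes a per-pixel vegetation index on chromaticity coordinates:
#' NDI = (g-r)/(g+r), ExG = 2g-r-b, ExR = 1.48r-g, ExGR = ExG-ExR,
#' VEG = g / (r^0.667 * b^0.333). ExGR (the default throughout the package)
#' amplifies the green-crop / brown-soil contrast and is negative on soil.
#' Division-by-zero pixels (NDI with g+r = 0; VEG with r = 0 or b = 0) are
#' set to 0 by convention.
#'
#' @param image RGB array.
#' @param index_name one of `"NDI"`, `"ExG"`, `"ExR"`, `"ExGR"`, `"VEG"`
#'   (case-insensitive).
#' @return a numeric H x W matrix of index values.
#' @export
vegetation_index <- function(image, index_name = "ExGR") {
  idx <- toupper(index_name)
  if (!idx %in% c("NDI", "EXG", "EXR", "EXGR", "VEG"))
    stopf("unknown vegetation index '%s'", index_name)
  ch <- chromaticity(image)
  d <- dim(ch)
  r <- matrix(ch[, , 1], d[1], d[2])        # keep dims even for 1 x 1 rasters
  g <- matrix(ch[, , 2], d[1], d[2])
  b <- matrix(ch[, , 3], d[1], d[2])
  switch(idx,
    NDI = {
      den <- g + r
      out <- (g - r)
      nz <- den != 0
      out[nz] <- out[nz] / den[nz]
      out[!nz] <- 0
      out
    },
    EXG = 2 * g - r - b,
    EXR = 1.48 * r - g,
    EXGR = (2 * g - r - b) - (1.48 * r - g),
    VEG = {
      out <- matrix(0, nrow(r), ncol(r))
      ok <- r > 0 & b > 0
      out[ok] <- g[ok] / (r[ok]^0.667 * b[ok]^0.333)
      out
    })
}

#' Grayscale crop saliency map
#'
#' Clips the negative part of a vegetation-index raster (soil) and linearly
#' rescales the remainder to 8-bit range: the strongest crop pixel maps to
#' 255; an all-soil frame yields an all-zero map.
#'
#' @inheritParams vegetation_index
#' @return H x W matrix with values in 0..255.
#' @export
saliency_map <- function(image, index_name = "ExGR") {
  v <- vegetation_index(image, index_name)
  v[v < 0] <- 0
  m <- max(v)
  if (m > 0) v <- v * (255 / m)
  v
}
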