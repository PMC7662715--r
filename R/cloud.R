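# The point-cloud container and its PLY/PCD serialisation.

#' Construct a 3D point cloud
#'
#' The container used throughout the pipeline: an N x 3 coordinate matrix in
#' virtual (reconstruction) units, optional 8-bit RGB colours and optional
#' integer branch labels (-1 = unassigned/noise).
#'
#' @param points N x 3 numeric matrix (columns x, y, z).
#' @param colors optional N x 3 matrix of 0..255 integers.
#' @param labels optional integer vector of length N.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, colors = NULL, labels = NULL) {
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), 0, 3)
  if (ncol(points) != 3) stopf("points must have 3 columns")
  if (any(!is.finite(points))) stopf("coordinates must be finite")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  n <- nrow(points)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (nrow(colors) != n || ncol(colors) != 3) stopf("colors must be N x 3")
    storage.mode(colors) <- "integer"
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stopf("labels must have length N")
  }
  structure(list(points = points, colors = colors, labels = labels),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("point_cloud: %d points%s%s\n", n,
              if (!is.null(x$colors)) ", RGB" else "",
              if (!is.null(x$labels)) sprintf(", %d labels",
                                              length(unique(x$labels))) else ""))
  if (n > 0) {
    bb <- apply(x$points, 2, range)
    cat(sprintf("  bbox: x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

# Subset a cloud by point index, keeping colours/labels in step.
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              colors = if (!is.null(cloud$colors)) cloud$colors[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx])
}

bbox_diagonal <- function(cloud) {
  if (n_points(cloud) == 0) return(0)
  sqrt(sum((apply(cloud$points, 2, max) - apply(cloud$points, 2, min))^2))
}

#' @export
plot.point_cloud <- function(x, which = c("xz", "xy", "yz"), cex = 0.2, ...) {
  which <- match.arg(which)
  ax <- strsplit(which, "")[[1]]
  cols <- if (!is.null(x$colors))
    grDevices::rgb(x$colors[, 1], x$colors[, 2], x$colors[, 3], maxColorValue = 255)
  else if (!is.null(x$labels)) x$labels + 2L else "black"
  graphics::plot(x$points[, ax[1]], x$points[, ax[2]], col = cols, pch = 16,
                 cex = cex, xlab = ax[1], ylab = ax[2], asp = 1, ...)
  invisible(x)
}

#' Read a PLY point cloud
#'
#' Supports ASCII and binary little-endian PLY with per-vertex `x`, `y`, `z`
#' and optionally `red`, `green`, `blue` (uchar) and an integer `branch`
#' label property (the convention used by [write_ply()]).
#'
#' @param path PLY file.
#' @return a [point_cloud()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stopf("unexpected end of PLY header")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 200) stopf("PLY header too long")
  }
  if (trimws(header[1]) != "ply") stopf("not a PLY file: %s", path)
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stopf("unsupported PLY format '%s'", fmt)

  # vertex element and its properties (list types unsupported for vertices)
  props <- list(); nvert <- NULL; in_vertex <- FALSE
  other_elements <- FALSE
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
      else if (as.integer(tok[3]) > 0) other_elements <- TRUE
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stopf("list vertex properties are not supported")
      props[[tok[3]]] <- tok[2]
    }
  }
  if (is.null(nvert)) stopf("no vertex element in PLY header")

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  pn <- names(props)
  if (fmt == "ascii") {
    txt <- readLines(con)
    tab <- utils::read.table(text = txt, nrows = nvert, colClasses = "numeric")
    if (ncol(tab) < length(pn)) stopf("malformed PLY vertex data")
    colnames(tab)[seq_along(pn)] <- pn
    vals <- as.list(tab)
  } else {
    sizes <- unname(type_size[unlist(props)])
    if (any(is.na(sizes))) stopf("unknown PLY property type")
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * nvert)
    if (length(raw) < rec * nvert) stopf("truncated PLY payload")
    mat <- matrix(raw, nrow = rec)
    off <- cumsum(c(0, sizes))
    vals <- list()
    for (k in seq_along(pn)) {
      ty <- props[[k]]; sz <- sizes[k]
      bytes <- as.vector(mat[(off[k] + 1):(off[k] + sz), , drop = FALSE])
      vals[[pn[k]]] <- if (ty %in% c("float", "float32", "double", "float64"))
        readBin(bytes, "double", n = nvert, size = sz, endian = "little")
      else
        readBin(bytes, "integer", n = nvert, size = sz, endian = "little",
                signed = !(ty %in% c("uchar", "uint8", "ushort", "uint16")))
    }
  }
  if (!all(c("x", "y", "z") %in% pn)) stopf("PLY lacks x/y/z vertex properties")
  pts <- cbind(vals$x, vals$y, vals$z)
  cols <- if (all(c("red", "green", "blue") %in% pn))
    cbind(vals$red, vals$green, vals$blue)
  labs <- if ("branch" %in% pn) vals$branch
  point_cloud(pts, colors = cols, labels = labs)
}

#' Write a point cloud as ASCII PLY
#'
#' Colours are written as uchar `red`/`green`/`blue`; labels as an `int`
#' vertex property `branch`.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param comment optional header comment lines.
#' @return invisibly, `path`.
#' @export
write_ply <- function(cloud, path, comment = NULL) {
  n <- n_points(cloud)
  props <- c("property float x", "property float y", "property float z")
  if (!is.null(cloud$colors))
    props <- c(props, "property uchar red", "property uchar green",
               "property uchar blue")
  if (!is.null(cloud$labels)) props <- c(props, "property int branch")
  header <- c("ply", "format ascii 1.0",
              if (!is.null(comment)) paste("comment", comment),
              sprintf("element vertex %d", n), props, "end_header")
  body <- cloud$points
  fmtcols <- sprintf("%.8g %.8g %.8g", body[, 1], body[, 2], body[, 3])
  if (!is.null(cloud$colors))
    fmtcols <- paste(fmtcols, cloud$colors[, 1], cloud$colors[, 2], cloud$colors[, 3])
  if (!is.null(cloud$labels)) fmtcols <- paste(fmtcols, cloud$labels)
  writeLines(c(header, fmtcols), path)
  invisible(path)
}

#' Read an ASCII PCD point cloud
#'
#' Minimal reader for ASCII PCD files with at least `x y z` fields; a
#' `branch` field is mapped to labels.
#'
#' @param path PCD file.
#' @return a [point_cloud()].
#' @export
read_pcd <- function(path) {
  lines <- readLines(path)
  hend <- grep("^DATA", lines)[1]
  if (is.na(hend)) stopf("not a PCD file: %s", path)
  if (!grepl("ascii", lines[hend])) stopf("only ASCII PCD is supported")
  fields <- strsplit(trimws(sub("^FIELDS\\s+", "", grep("^FIELDS", lines, value = TRUE)[1])), "\\s+")[[1]]
  dat <- utils::read.table(text = lines[(hend + 1):length(lines)])
  colnames(dat)[seq_along(fields)] <- fields
  labs <- if ("branch" %in% fields) as.integer(dat$branch)
  point_cloud(cbind(dat$x, dat$y, dat$z), labels = labs)
}

#' Write a point cloud as ASCII PCD
#'
#' @inheritParams write_ply
#' @return invisibly, `path`.
#' @export
write_pcd <- function(cloud, path) {
  n <- n_points(cloud)
  fields <- c("x", "y", "z", if (!is.null(cloud$labels)) "branch")
  k <- length(fields)
  header <- c("# .PCD v0.7 - Point Cloud Data file format",
              "VERSION 0.7",
              paste("FIELDS", paste(fields, collapse = " ")),
              paste("SIZE", paste(rep(4, k), collapse = " ")),
              paste("TYPE", paste(c("F", "F", "F", if (k == 4) "I"), collapse = " ")),
              paste("COUNT", paste(rep(1, k), collapse = " ")),
              sprintf("WIDTH %d", n), "HEIGHT 1",
              "VIEWPOINT 0 0 0 1 0 0 0",
              sprintf("POINTS %d", n), "DATA ascii")
  body <- sprintf("%.8g %.8g %.8g", cloud$points[, 1], cloud$points[, 2],
                  cloud$points[, 3])
  if (!is.null(cloud$labels)) body <- paste(body, cloud$labels)
  writeLines(c(header, body), path)
  invisible(path)
}
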