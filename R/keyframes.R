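# Key-frame selection: blur gating + ExGR saliency + invariant-feature
# matching against the previous key frame.

# Normalise the accepted frame sources to a lazy accessor.
#  - list of H x W x 3 arrays (in-memory video)
#  - "frame_sequence" object from make_video()
#  - character vector of PNG paths, or a single directory of PNGs
as_frames <- function(x) {
  if (inherits(x, "frame_sequence")) x <- x$frames
  if (is.list(x) && length(x) > 0 && is.array(x[[1]]))
    return(list(n = length(x), get = function(i) x[[i]], paths = NULL))
  if (is.character(x)) {
    paths <- x
    if (length(x) == 1 && dir.exists(x)) {
      paths <- list.files(x, pattern = "\\.png$", ignore.case = TRUE,
                          full.names = TRUE)
      paths <- paths[order(basename(paths))]
    }
    if (length(paths) == 0) stopf("no PNG frames found")
    return(list(n = length(paths),
                get = function(i) {
                  a <- png::readPNG(paths[i])
                  if (is.matrix(a)) a <- array(rep(a, 3), c(dim(a), 3))
                  a[, , 1:3, drop = FALSE]
                },
                paths = paths))
  }
  stopf("unsupported frame source; give a list of RGB arrays, PNG paths, or a directory")
}

# Contiguous equal-interval partition of 1..n into m sets (last absorbs rest).
frame_sets <- function(n, m) {
  base <- n %/% m
  lapply(seq_len(m), function(s) {
    from <- (s - 1L) * base + 1L
    to <- if (s == m) n else s * base
    seq.int(from, to)
  })
}

#' Select sharp, crop-containing key frames from a frame sequence
#'
#' Implements the key-frame rule: the video is partitioned into `m`
#' equal-interval contiguous sets; frames whose Laplacian blur score falls
#' below a threshold (a fraction of the mean score of sharp reference frames)
#' are discarded; the first surviving frame of set 1 becomes key frame 1; in
#' every later set the member whose crop saliency map has the most invariant
#' feature matches against the previous key frame's map is selected. If every
#' frame of a set is blurred, its least-blurred member is kept and a warning
#' is issued. The procedure is fully deterministic.
#'
#' @param frames a list of RGB arrays, a `frame_sequence` from [make_video()],
#'   a character vector of PNG paths, or a directory of PNG frames. Frame
#'   indices in the result are 1-based positions in this sequence.
#' @param m target number of key frames (>= 2); default 40 balances
#'   reconstruction quality against computation for a single plant.
#' @param blur_fraction fraction of the mean reference blur score used as the
#'   rejection threshold (default 0.75).
#' @param index_name vegetation index used for saliency (default `"ExGR"`).
#' @param match_ratio Lowe ratio-test threshold for descriptor matching.
#' @param blur_mode blur score mode, see [blur_score()].
#' @param reference_sharp optional indices of visibly sharp frames used to set
#'   the blur threshold; by default the 10 highest-scoring frames are used.
#' @param n_keypoints per-map keypoint budget for matching.
#' @return an object of class `keyframe_result`: `selected_indices` (strictly
#'   increasing), `match_counts` (NA for the first key frame), `rejected_blurry`,
#'   `blur_scores`, `threshold`, and the set partition.
#' @export
select_keyframes <- function(frames, m = 40, blur_fraction = 0.75,
                             index_name = "ExGR", match_ratio = 0.75,
                             blur_mode = "sum_abs", reference_sharp = NULL,
                             n_keypoints = 120) {
  src <- as_frames(frames)
  n <- src$n
  if (m < 2) stopf("m must be >= 2")
  if (n < m) stopf("frame count (%d) is smaller than m (%d)", n, m)

  scores <- vapply(seq_len(n), function(i) blur_score(src$get(i), mode = blur_mode),
                   numeric(1))
  ref <- if (!is.null(reference_sharp)) scores[reference_sharp] else
    utils::head(sort(scores, decreasing = TRUE), 10L)
  thr <- blur_threshold(ref, blur_fraction)
  sharp <- scores >= thr
  if (sum(sharp) < 2) stopf("fewer than 2 usable frames after blur gating")
  sets <- frame_sets(n, m)

  # features are computed on the saliency support (plus padding): the map is
  # zero on soil by construction, so cropping changes nothing but cost
  feat_of <- function(i) {
    s <- saliency_map(src$get(i), index_name)
    nz <- which(s > 0, arr.ind = TRUE)
    if (nrow(nz) > 0) {
      r0 <- max(1L, min(nz[, 1]) - 12L); r1 <- min(nrow(s), max(nz[, 1]) + 12L)
      c0 <- max(1L, min(nz[, 2]) - 12L); c1 <- min(ncol(s), max(nz[, 2]) + 12L)
      s <- s[r0:r1, c0:c1, drop = FALSE]
    }
    sift_features(s, n_keypoints = n_keypoints)
  }

  selected <- integer(0)
  match_counts <- rep(NA_real_, m)
  prev_feat <- NULL
  for (s in seq_len(m)) {
    cand <- sets[[s]][sharp[sets[[s]]]]
    if (length(cand) == 0) {
      cand <- sets[[s]][which.max(scores[sets[[s]]])]
      warning(sprintf("all %d frames of set %d are blurred; keeping least-blurred frame %d",
                      length(sets[[s]]), s, cand), call. = FALSE)
    }
    if (s == 1) {
      pick <- cand[1]
      prev_feat <- feat_of(pick)
    } else {
      counts <- integer(length(cand))
      feats <- vector("list", length(cand))
      for (k in seq_along(cand)) {
        feats[[k]] <- feat_of(cand[k])
        counts[k] <- nrow(match_descriptors(feats[[k]]$descriptors,
                                            prev_feat$descriptors,
                                            ratio = match_ratio))
      }
      k <- which.max(counts)           # ties: earliest frame wins
      pick <- cand[k]
      match_counts[s] <- counts[k]
      prev_feat <- feats[[k]]
    }
    selected <- c(selected, pick)
  }

  structure(list(selected_indices = selected,
                 match_counts = match_counts,
                 rejected_blurry = which(!sharp),
                 blur_scores = scores,
                 threshold = thr,
                 blur_fraction = blur_fraction,
                 index_name = index_name,
                 sets = sets),
            class = "keyframe_result")
}

#' @export
print.keyframe_result <- function(x, ...) {
  cat(sprintf("Key-frame selection: %d key frames from %d frames\n",
              length(x$selected_indices), length(x$blur_scores)))
  cat(sprintf("  blur threshold %.4g (%.0f%% of reference mean); %d frames rejected as blurred\n",
              x$threshold, 100 * x$blur_fraction, length(x$rejected_blurry)))
  cat(sprintf("  saliency index %s; median match count %.0f\n",
              x$index_name, stats::median(x$match_counts, na.rm = TRUE)))
  cat("  indices:", paste(utils::head(x$selected_indices, 15), collapse = " "),
      if (length(x$selected_indices) > 15) "..." else "", "\n")
  invisible(x)
}

#' Write selected key frames and a JSON sidecar to a directory
#'
#' @param result a `keyframe_result`.
#' @param frames the same frame source passed to [select_keyframes()].
#' @param dir output directory (created if missing).
#' @return invisibly, the sidecar path.
#' @export
write_keyframes <- function(result, frames, dir) {
  src <- as_frames(frames)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in result$selected_indices)
    png::writePNG(src$get(i), file.path(dir, sprintf("frame_%06d.png", i)))
  side <- file.path(dir, "keyframes.json")
  jsonlite::write_json(list(selected_indices = result$selected_indices,
                            match_counts = result$match_counts,
                            rejected_blurry = result$rejected_blurry,
                            blur_scores = result$blur_scores,
                            threshold = result$threshold,
                            index_name = result$index_name),
                       side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}
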