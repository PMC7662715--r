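# End-to-end orchestration: keyframes -> [external SfM adapter] -> prep ->
# skeleton -> measure, with a single flat configuration and one top-level
# seed feeding every stochastic stage.

pipeline_defaults <- function() list(
  frames = NULL,            # frame dir / PNG paths (keyframes stage input)
  cloud = NULL,             # scene PLY/PCD path (prep stage input)
  cube_cloud = NULL,        # cube PLY path (optional, for auto calibration)
  out = NULL,               # artifact directory (optional)
  m = 40, blur_fraction = 0.75, index_name = "ExGR", match_ratio = 0.75,
  blur_mode = "sum_abs",
  ransac_threshold = NULL, ransac_iterations = 1000, margin = NULL,
  target_points = c(10000, 30000), filter_radius = NULL, min_neighbors = 5,
  dh = NULL, eps = NULL, link_dist = NULL, min_nodes = NULL,
  cube_edge_mm = 56, cube_l_virtual = NULL,
  tilt = "off", use_spline = TRUE, seed = 17)

#' Build and validate a pipeline configuration
#'
#' A single flat configuration holding every stage parameter with its
#' default. Unknown keys are rejected; the object serialises losslessly to
#' JSON and back.
#'
#' @param ... named overrides of the defaults (see Details in the package
#'   vignette for the full parameter table).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stopf("all configuration values must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$m < 2) stopf("m must be >= 2")
  if (cfg$blur_fraction <= 0 || cfg$blur_fraction > 1)
    stopf("blur_fraction must be in (0, 1]")
  if (!is.null(cfg$min_nodes) && cfg$min_nodes < 1)
    stopf("min_nodes must be >= 1")
  if (length(cfg$target_points) != 2 ||
      cfg$target_points[1] > cfg$target_points[2])
    stopf("target_points must be c(lower, upper)")
  if (!cfg$tilt %in% c("off", "pca")) stopf("tilt must be 'off' or 'pca'")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(v)) "auto/none" else paste(v, collapse = ":")))
  }
  invisible(x)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a `pipeline_config`.
#' @param path JSON file.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   validated `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(Filter(Negate(is.null), unclass(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j)
}

#' Run the phenotyping pipeline end to end
#'
#' Runs the configured stages in order, skipping stages whose inputs are not
#' given: key-frame selection (when frames are supplied), cloud
#' preprocessing, skeleton extraction, calibration and trait measurement.
#' Starting from an intermediate artifact yields the same downstream results
#' as a full run that produced it. When `config$out` is set, every artifact
#' is written to disk together with a provenance block (parameters, seed,
#' input hashes).
#'
#' The dense SfM/MVS reconstruction between key frames and scene cloud is
#' external: when frames are given but no cloud, the run stops with an
#' explicit "reconstruction adapter required" error.
#'
#' @param config a [pipeline_config()].
#' @param frames optional in-memory frame source (overrides `config$frames`).
#' @param cloud optional in-memory scene [point_cloud()] (overrides
#'   `config$cloud`).
#' @param cube_cloud optional in-memory cube [point_cloud()] for calibration.
#' @return list with the stage artifacts: `keyframes`, `plane`, `plant`
#'   (clean cloud), `skeleton`, `calibration`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), frames = NULL,
                         cloud = NULL, cube_cloud = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()

  src <- frames %||% config$frames
  if (!is.null(src)) {
    kf <- select_keyframes(src, m = config$m,
                           blur_fraction = config$blur_fraction,
                           index_name = config$index_name,
                           match_ratio = config$match_ratio,
                           blur_mode = config$blur_mode)
    artifacts$keyframes <- kf
    if (!is.null(out)) write_keyframes(kf, src, file.path(out, "keyframes"))
  }

  scene <- cloud
  if (is.null(scene) && !is.null(config$cloud))
    scene <- if (grepl("\\.pcd$", config$cloud, ignore.case = TRUE))
      read_pcd(config$cloud) else read_ply(config$cloud)
  if (is.null(scene)) {
    if (!is.null(src))
      stopf(paste("reconstruction adapter required: key frames were selected",
                  "but no point cloud was supplied; run an external SfM/MVS",
                  "tool on the key frames and pass its PLY via `cloud`"))
    stopf("no input: supply frames and/or a scene cloud")
  }

  plane <- fit_ground_plane(scene, distance_threshold = config$ransac_threshold,
                            max_iterations = config$ransac_iterations,
                            seed = derive_seed(config$seed, 1))
  aligned <- align_to_ground(scene, plane)
  plant <- remove_ground(aligned, plane, margin = config$margin)
  plant <- select_plant_component(plant)
  plant <- simplify_cloud(plant, target_count_range = config$target_points)
  plant <- radius_outlier_filter(plant, radius = config$filter_radius,
                                 min_neighbors = config$min_neighbors)
  artifacts$plane <- plane
  artifacts$plant <- plant

  skel <- extract_skeleton(plant, dh = config$dh, eps = config$eps,
                           link_dist = config$link_dist,
                           min_nodes = config$min_nodes)
  artifacts$skeleton <- skel

  l_virtual <- config$cube_l_virtual
  cc <- cube_cloud
  if (is.null(cc) && !is.null(config$cube_cloud)) cc <- read_ply(config$cube_cloud)
  if (is.null(l_virtual) && !is.null(cc))
    l_virtual <- cube_edge_from_cloud(cc, seed = derive_seed(config$seed, 2))
  if (is.null(l_virtual))
    stopf("calibration required: give cube_l_virtual or a cube cloud")
  calib <- scale_factor(config$cube_edge_mm, l_virtual)
  artifacts$calibration <- calib

  labeled <- segment_cloud(plant, skel)
  artifacts$plant <- labeled
  report <- measure_traits(labeled, skel, calib, tilt = config$tilt,
                           use_spline = config$use_spline)
  artifacts$report <- report

  if (!is.null(out)) {
    write_ply(labeled, file.path(out, "plant_labeled.ply"))
    write_skeleton_json(skel, file.path(out, "skeleton.json"))
    write_report(report, json_path = file.path(out, "report.json"),
                 csv_path = file.path(out, "report.csv"))
    prov <- list(config = Filter(Negate(is.null), unclass(config)),
                 seed = config$seed,
                 input_hash = object_hash(scene$points),
                 n_scene_points = n_points(scene),
                 n_plant_points = n_points(labeled))
    jsonlite::write_json(prov, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  artifacts
}
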