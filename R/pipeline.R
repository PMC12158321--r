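#' Read a YAML run configuration
#'
#' Loads the nested run configuration. A learning rate given as -1 maps to
#' the package default (0.005).
#'
#' @param path YAML file path
#' @return configuration list for [run_pipeline()]
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$itf$default_alpha) && cfg$itf$default_alpha == -1)
    cfg$itf$default_alpha <- 0.005
  cfg
}

merge_args <- function(fn, overrides) {
  overrides <- overrides[names(overrides) %in% names(formals(fn))]
  do.call(fn, overrides)
}

#' Run the full segmentation pipeline
#'
#' Ties the stages together: background subtraction (plain or adaptive),
#' optional network segmentation from a checkpoint, pixel-level fusion with
#' morphological refinement, and scoring against ground truth when supplied.
#' Per-frame masks are written as PNG (0/255), a manifest records the exact
#' configuration and seed, and a JSON + CSV report is written when ground
#' truth is available.
#'
#' @param config a list (see [read_run_config()]) with fields:
#'   `input` (frame directory, or an in-memory frame list), `output`
#'   (output directory), `mode` (one of `"gmm"`, `"gmm+lr"`, `"itf-gmm"`,
#'   `"unet"`, `"fused"`), optional `ground_truth` (mask directory or list),
#'   optional `checkpoint` (network RDS path, required for `"unet"` and
#'   `"fused"`), optional nested `itf` and `fusion` sections, and `seed`
#' @return invisibly, a list with `masks`, `metrics` (or `NULL`) and the
#'   output paths
#' @export
run_pipeline <- function(config) {
  mode <- match.arg(config$mode %||% "itf-gmm",
                    c("gmm", "gmm+lr", "itf-gmm", "unet", "fused"))
  out <- config$output %||% stop("config$output is required")
  dir.create(file.path(out, "masks"), recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)
  frames <- if (is.character(config$input)) read_frames(config$input)
            else as_frame_sequence(config$input)
  itf_over <- config$itf %||% list()
  if (mode %in% c("gmm", "gmm+lr"))
    itf_over <- utils::modifyList(itf_over,
      list(adapt_k = FALSE, adapt_lr = (mode == "gmm+lr")))
  cf <- merge_args(itf_config, itf_over)
  need_net <- mode %in% c("unet", "fused")
  net <- NULL
  if (need_net) {
    if (is.null(config$checkpoint) || !file.exists(config$checkpoint %||% ""))
      stop("mode '", mode, "' needs a network checkpoint; train one with ",
           "train_conunet() and save_conunet(), or run: irseg train")
    net <- load_conunet(config$checkpoint)
  }
  bg_masks <- NULL
  if (mode != "unet") {
    run <- itf_gmm(frames, cf)
    bg_masks <- run$masks
  }
  net_masks <- NULL
  if (need_net)
    net_masks <- lapply(frames, function(f)
      predict_mask(net, gray_plane(f),
                   threshold = config$threshold %||% 0.5))
  fus <- merge_args(fusion_config, config$fusion %||% list())
  masks <- switch(mode,
    "unet" = net_masks,
    "fused" = Map(function(a, b) fuse_and_refine(a, b, fus),
                  bg_masks, net_masks),
    bg_masks)
  for (t in seq_along(masks))
    write_mask_png(masks[[t]], file.path(out, "masks",
                                         sprintf("frame_%05d.png", t)))
  metrics <- NULL
  if (!is.null(config$ground_truth)) {
    truth <- if (is.character(config$ground_truth)) {
      files <- sort(list.files(config$ground_truth, pattern = "\\.png$",
                               full.names = TRUE))
      lapply(files, read_mask_png)
    } else config$ground_truth
    metrics <- evaluate_masks(masks, truth, out)
  }
  keep <- names(config)
  if (!is.character(config$input)) keep <- setdiff(keep, "input")
  if (!is.character(config$ground_truth)) keep <- setdiff(keep, "ground_truth")
  manifest <- list(package = "irseg",
                   version = as.character(utils::packageVersion("irseg")),
                   mode = mode, seed = seed, config = config[keep])
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(masks = masks, metrics = metrics, output = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score predicted masks against ground truth and write a report
#'
#' Pooled (micro-averaged) and per-frame precision/accuracy/IOU/recall; when
#' `out` is given, writes `report.json` and `report.csv` there.
#'
#' @param pred,truth lists of binary masks of equal length
#' @param out optional output directory
#' @return the pooled [segmentation_metrics()] with a `per_frame` data frame
#' @export
evaluate_masks <- function(pred, truth, out = NULL) {
  pooled <- segmentation_metrics(pred, truth)
  per <- do.call(rbind, lapply(seq_along(pred), function(t) {
    m <- segmentation_metrics(pred[[t]], truth[[t]])
    data.frame(frame = t, precision = m$precision, accuracy = m$accuracy,
               iou = m$iou, recall = m$recall)
  }))
  pooled$per_frame <- per
  if (!is.null(out)) {
    jsonlite::write_json(
      list(pooled = pooled[c("precision", "accuracy", "iou", "recall")],
           counts = pooled$counts),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.csv(per, file.path(out, "report.csv"), row.names = FALSE)
  }
  pooled
}

#' Sharpness comparison of two images
#'
#' Computes the Brenner, Roberts and SMD2 scores of both images and the
#' relative difference of each metric, taking the sharper (larger) value as
#' the reference.
#'
#' @param img_a,img_b numeric intensity matrices
#' @return list with both [sharpness_report()]s and per-metric
#'   `relative_difference`
#' @export
quality_report <- function(img_a, img_b) {
  ra <- sharpness_report(img_a)
  rb <- sharpness_report(img_b)
  rel <- Map(function(a, b) relative_difference(min(a, b), max(a, b)), ra, rb)
  list(a = ra, b = rb, relative_difference = rel)
}

#' Write a synthetic scene to disk as a dataset
#'
#' Frames go to `frames/`, ground-truth masks to `masks/` (both PNG), and
#' `scenario.yaml` records the exact configuration and seed so the scene can
#' be regenerated.
#'
#' @param scene result of [generate_sequence()] or [stay_hole_benchmark()]
#' @param out output directory
#' @return `out`, invisibly
#' @export
write_scene <- function(scene, out) {
  dir.create(file.path(out, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(scene$frames)) {
    png::writePNG(scene$frames[[t]] / 255,
                  file.path(out, "frames", sprintf("frame_%05d.png", t)))
    write_mask_png(scene$masks[[t]],
                   file.path(out, "masks", sprintf("frame_%05d.png", t)))
  }
  cfg <- scene$config
  cfg$target_shape <- as.character(cfg$target_shape)
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.null(v)) NULL else v), file.path(out, "scenario.yaml"))
  invisible(out)
}
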