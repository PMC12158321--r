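#' Scaled end-to-end benchmark of the fused pipeline
#'
#' Runs the whole method on synthetic scenes at a desk scale: generates a
#' seeded training set, trains a width- and depth-scaled Con-UNet, runs the
#' adaptive background model on a stay-hole-regime evaluation scene, fuses
#' the two mask streams with morphological refinement, and scores the result
#' against the scene's ground truth (micro-averaged over the post-warmup
#' frames).
#'
#' The default problem sizes — 128 x 128 scenes, a depth-2/width-12 network,
#' 32 labeled pairs and 100 epochs — are the package's scaled stand-in for
#' the full training protocol (256 x 256, depth 4, width 64, 1000 epochs);
#' see the methods vignette.
#'
#' @param seed integer seed driving scene generation, network initialization
#'   and shuffling
#' @param n_pairs labeled training pairs
#' @param epochs training epochs
#' @param base_width,depth network size
#' @param size scene edge length in pixels (must suit the network depth)
#' @param lr Adam step size for the scaled run
#' @return list with pooled `precision`, `accuracy`, `iou`, `recall` of the
#'   fused masks, the same for the background-model and network streams
#'   alone (`itf`, `unet`), the trained `net` and the evaluation scene config
#' @export
run_e2e_benchmark <- function(seed = 1L, n_pairs = 32L, epochs = 100L,
                              base_width = 12L, depth = 2L, size = 128L,
                              lr = 1e-3) {
  seed <- as.integer(seed)
  train_cfg <- synthetic_scene_config(height = size, width = size,
                                      seed = seed)
  ts <- generate_training_set(train_cfg, n_pairs)
  net <- with_seed(seed, conunet(conunet_spec(depth = depth,
                                              base_width = base_width,
                                              input_size = size)))
  net <- train_conunet(net, ts$images, ts$masks,
                       training_config(epochs = epochs, batch_size = 2L,
                                       lr = lr, input_size = size,
                                       seed = seed))
  eval_cfg <- synthetic_scene_config(
    height = size, width = size, n_frames = 220L, n_targets = 4L,
    dwell_prob = 0.85, cluster = TRUE, target_area = c(45, 75),
    seed = (seed + 1000L) %% .Machine$integer.max)
  scene <- generate_sequence(eval_cfg)
  run <- itf_gmm(scene$frames, itf_config())
  post <- setdiff(seq_along(run$masks), run$warmup)
  net_masks <- lapply(scene$frames[post], function(f)
    predict_mask(net, gray_plane(f)))
  fused <- Map(function(a, b) fuse_and_refine(a, b),
               run$masks[post], net_masks)
  m <- segmentation_metrics(fused, scene$masks[post])
  list(precision = m$precision, accuracy = m$accuracy, iou = m$iou,
       recall = m$recall,
       itf = segmentation_metrics(run$masks[post], scene$masks[post]),
       unet = segmentation_metrics(net_masks, scene$masks[post]),
       net = net, eval_config = eval_cfg)
}
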