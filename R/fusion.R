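#' Fusion configuration
#'
#' Controls how the background-model mask and the network mask are combined
#' and which morphological refinement is applied afterwards. The default
#' refinement opens with a 3x3 elliptical element (removes isolated speckle)
#' and then closes with a 5x5 one (fills small holes).
#'
#' @param mode bitwise combination, `"or"` (default, union) or `"and"`
#' @param morphology ordered list of steps, each a list with fields
#'   `op` (`"open"`, `"close"`, `"erode"`, `"dilate"`), `shape` (`"ellipse"`
#'   or `"rect"`) and odd integer `size`
#' @return a `fusion_config` list
#' @export
fusion_config <- function(mode = c("or", "and"),
                          morphology = list(
                            list(op = "open",  shape = "ellipse", size = 3L),
                            list(op = "close", shape = "ellipse", size = 5L))) {
  mode <- match.arg(mode)
  for (step in morphology) {
    if (!step$op %in% c("open", "close", "erode", "dilate"))
      stop("unknown morphology op: ", step$op)
    if (!step$shape %in% c("ellipse", "rect"))
      stop("unknown structuring element shape: ", step$shape)
    if (step$size < 1L || step$size %% 2L == 0L)
      stop("structuring element sizes must be odd and >= 1")
  }
  structure(list(mode = mode, morphology = morphology),
            class = "fusion_config")
}

#' Fuse two binary masks pixel-by-pixel
#'
#' @param mask_a,mask_b binary masks of identical shape
#' @param mode `"or"` (union, default) or `"and"` (intersection)
#' @return logical mask
#' @export
fuse_masks <- function(mask_a, mask_b, mode = c("or", "and")) {
  mode <- match.arg(mode)
  a <- as_mask(mask_a); b <- as_mask(mask_b)
  check_same_shape(a, b, "masks")
  if (mode == "or") a | b else a & b
}

#' Morphological refinement of a binary mask
#'
#' Applies the configured sequence of openings/closings/erosions/dilations.
#' With `size = 1` a step is the identity and is skipped.
#'
#' @param mask binary mask
#' @param config a [fusion_config()]
#' @return refined logical mask of the same shape
#' @export
refine_morphology <- function(mask, config = fusion_config()) {
  m <- as_mask(mask)
  x <- matrix(as.numeric(m), nrow(m), ncol(m))
  for (step in config$morphology) {
    if (step$size <= 1L) next
    brush <- EBImage::makeBrush(step$size,
                                shape = if (step$shape == "ellipse") "disc" else "box")
    x <- switch(step$op,
      open   = EBImage::opening(x, brush),
      close  = EBImage::closing(x, brush),
      erode  = EBImage::erode(x, brush),
      dilate = EBImage::dilate(x, brush))
    x <- matrix(as.numeric(x), nrow(m), ncol(m))
  }
  x > 0.5
}

#' Fuse and refine in one call (the full mask post-processing stage)
#'
#' Exactly `refine_morphology(fuse_masks(mask_a, mask_b))`; no hidden stages.
#'
#' @inheritParams fuse_masks
#' @param config a [fusion_config()]
#' @return logical mask
#' @export
fuse_and_refine <- function(mask_a, mask_b, config = fusion_config()) {
  refine_morphology(fuse_masks(mask_a, mask_b, config$mode), config)
}
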