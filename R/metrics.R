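#' Pixelwise confusion counts between a predicted and a true mask
#'
#' @param pred,truth binary masks (logical or 0/1 matrices) of identical shape
#' @return named list with `tp`, `fp`, `fn`, `tn` pixel counts
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  check_same_shape(pred, truth, "pred and truth")
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Segmentation quality metrics
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, intersection over
#' union `TP/(TP+FP+FN)` and accuracy `(TP+TN)/total`. A metric whose
#' denominator is zero is reported as 0 and flagged `degenerate`.
#'
#' `pred` and `truth` may also be lists of masks (one per frame); counts are
#' then pooled over frames before dividing (micro-averaging).
#'
#' @param pred predicted binary mask or list of masks
#' @param truth ground-truth binary mask or list of masks
#' @return named list: `precision`, `accuracy`, `iou`, `recall`,
#'   `counts` and `degenerate` (logical)
#' @export
segmentation_metrics <- function(pred, truth) {
  if (is.list(pred) != is.list(truth))
    stop("pred and truth must both be masks or both be lists of masks")
  if (is.list(pred)) {
    if (length(pred) != length(truth))
      stop("pred and truth lists must have equal length")
    cc <- list(tp = 0, fp = 0, fn = 0, tn = 0)
    for (i in seq_along(pred)) {
      ci <- confusion_counts(pred[[i]], truth[[i]])
      cc <- Map(`+`, cc, ci)
    }
  } else {
    cc <- confusion_counts(pred, truth)
  }
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  degenerate <- (cc$tp + cc$fp) == 0 || (cc$tp + cc$fn) == 0 ||
    (cc$tp + cc$fp + cc$fn) == 0
  list(
    precision = safe_div(cc$tp, cc$tp + cc$fp),
    accuracy  = safe_div(cc$tp + cc$tn, cc$tp + cc$fp + cc$fn + cc$tn),
    iou       = safe_div(cc$tp, cc$tp + cc$fp + cc$fn),
    recall    = safe_div(cc$tp, cc$tp + cc$fn),
    counts    = cc,
    degenerate = degenerate
  )
}

#' Brenner gradient sharpness
#'
#' Sum over the image of the squared grayscale difference at horizontal
#' offset 2: `sum_(x,y) (f(x+2, y) - f(x, y))^2`. Larger values indicate a
#' sharper image; a constant image scores 0.
#'
#' @param img numeric intensity matrix (width >= 3); cast to double internally
#' @return nonnegative scalar
#' @export
sharpness_brenner <- function(img) {
  img <- as_intensity(img)
  if (ncol(img) < 3L) stop("Brenner sharpness needs width >= 3")
  w <- ncol(img)
  d <- img[, 3:w, drop = FALSE] - img[, 1:(w - 2), drop = FALSE]
  sum(d * d)
}

#' Roberts cross-gradient sharpness
#'
#' Sum of the squared diagonal cross differences over each 2x2 neighbourhood:
#' `(f(x+1,y+1)-f(x,y))^2 + (f(x+1,y)-f(x,y+1))^2`.
#'
#' @param img numeric intensity matrix (height and width >= 2)
#' @return nonnegative scalar
#' @export
sharpness_roberts <- function(img) {
  img <- as_intensity(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 2L || w < 2L) stop("Roberts sharpness needs height and width >= 2")
  d1 <- img[2:h, 2:w, drop = FALSE] - img[1:(h - 1), 1:(w - 1), drop = FALSE]
  d2 <- img[2:h, 1:(w - 1), drop = FALSE] - img[1:(h - 1), 2:w, drop = FALSE]
  sum(d1 * d1) + sum(d2 * d2)
}

#' SMD2 (product-of-differences) sharpness
#'
#' For each pixel, the product of its gray differences to the right and to the
#' bottom neighbour, summed over the image. The default takes absolute
#' differences (the standard SMD2 form, guaranteeing a nonnegative score);
#' `signed = TRUE` multiplies the raw differences instead.
#'
#' @param img numeric intensity matrix (height and width >= 2)
#' @param signed use raw signed differences instead of absolute values
#' @return scalar (nonnegative unless `signed = TRUE`)
#' @export
sharpness_smd2 <- function(img, signed = FALSE) {
  img <- as_intensity(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 2L || w < 2L) stop("SMD2 sharpness needs height and width >= 2")
  a <- img[1:(h - 1), 1:(w - 1), drop = FALSE]
  dv <- a - img[2:h, 1:(w - 1), drop = FALSE]   # f(x,y) - f(x+1,y)
  dh <- a - img[1:(h - 1), 2:w, drop = FALSE]   # f(x,y) - f(x,y+1)
  if (signed) sum(dv * dh) else sum(abs(dv) * abs(dh))
}

#' No-reference sharpness report
#'
#' @param img numeric intensity matrix
#' @return named list with `brenner`, `roberts` and `smd2` scores
#' @export
sharpness_report <- function(img) {
  list(brenner = sharpness_brenner(img),
       roberts = sharpness_roberts(img),
       smd2 = sharpness_smd2(img))
}

#' Relative difference of two sharpness measurements
#'
#' `(reference - smaller) / reference`, with the larger (sharper) measurement
#' as the reference, expressing how much less sharp the other image is.
#'
#' @param smaller_value the smaller (less sharp) measurement
#' @param reference_value the larger measurement used as the benchmark
#' @return fraction in `[0, 1)` for `smaller_value <= reference_value`
#' @export
relative_difference <- function(smaller_value, reference_value) {
  if (!is.numeric(reference_value) || reference_value <= 0)
    stop("reference_value must be > 0")
  (reference_value - smaller_value) / reference_value
}

as_intensity <- function(img) {
  if (!is.numeric(img) || !is.matrix(img)) {
    if (is.array(img) && length(dim(img)) == 3L)
      img <- apply(img, c(1L, 2L), mean)
    else stop("img must be a numeric matrix")
  }
  storage.mode(img) <- "double"
  img
}
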