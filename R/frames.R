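#' Frame sequences
#'
#' A frame sequence is an ordered list of grayscale frames, each a numeric
#' `H x W` matrix with intensities in `[0, 255]` (3-channel frames are
#' `H x W x 3` arrays). All frames in a sequence share one shape.
#'
#' @param frames list of numeric matrices (or `H x W x 3` arrays)
#' @return an object of class `frame_sequence` (a validated list)
#' @export
as_frame_sequence <- function(frames) {
  if (inherits(frames, "frame_sequence")) return(frames)
  if (is.matrix(frames) || (is.array(frames) && length(dim(frames)) == 3L))
    frames <- list(frames)
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of numeric matrices")
  shp <- frame_shape(frames[[1L]])
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.numeric(f) || !(is.matrix(f) || length(dim(f)) %in% c(2L, 3L)))
      stop("frame ", i, " is not a numeric matrix/array")
    if (!identical(frame_shape(f), shp))
      stop("frame ", i, " has a different shape from frame 1")
    if (anyNA(f) || min(f) < 0 || max(f) > 255)
      stop("frame ", i, " has intensities outside [0, 255]")
  }
  structure(frames, class = "frame_sequence")
}

frame_shape <- function(f) {
  d <- dim(f)
  if (is.null(d)) stop("frame has no dim attribute")
  if (length(d) == 2L) c(d, 1L) else d
}

#' @export
print.frame_sequence <- function(x, ...) {
  shp <- frame_shape(x[[1L]])
  cat(sprintf("<frame_sequence> %d frames, %d x %d, %d channel(s)\n",
              length(x), shp[1L], shp[2L], shp[3L]))
  invisible(x)
}

#' Read a directory of frames
#'
#' Reads all PNG (and, if the `tiff` package is installed, TIFF) files in a
#' directory in lexicographic order and returns them as a grayscale frame
#' sequence scaled to `[0, 255]`. Multi-channel images are averaged to one
#' channel unless `channels = 3`.
#'
#' @param dir directory containing the frames
#' @param channels 1 (grayscale, default) or 3
#' @return a [as_frame_sequence()] object
#' @export
read_frames <- function(dir, channels = 1L) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no PNG/TIFF frames found in ", dir)
  frames <- lapply(files, read_frame, channels = channels)
  as_frame_sequence(frames)
}

read_frame <- function(path, channels = 1L) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF frames requires the 'tiff' package")
    tiff::readTIFF(path)
  }
  img <- img * 255
  d <- dim(img)
  if (length(d) == 3L) {
    if (channels == 3L) return(img[, , 1:3, drop = FALSE])
    img <- apply(img[, , 1:min(3L, d[3L]), drop = FALSE], c(1L, 2L), mean)
  } else if (channels == 3L) {
    img <- array(rep(img, 3L), dim = c(d, 3L))
  }
  img
}

#' Write a binary mask as a PNG file (foreground = 255)
#'
#' @param mask logical (or 0/1) matrix
#' @param path output file path
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask(mask)
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' Read a binary mask PNG (any value > 0.5 of full scale is foreground)
#' @param path PNG file path
#' @return logical matrix
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

# canonical mask representation: logical matrix
as_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  if (is.numeric(mask) || is.integer(mask)) {
    if (!all(mask %in% c(0, 1)))
      stop("mask values must be binary (0/1 or logical)")
    m <- mask > 0
    dim(m) <- dim(mask)
    return(m)
  }
  stop("mask must be a logical or 0/1 numeric matrix")
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(what, " must have identical shapes")
  invisible(TRUE)
}

#' Resize a grayscale image or a binary mask
#'
#' Images are resampled bilinearly; masks use nearest-neighbour resampling so
#' labels stay binary.
#'
#' @param img numeric matrix (image) or logical matrix (mask)
#' @param h,w target size
#' @param method `"bilinear"` or `"nearest"`
#' @return resized matrix (logical if the input was logical)
#' @export
resize_image <- function(img, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  was_mask <- is.logical(img)
  if (nrow(img) == h && ncol(img) == w) return(img)
  x <- matrix(as.numeric(img), nrow(img), ncol(img))
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(x, w = h, h = w, filter = filt)
  out <- matrix(as.numeric(out), h, w)
  if (was_mask) out > 0.5 else out
}
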