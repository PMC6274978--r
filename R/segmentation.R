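#' Noise reduction and contrast enhancement
#'
#' Applies a square median filter of side `w_median` followed by a linear
#' histogram stretch mapping the filtered frame's \[min, max\] onto
#' \[0, 255\]. Median windows are cropped at the image borders; for even
#' window sides the extra pixel lies below/right of the centre. A constant
#' frame is returned unchanged (the stretch degenerates to the identity).
#'
#' @param frame numeric matrix, raw 340-nm intensities. The input is never
#'   modified; processing happens on a copy.
#' @param params a [segmentation_params()] object.
#' @return real-valued matrix on the 0--255 scale.
#' @export
preprocess <- function(frame, params) {
  filt <- if (params$w_median > 1)
    median_filter_cpp(frame, params$w_median) else frame
  lo <- min(filt)
  hi <- max(filt)
  if (hi == lo) return(filt)
  (filt - lo) / (hi - lo) * 255
}

#' Niblack adaptive thresholding
#'
#' Binarises a frame with the local threshold `T(x, y) = m(x, y) + k_T *
#' s(x, y)`, where `m` and `s` are the mean and population standard
#' deviation over the `w` x `w` window centred at each pixel (cropped at
#' borders). The implementation uses summed-area tables of the image and its
#' square, making the cost independent of `w`, and is numerically equivalent
#' to the direct per-pixel computation. A pixel is foreground iff its
#' intensity strictly exceeds the threshold, so a uniform frame maps to all
#' background (cells are bright on dark).
#'
#' @param frame numeric matrix.
#' @param w window side in px (>= 3, at most the smaller image dimension).
#' @param k_T threshold gain (default 1).
#' @return logical matrix, `TRUE` = foreground.
#' @export
niblack_threshold <- function(frame, w, k_T = 1) {
  if (w < 3) stop("`w` must be >= 3", call. = FALSE)
  if (w > nrow(frame) && w > ncol(frame))
    stop("window larger than both image dimensions", call. = FALSE)
  niblack_threshold_cpp(frame, as.integer(w), k_T)
}

disc_kernel <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Morphological conditioning of a binary mask
#'
#' Cleans the thresholded mask with, in order: opening by a disc of radius
#' `open_radius` (removes specks and thin bridges), hole filling (background
#' regions not 4-connected to the image border become foreground), and
#' dilation by a disc of radius `dilate_radius`.
#'
#' @param binary logical matrix.
#' @param params a [segmentation_params()] object.
#' @return conditioned logical matrix.
#' @export
condition_binary <- function(binary, params) {
  img <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  img <- EBImage::opening(img, disc_kernel(params$open_radius))
  img <- EBImage::fillHull(img)
  img <- EBImage::dilate(img, disc_kernel(params$dilate_radius))
  matrix(as.logical(img > 0), nrow(binary), ncol(binary))
}

#' Label connected components
#'
#' Labels the 8-connected foreground components 1..L in raster-scan order of
#' each component's first pixel, and computes per-component unweighted
#' centroids and pixel areas. Coordinates are 0-based with `x` = column and
#' `y` = row, origin at the top-left pixel centre; this convention is shared
#' by the tracking and Kalman state.
#'
#' @param binary logical matrix (a conditioned mask).
#' @return an object of class `labeled_frame` with fields `binary`, `labels`
#'   (integer matrix, 0 = background) and `components` (data frame with
#'   columns `label`, `x`, `y`, `area`).
#' @export
label_components <- function(binary) {
  labels <- label_components_cpp(binary)
  n <- max(labels)
  if (n == 0) {
    comp <- data.frame(label = integer(), x = numeric(), y = numeric(),
                       area = numeric())
  } else {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    comp <- data.frame(
      label = seq_len(n),
      x = as.numeric(tapply(idx[, "col"] - 1, lab, mean)),
      y = as.numeric(tapply(idx[, "row"] - 1, lab, mean)),
      area = as.numeric(tabulate(lab, n)))
  }
  structure(list(binary = binary, labels = labels, components = comp),
            class = "labeled_frame")
}

#' @export
print.labeled_frame <- function(x, ...) {
  cat(sprintf("<labeled_frame> %d x %d px, %d component(s)\n",
              nrow(x$binary), ncol(x$binary), nrow(x$components)))
  invisible(x)
}

#' Segment a single raw frame
#'
#' Runs the per-frame pipeline [preprocess()] -> [niblack_threshold()] ->
#' [condition_binary()] -> [label_components()].
#'
#' @param frame numeric matrix of raw 340-nm intensities.
#' @param params a [segmentation_params()] object.
#' @return a `labeled_frame`.
#' @export
segment_frame <- function(frame, params) {
  pre <- preprocess(frame, params)
  bin <- niblack_threshold(pre, params$w, params$k_T)
  label_components(condition_binary(bin, params))
}

#' Segment a 340-nm sequence
#'
#' Applies [segment_frame()] independently to every frame of the sequence.
#'
#' @param seq an `"EX340"` [frame_sequence()].
#' @param params a [segmentation_params()] object.
#' @return list of `labeled_frame` objects, one per frame.
#' @export
segment_sequence <- function(seq, params) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (seq$channel != "EX340")
    stop("segmentation operates on the EX340 channel", call. = FALSE)
  lapply(seq_len(n_frames(seq)), function(i)
    segment_frame(get_frame(seq, i), params))
}
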