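round_half_up <- function(x) floor(x + 0.5)

#' Segmentation parameters
#'
#' Bundles the calibrated window size with the fixed conditioning parameters
#' of the segmentation stage. The processing window side `w` comes from the
#' area calibration (see [compute_window_size()]); the median-filter window
#' is tied to it as `w_median = max(1, round(w / 8))`.
#'
#' @param w processing window side in px (integer, >= 3).
#' @param a scale factor used to derive `w` from cell areas (default 2).
#' @param k_T Niblack gain (default 1).
#' @param open_radius structuring-disk radius for the binary opening
#'   (default 3).
#' @param dilate_radius structuring-disk radius for the final dilation
#'   (default 1).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(w, a = 2, k_T = 1, open_radius = 3,
                                dilate_radius = 1) {
  w <- as.integer(w)
  if (w < 3) stop("window side `w` must be >= 3", call. = FALSE)
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  structure(
    list(w = w, a = a, w_median = max(1L, as.integer(round_half_up(w / 8))),
         k_T = k_T, open_radius = open_radius, dilate_radius = dilate_radius),
    class = "segmentation_params")
}

#' @export
print.segmentation_params <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_params> w = %d, w_median = %d, k_T = %g,",
                     " open r = %g, dilate r = %g\n"),
              x$w, x$w_median, x$k_T, x$open_radius, x$dilate_radius))
  invisible(x)
}

#' Window size from sample cell areas
#'
#' Under the assumption that each cell fits a `w` x `w` square, the
#' processing window side is `w = round(a * sqrt(mean(areas)))` (round half
#' up), clamped to at least 3 px. More sampled ROIs give a better area
#' estimate but do not change the formula.
#'
#' @param roi_areas numeric vector of sample ROI areas in px^2 (all > 0).
#' @param a scale factor (default 2, the value minimising the segmentation
#'   mask error in calibration experiments).
#' @return integer window side.
#' @export
compute_window_size <- function(roi_areas, a = 2) {
  if (length(roi_areas) == 0 || any(!is.finite(roi_areas)) ||
      any(roi_areas <= 0))
    stop("`roi_areas` must be a non-empty vector of positive areas",
         call. = FALSE)
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  max(3L, as.integer(round_half_up(a * sqrt(mean(roi_areas)))))
}

#' Mean square error between two binary masks
#'
#' Masks are converted to 0/1 reals and the mean squared pixel difference is
#' taken, i.e. the fraction of disagreeing pixels. Symmetric, bounded in
#' \[0, 1\].
#'
#' @param mask_a,mask_b logical (or 0/1) matrices of equal dimensions.
#' @return scalar MSE.
#' @export
mask_mse <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask dimensions differ", call. = FALSE)
  mean((as.numeric(mask_a) - as.numeric(mask_b))^2)
}

#' Calibrate the window scale factor against ground-truth masks
#'
#' For each candidate scale `a`, the full segmentation pipeline is run on the
#' supplied raw 340-nm frames with the window implied by the sample areas,
#' and the mean [mask_mse()] against the expert ground-truth masks is
#' recorded. The best `a` is the argmin of that curve (ties broken towards
#' the smaller `a`).
#'
#' @param ground_truth_masks list of logical matrices (expert segmentations).
#' @param raw_frames list of 8-bit matrices, one per ground-truth mask.
#' @param roi_areas sample cell areas in px^2 used to derive `w` from `a`.
#' @param a_grid numeric vector of candidate scale factors.
#' @return list with `best_a`, `best_mse` and `curve` (data frame with
#'   columns `a`, `w`, `mse`).
#' @export
calibrate_a <- function(ground_truth_masks, raw_frames, roi_areas,
                        a_grid = seq(0.5, 4, by = 0.25)) {
  if (length(ground_truth_masks) != length(raw_frames))
    stop("masks and frames must correspond one-to-one", call. = FALSE)
  if (length(a_grid) == 0) stop("`a_grid` is empty", call. = FALSE)
  a_grid <- sort(a_grid)
  mse <- numeric(length(a_grid))
  w_used <- integer(length(a_grid))
  for (i in seq_along(a_grid)) {
    w_used[i] <- compute_window_size(roi_areas, a_grid[i])
    params <- segmentation_params(w = w_used[i], a = a_grid[i])
    errs <- mapply(function(frame, truth) {
      lf <- segment_frame(frame, params)
      mask_mse(lf$binary, truth)
    }, raw_frames, ground_truth_masks)
    mse[i] <- mean(errs)
  }
  best <- which.min(mse)  # which.min takes the first minimum: smaller a wins
  list(best_a = a_grid[best], best_mse = mse[best],
       curve = data.frame(a = a_grid, w = w_used, mse = mse))
}
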