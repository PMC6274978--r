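#' Extract the calcium-profile sample for one ROI
#'
#' Mean of the ratio values inside the `w` x `w` square ROI centred on the
#' cell's current centroid. The centre is rounded to the nearest pixel; for
#' even `w` the extra row/column lies below/right of the centre. ROIs are
#' cropped at the image borders rather than rejected, since injury drives
#' cells towards the edges.
#'
#' @param ratio_frame numeric matrix of ratio values.
#' @param center numeric `c(x, y)` in px (0-based, x = column).
#' @param w ROI side in px.
#' @return scalar mean ratio (the CP sample).
#' @export
extract_cp <- function(ratio_frame, center, w) {
  nr <- nrow(ratio_frame)
  nc <- ncol(ratio_frame)
  cx <- round_half_up(center[1])
  cy <- round_half_up(center[2])
  lo <- (w - 1) %/% 2
  hi <- w %/% 2
  rows <- max(0, cy - lo):min(nr - 1, cy + hi)
  cols <- max(0, cx - lo):min(nc - 1, cx + hi)
  if (cy + hi < 0 || cy - lo > nr - 1 || cx + hi < 0 || cx - lo > nc - 1)
    stop("ROI lies entirely outside the image", call. = FALSE)
  mean(ratio_frame[rows + 1, cols + 1])
}

#' Tracked-cell density at one frame
#'
#' The per-frame figure of merit `rho_i = 100 * n_online / n_blobs`
#' (percent). It can exceed 100 when transiently vanished cells keep more
#' ROIs ONLINE than there are binary objects in the frame.
#'
#' @param n_online number of ONLINE cells at the frame.
#' @param n_blobs number of binary objects at the frame (> 0).
#' @return percentage.
#' @export
density_metric <- function(n_online, n_blobs) {
  if (n_blobs <= 0) stop("`n_blobs` must be positive", call. = FALSE)
  100 * n_online / n_blobs
}

#' Summarise the per-frame density series
#'
#' @param rho data frame as returned in `tracking_result$rho`. Frames with
#'   undefined density (zero binary objects) are skipped.
#' @return named list `rho_max`, `rho_min`, `rho_mean` (percent).
#' @export
summarize_rho <- function(rho) {
  v <- rho$rho[is.finite(rho$rho)]
  list(rho_max = max(v), rho_min = min(v), rho_mean = mean(v))
}

#' Mean square error between two calcium profiles
#'
#' @param cp_a,cp_b numeric series of equal length.
#' @return scalar MSE.
#' @export
profile_mse <- function(cp_a, cp_b) {
  if (length(cp_a) != length(cp_b))
    stop("profile lengths differ", call. = FALSE)
  mean((cp_a - cp_b)^2)
}

#' Per-cell summary of a tracking run
#'
#' For every cell: the mean calcium profile over the frames where the cell
#' was actually found (missing frames contribute no sample -- they would
#' otherwise introduce false negatives in the Ca2+ signal), the fraction of
#' frames found, and the final status. A never-found cell reports `NA`.
#'
#' @param result a `tracking_result` (or its `tracks` list).
#' @return data frame with columns `cell_id`, `mean_cp`, `frames_found`,
#'   `fraction_found`, `status`.
#' @export
summarize_tracks <- function(result) {
  tracks <- if (inherits(result, "tracking_result")) result$tracks else result
  do.call(rbind, lapply(tracks, function(tr) {
    found <- !is.na(tr$history$cp)
    data.frame(
      cell_id = tr$cell_id,
      mean_cp = if (any(found)) mean(tr$history$cp[found]) else NA_real_,
      frames_found = sum(found),
      fraction_found = mean(found),
      status = tr$status)
  }))
}

#' Long-format profile table of a tracking run
#'
#' One row per (cell, frame) with the status, position and calcium-profile
#' sample; frames where the cell was missing (or already OFFLINE) carry the
#' status and empty positions.
#'
#' @param result a `tracking_result` (or its `tracks` list).
#' @return data frame with columns `cell_id`, `frame`, `status`, `x`, `y`,
#'   `cp_value`, `found_by`.
#' @export
profile_table <- function(result) {
  tracks <- if (inherits(result, "tracking_result")) result$tracks else result
  do.call(rbind, lapply(tracks, function(tr) {
    h <- tr$history
    # frames after the OFFLINE flip have no recorded rows: carry the status
    h$status[is.na(h$status)] <- tr$status
    h$found_by[is.na(h$found_by)] <- "NONE"
    data.frame(cell_id = tr$cell_id, frame = h$frame, status = h$status,
               x = h$x, y = h$y, cp_value = h$cp, found_by = h$found_by)
  }))
}

#' Write profiles and per-cell summary to CSV
#'
#' Writes the long-format profile table to `destination` and the per-cell
#' summary (including each cell's mean CP) next to it, with suffix
#' `_summary.csv`. Values round-trip at full double precision.
#'
#' @param result a `tracking_result` (or its `tracks` list).
#' @param destination path of the profiles CSV.
#' @return invisibly, `c(profiles = ..., summary = ...)` paths.
#' @export
write_profiles <- function(result, destination) {
  profiles <- profile_table(result)
  summary <- summarize_tracks(result)
  spath <- sub("(\\.csv)?$", "_summary.csv", destination)
  # 17 significant digits: lossless double round-trip
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    df[df == "NA"] <- NA
    df
  }
  utils::write.csv(fmt(profiles), destination, row.names = FALSE, na = "")
  utils::write.csv(fmt(summary), spath, row.names = FALSE, na = "")
  invisible(c(profiles = destination, summary = spath))
}

#' Fraction of correct frame-level associations
#'
#' Validation helper against ground truth: a (cell, frame) association is
#' correct when the cell was rendered in that frame and the track that
#' started on it reports a position within `tol` px of the true one. Frames
#' where the cell was not rendered are excluded; a position claimed in such
#' a frame counts as wrong.
#'
#' Each track is paired with the ground-truth cell nearest to it at frame 1
#' (segmentation label order need not follow the generator's cell order).
#'
#' @param result a `tracking_result` run on a phantom.
#' @param truth data frame with columns `cell`, `frame`, `x`, `y`,
#'   `rendered` as returned by [gen_phantom()].
#' @param tol tolerance radius in px (default 3).
#' @return fraction in \[0, 1\].
#' @export
association_accuracy <- function(result, truth, tol = 3) {
  prof <- profile_table(result)
  ids <- unique(prof$cell_id)
  t1 <- truth[truth$frame == 1, ]
  ok <- 0L
  n <- 0L
  for (id in ids) {
    pp <- prof[prof$cell_id == id, ]
    d2 <- (t1$x - pp$x[1])^2 + (t1$y - pp$y[1])^2
    tt <- truth[truth$cell == t1$cell[which.min(d2)], ]
    m <- merge(tt, pp, by = "frame")
    claimed <- !is.na(m$x.y)
    hit <- claimed & m$rendered &
      sqrt((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2) <= tol
    n <- n + sum(m$rendered | claimed)
    ok <- ok + sum(hit, na.rm = TRUE)
  }
  ok / n
}
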