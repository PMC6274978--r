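new_track <- function(cell_id, label, kernel, k, model) {
  history <- data.frame(
    frame = seq_len(k), x = NA_real_, y = NA_real_, cp = NA_real_,
    found_by = NA_character_, status = NA_character_)
  # kernel: pixel indices of the cell's most recently found component; it
  # persists across missing frames so a transiently vanished cell can be
  # re-acquired by intersection when it reappears
  list(cell_id = cell_id, track_label = label, kernel = kernel,
       status = "ONLINE", reliability = 0L, model = model, history = history)
}

#' Candidate labels by kernel intersection
#'
#' The mask of a tracked component in frame n-1 (its kernel) is overlapped
#' with the labelled frame n; the logical AND picks out every component of
#' frame n sharing at least one pixel with the kernel.
#'
#' @param prev_cell_mask logical matrix: the tracked component in the
#'   previous frame.
#' @param current a `labeled_frame` for the current frame.
#' @return sorted integer vector of candidate labels (possibly empty).
#' @export
intersect_kernel <- function(prev_cell_mask, current) {
  if (!identical(dim(prev_cell_mask), dim(current$labels)))
    stop("mask dimensions differ", call. = FALSE)
  sort(setdiff(unique(current$labels[prev_cell_mask]), 0L))
}

#' Resolve the new tracking label for one cell
#'
#' A single intersection candidate is accepted outright. Otherwise the
#' Kalman-predicted position decides: if the prediction falls inside a
#' component (restricted to the candidates when there are any), that
#' component wins; failing that, the candidate (or, with no candidates, any)
#' component whose centroid lies nearest to the prediction within the gate
#' radius wins. If nothing qualifies the cell is missing in this frame.
#'
#' @param candidates integer labels from [intersect_kernel()].
#' @param prediction numeric `c(x, y)`: predicted position in px.
#' @param current a `labeled_frame`.
#' @param gate gating radius in px for the nearest-centroid fallback
#'   (half the processing window side).
#' @return list with `label` (integer or `NA` when missing) and `found_by`
#'   (`"INTERSECTION"`, `"KALMAN"` or `"NONE"`).
#' @export
resolve_label <- function(candidates, prediction, current, gate) {
  if (length(candidates) == 1)
    return(list(label = candidates, found_by = "INTERSECTION"))
  px <- round_half_up(prediction[1])
  py <- round_half_up(prediction[2])
  lab <- current$labels
  if (py >= 0 && py < nrow(lab) && px >= 0 && px < ncol(lab)) {
    hit <- lab[py + 1, px + 1]
    if (hit > 0 && (length(candidates) == 0 || hit %in% candidates))
      return(list(label = hit, found_by = "KALMAN"))
  }
  comp <- current$components
  if (length(candidates) > 0) comp <- comp[comp$label %in% candidates, ]
  if (nrow(comp) > 0) {
    d2 <- (comp$x - prediction[1])^2 + (comp$y - prediction[2])^2
    best <- which.min(d2)
    if (d2[best] <= gate^2)
      return(list(label = comp$label[best], found_by = "KALMAN"))
  }
  list(label = NA_integer_, found_by = "NONE")
}

track_step_one <- function(track, current, ratio_frame, params, rl,
                           frame_idx) {
  track$model <- kalman_predict(track$model)
  candidates <- sort(setdiff(unique(current$labels[track$kernel]), 0L))
  res <- resolve_label(candidates, kalman_position(track$model), current,
                       gate = params$w / 2)
  if (!is.na(res$label)) {
    comp <- current$components
    pos <- c(comp$x[comp$label == res$label], comp$y[comp$label == res$label])
    cp <- extract_cp(ratio_frame, pos, params$w)
    track$model <- kalman_correct(track$model, pos)
    track$track_label <- res$label
    track$kernel <- which(current$labels == res$label)
    track$reliability <- 0L
    track$history[frame_idx, c("x", "y", "cp")] <- c(pos[1], pos[2], cp)
    track$history$found_by[frame_idx] <- res$found_by
  } else {
    track$track_label <- NA_integer_
    track$reliability <- track$reliability + 1L
    track$history$found_by[frame_idx] <- "NONE"
    if (track$reliability >= rl) track$status <- "OFFLINE"
  }
  track$history$status[frame_idx] <- track$status
  track
}

#' One tracking iteration over a frame pair
#'
#' Advances every ONLINE track from frame n-1 to frame n: the cell's kernel
#' (the mask of its most recently found component, normally from frame n-1)
#' is intersected with frame n to propose candidate components,
#' [resolve_label()] settles the tracking label with Kalman support, and on
#' success the centroid and calcium-profile sample are stored, the kernel
#' replaced and the reliability counter reset. A missing cell increments its
#' counter, keeps its kernel, and lets the filter coast (prediction only,
#' one predict per missing frame, no correction); when the counter reaches
#' the reliability limit the track is tagged OFFLINE permanently and is no
#' longer searched. OFFLINE tracks are skipped entirely.
#'
#' @param prev,current `labeled_frame` objects for frames n-1 and n (`prev`
#'   documents the iteration contract; kernels are carried on the tracks).
#' @param ratio_frame numeric matrix: the ratio frame aligned with `current`.
#' @param tracks list of track records as built by [run_tracking()].
#' @param params a [segmentation_params()] object (supplies the ROI side and
#'   gate).
#' @param rl reliability limit: consecutive missing frames allowed before a
#'   track goes OFFLINE (default 3).
#' @param frame_idx index of `current` in the sequence.
#' @return the updated list of tracks.
#' @export
step_tracking <- function(prev, current, ratio_frame, tracks, params,
                          rl = 3L, frame_idx) {
  for (i in seq_along(tracks)) {
    if (tracks[[i]]$status != "ONLINE") next
    tracks[[i]] <- track_step_one(tracks[[i]], current, ratio_frame,
                                  params, rl, frame_idx)
  }
  tracks
}

init_tracks <- function(first, ratio_frame, selections, params, kalman_stats,
                        sigma_obs, period, k) {
  comp <- first$components
  if (identical(selections, "all")) {
    sel <- comp$label
  } else {
    sel <- vapply(seq_len(nrow(selections)), function(i) {
      px <- round_half_up(selections$x[i])
      py <- round_half_up(selections$y[i])
      hit <- if (py >= 0 && py < nrow(first$labels) &&
                 px >= 0 && px < ncol(first$labels))
        first$labels[py + 1, px + 1] else 0L
      if (hit > 0) return(as.integer(hit))
      d2 <- (comp$x - selections$x[i])^2 + (comp$y - selections$y[i])^2
      as.integer(comp$label[which.min(d2)])
    }, integer(1))
  }
  tracks <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    pos <- c(comp$x[comp$label == sel[i]], comp$y[comp$label == sel[i]])
    model <- build_kalman(kalman_stats, sigma_obs, period, pos)
    tr <- new_track(sprintf("A%03d", i), sel[i],
                    which(first$labels == sel[i]), k, model)
    tr$history[1, c("x", "y", "cp")] <-
      c(pos[1], pos[2], extract_cp(ratio_frame, pos, params$w))
    tr$history$found_by[1] <- "INTERSECTION"
    tr$history$status[1] <- "ONLINE"
    tracks[[i]] <- tr
  }
  tracks
}

#' Track selected cells through a segmented sequence
#'
#' Initialises one track per selected component of frame 1 (cell ids
#' `"A001"`, `"A002"`, ... in selection order), then iterates
#' [step_tracking()] over consecutive frame pairs (frames 1-2 up to
#' (k-1)-k). The per-frame tracked-cell density `rho = 100 * ONLINE cells /
#' binary objects` is recorded as the performance figure of merit.
#'
#' @param labeled_seq list of `labeled_frame` objects from
#'   [segment_sequence()].
#' @param ratio_seq the aligned `"RATIO"` [frame_sequence()].
#' @param selections `"all"` to track every component detected in frame 1,
#'   or a data frame with columns `x`, `y` of seed points (0-based px).
#' @param params a [segmentation_params()] object.
#' @param rl reliability limit (default 3).
#' @param kalman_stats jerk statistics for the motion model
#'   (default [default_kalman_params()]).
#' @param sigma_obs observation sigmas in px (default `c(0.001, 0.001)`).
#' @return an object of class `tracking_result`: list with `tracks` (list of
#'   track records), `rho` (data frame `frame`, `n_online`, `n_blobs`,
#'   `rho`) and `params`.
#' @export
run_tracking <- function(labeled_seq, ratio_seq, selections = "all", params,
                         rl = 3L, kalman_stats = default_kalman_params(),
                         sigma_obs = c(0.001, 0.001)) {
  k <- length(labeled_seq)
  if (k < 2) stop("tracking needs at least two frames", call. = FALSE)
  if (n_frames(ratio_seq) != k)
    stop("labeled and ratio sequences are not aligned", call. = FALSE)
  if (identical(selections, "all") &&
      nrow(labeled_seq[[1]]$components) == 0) {
    warning("no components in frame 1; nothing to track", call. = FALSE)
    return(structure(list(tracks = list(),
                          rho = data.frame(frame = integer(),
                                           n_online = integer(),
                                           n_blobs = integer(),
                                           rho = numeric()),
                          params = params),
                     class = "tracking_result"))
  }
  tracks <- init_tracks(labeled_seq[[1]], get_frame(ratio_seq, 1), selections,
                        params, kalman_stats, sigma_obs, ratio_seq$period, k)
  rho <- data.frame(frame = seq_len(k), n_online = NA_integer_,
                    n_blobs = NA_integer_, rho = NA_real_)
  count_online <- function() sum(vapply(tracks, function(t)
    t$status == "ONLINE", logical(1)))
  record_rho <- function(f) {
    n_on <- count_online()
    n_bl <- nrow(labeled_seq[[f]]$components)
    rho[f, c("n_online", "n_blobs")] <<- c(n_on, n_bl)
    rho$rho[f] <<- if (n_bl > 0) 100 * n_on / n_bl else NA_real_
  }
  record_rho(1)
  for (f in 2:k) {
    tracks <- step_tracking(labeled_seq[[f - 1]], labeled_seq[[f]],
                            get_frame(ratio_seq, f), tracks, params, rl, f)
    record_rho(f)
  }
  if (anyNA(rho$rho))
    warning("frames with zero binary objects skipped from rho summaries",
            call. = FALSE)
  structure(list(tracks = tracks, rho = rho, params = params),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  n_on <- sum(vapply(x$tracks, function(t) t$status == "ONLINE", logical(1)))
  cat(sprintf(
    "<tracking_result> %d track(s), %d ONLINE, %d frame(s), mean rho %.2f%%\n",
    length(x$tracks), n_on, nrow(x$rho), mean(x$rho$rho, na.rm = TRUE)))
  invisible(x)
}
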