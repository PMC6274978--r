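render_disk <- function(frame, cx, cy, radius, level, bg) {
  nr <- nrow(frame)
  nc <- ncol(frame)
  r0 <- max(0, floor(cy - radius - 1)):min(nr - 1, ceiling(cy + radius + 1))
  c0 <- max(0, floor(cx - radius - 1)):min(nc - 1, ceiling(cx + radius + 1))
  if (length(r0) == 0 || length(c0) == 0) return(frame)
  d <- sqrt(outer((r0 - cy)^2, (c0 - cx)^2, `+`))
  # linear edge falloff over one pixel approximates area coverage
  cov <- pmin(1, pmax(0, radius + 0.5 - d))
  frame[r0 + 1, c0 + 1] <- frame[r0 + 1, c0 + 1] + (level - bg) * cov
  frame
}

quantize8 <- function(frame) pmin(pmax(round(frame), 0), 255)

#' Sinusoidal single-cell test sequence
#'
#' Renders one bright blob whose true centre follows `x = c` (constant) and
#' `y = y0 + A cos(2 pi f t)` with `t` uniform on \[0, 1): `f` counts whole
#' cycles over the sequence, and the peak-to-peak excursion is `2 A`. This
#' is the deterministic benchmark trajectory used to exercise the Kalman
#' estimator in isolation from segmentation.
#'
#' @param bias_c constant x coordinate in px (default mid-width).
#' @param peak_to_peak vertical excursion in px (default 36).
#' @param f number of full cycles over the sequence (default 4).
#' @param n_frames number of frames (default 100, >= 10).
#' @param object_area blob area in px^2 (default 100, the typical calibrated
#'   cell area).
#' @param dropout_frames integer frame indices at which the blob is not
#'   rendered (default none).
#' @param dim image height and width in px (default `c(96, 96)`).
#' @param bg,peak background and blob 8-bit intensities.
#' @param noise_sd Gaussian intensity noise sd (default 0, deterministic).
#' @param period sampling interval in seconds (default 3).
#' @param seed RNG seed, used only when `noise_sd > 0`.
#' @return list with `seq` (an `"EX340"` [frame_sequence()]) and `truth`
#'   (data frame `frame`, `x`, `y`, `rendered`).
#' @export
gen_sinusoid_test <- function(bias_c = NULL, peak_to_peak = 36, f = 4,
                              n_frames = 100, object_area = 100,
                              dropout_frames = integer(), dim = c(96, 96),
                              bg = 20, peak = 200, noise_sd = 0, period = 3,
                              seed = 1) {
  if (n_frames < 10) stop("need at least 10 frames", call. = FALSE)
  if (peak_to_peak >= dim[1])
    stop("peak-to-peak amplitude exceeds image height", call. = FALSE)
  if (is.null(bias_c)) bias_c <- (dim[2] - 1) / 2
  A <- peak_to_peak / 2
  y0 <- (dim[1] - 1) / 2
  t <- (seq_len(n_frames) - 1) / n_frames
  x <- rep(bias_c, n_frames)
  y <- y0 + A * cos(2 * pi * f * t)
  radius <- sqrt(object_area / pi)
  if (any(y - radius < 0 | y + radius > dim[1] - 1 |
          x - radius < 0 | x + radius > dim[2] - 1))
    stop("trajectory leaves the frame", call. = FALSE)
  if (noise_sd > 0) set.seed(seed)
  stack <- array(bg, c(dim[1], dim[2], n_frames))
  for (i in seq_len(n_frames)) {
    fr <- matrix(bg, dim[1], dim[2])
    if (!(i %in% dropout_frames))
      fr <- render_disk(fr, x[i], y[i], radius, peak, bg)
    if (noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), 0, noise_sd), dim[1])
    stack[, , i] <- quantize8(fr)
  }
  list(seq = frame_sequence(stack, "EX340", period),
       truth = data.frame(frame = seq_len(n_frames), x = x, y = y,
                          rendered = !(seq_len(n_frames) %in% dropout_frames)))
}

#' Per-axis mean square error between trajectories
#'
#' @param estimated,truth data frames (or matrices) with columns `x`, `y`
#'   and equal row counts.
#' @return named numeric `c(mse_x, mse_y)` in px^2.
#' @export
trajectory_mse <- function(estimated, truth) {
  estimated <- as.data.frame(estimated)
  truth <- as.data.frame(truth)
  if (nrow(estimated) != nrow(truth))
    stop("trajectory lengths differ", call. = FALSE)
  c(mse_x = mean((estimated$x - truth$x)^2),
    mse_y = mean((estimated$y - truth$y)^2))
}

blob_centroid <- function(frame, thr) {
  idx <- which(frame > thr, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  c(mean(idx[, "col"]) - 1, mean(idx[, "row"]) - 1)
}

#' Kalman benchmark on the sinusoidal test trajectory
#'
#' Measures blob centroids on the rendered sinusoid sequence and runs the
#' constant-acceleration filter over them. In `"predict_correct"` mode every
#' frame is corrected with its measured centroid. In `"prediction_only"`
#' mode the observations of `gap_frames` (default a contiguous 5-frame block
#' at mid-sequence) are withheld and the filter coasts on prediction alone
#' through the gap, emulating a transiently vanished cell. The per-axis mean
#' square error of the estimated trajectory against the analytic one is
#' returned together with the series.
#'
#' @param mode `"predict_correct"` or `"prediction_only"`.
#' @param gap_frames frames with withheld observations
#'   (`"prediction_only"` mode only); `NULL` selects the default mid-run
#'   5-frame block.
#' @param stats,sigma_obs filter noise parameters, defaulting to
#'   [default_kalman_params()].
#' @param ... passed to [gen_sinusoid_test()].
#' @return list with `mse` (named `mse_x`, `mse_y`), `estimate`, `truth` and
#'   `observations` data frames.
#' @export
sinusoid_kalman_test <- function(mode = c("predict_correct",
                                          "prediction_only"),
                                 gap_frames = NULL,
                                 stats = default_kalman_params(),
                                 sigma_obs = c(0.001, 0.001), ...) {
  mode <- match.arg(mode)
  sim <- gen_sinusoid_test(...)
  p <- n_frames(sim$seq)
  if (mode == "prediction_only" && is.null(gap_frames)) {
    mid <- p %/% 2
    gap_frames <- (mid - 2):(mid + 2)
  }
  thr <- (max(sim$seq$frames) + min(sim$seq$frames)) / 2
  obs <- t(vapply(seq_len(p), function(i)
    blob_centroid(get_frame(sim$seq, i), thr), numeric(2)))
  model <- build_kalman(stats, sigma_obs, sim$seq$period, obs[1, ])
  est <- matrix(NA_real_, p, 2)
  est[1, ] <- obs[1, ]
  for (i in 2:p) {
    model <- kalman_predict(model)
    observed <- !(mode == "prediction_only" && i %in% gap_frames) &&
      !anyNA(obs[i, ])
    if (observed) model <- kalman_correct(model, obs[i, ])
    est[i, ] <- kalman_position(model)
  }
  estimate <- data.frame(frame = seq_len(p), x = est[, 1], y = est[, 2])
  list(mse = trajectory_mse(estimate, sim$truth),
       estimate = estimate, truth = sim$truth,
       observations = data.frame(frame = seq_len(p), x = obs[, 1],
                                 y = obs[, 2]))
}

waveform_value <- function(cp, frame) {
  with(cp, ifelse(frame < peak_frame, baseline,
                  plateau + (baseline + peak_amp - plateau) *
                    exp(-(frame - peak_frame) / tau)))
}

#' Phantom specification
#'
#' Describes a multi-cell dual-wavelength phantom: bright elliptical-to-round
#' cell blobs on a noisy dark background, slow random motion with an
#' optional jump event, per-cell transient disappearance, and a biphasic
#' calcium waveform (baseline, rapid peak, decay towards a plateau) that
#' modulates the 340/380 channel pair so the pixel ratio carries the target
#' profile.
#'
#' @param dim image height and width in px.
#' @param n_cells number of cells.
#' @param n_frames number of frames.
#' @param area_mean,area_sd cell area distribution in px^2.
#' @param motion_sd per-frame displacement sd in px of the shared tissue
#'   drift. Endothelial cells ride the slow contraction of the underlying
#'   smooth-muscle layer, so the monolayer moves coherently: the drift is
#'   common to all cells and temporally correlated.
#' @param motion_smooth AR(1) correlation of successive drift displacements
#'   (default 0.8); 0 gives a white random walk.
#' @param jitter_sd per-frame sd in px of the independent per-cell jitter on
#'   top of the drift (default 0.1). Keeping it small preserves the
#'   monolayer geometry: neighbouring cells do not wander into each other.
#' @param jump optional list `(frame, dx, dy, cells)`: an abrupt
#'   displacement applied at `frame` to `cells` (`NULL` = all), emulating a
#'   mechanical-injury jolt.
#' @param dropout list, per cell, of frame indices where the cell is not
#'   rendered (transient fluorescence loss); `NULL` for none. Frame 1 must
#'   remain rendered for every cell.
#' @param cp list `(baseline, peak_amp, peak_frame, plateau, tau)` of the
#'   calcium waveform on the ratio scale.
#' @param cell_level 8-bit brightness scale of cells (both channels equal at
#'   ratio 1).
#' @param bg380 8-bit background of the 380-nm channel; the 340-nm
#'   background is `round(bg380 * baseline)` so the background ratio sits at
#'   the baseline.
#' @param noise_sd Gaussian intensity noise sd in 8-bit counts (default 5).
#' @param period sampling interval in seconds (default 3).
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(256, 256), n_cells = 30, n_frames = 50,
                         area_mean = 100, area_sd = 10, motion_sd = 0.5,
                         motion_smooth = 0.8, jitter_sd = 0.1, jump = NULL,
                         dropout = NULL,
                         cp = list(baseline = 0.85, peak_amp = 0.25,
                                   peak_frame = 20, plateau = 0.95,
                                   tau = 8),
                         cell_level = 140, bg380 = 40, noise_sd = 5,
                         period = 3, seed = 1) {
  structure(list(dim = dim, n_cells = n_cells, n_frames = n_frames,
                 area_mean = area_mean, area_sd = area_sd,
                 motion_sd = motion_sd, motion_smooth = motion_smooth,
                 jitter_sd = jitter_sd, jump = jump, dropout = dropout,
                 cp = cp, cell_level = cell_level, bg380 = bg380,
                 noise_sd = noise_sd, period = period, seed = seed),
            class = "phantom_spec")
}

place_cells <- function(spec, radii) {
  margin <- max(radii) + 8
  min_sep <- 2 * max(radii) + 12
  centers <- matrix(NA_real_, spec$n_cells, 2)
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in 1:2000) {
      cand <- c(stats::runif(1, margin, spec$dim[2] - 1 - margin),
                stats::runif(1, margin, spec$dim[1] - 1 - margin))
      if (i == 1 || all((centers[seq_len(i - 1), 1] - cand[1])^2 +
                        (centers[seq_len(i - 1), 2] - cand[2])^2 >=
                        min_sep^2)) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not pack ", spec$n_cells, " cells into the image",
           call. = FALSE)
  }
  centers
}

#' Generate a dual-wavelength phantom with ground truth
#'
#' Renders the 340- and 380-nm channel pair of a moving multi-cell phantom.
#' Cell brightness is `cell_level * sqrt(cp)` at 340 nm and
#' `cell_level / sqrt(cp)` at 380 nm, so the noise-free pixel ratio inside a
#' cell equals its calcium waveform value. Ground truth covers every
#' rendered frame of every cell; the ground-truth calcium profile is the
#' ROI mean of the noise-free ratio image at the true centroid (i.e. the
#' profile an ideal extractor would report), computed with ROI side `w =
#' round(2 sqrt(area_mean))`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `seq340`, `seq380` ([frame_sequence()] pair), `truth`
#'   (data frame `cell`, `frame`, `x`, `y`, `rendered`), `truth_cp` (data
#'   frame `cell`, `frame`, `cp`), `waveform` (analytic per-frame series)
#'   and `w` (ROI side used for the truth profiles).
#' @export
gen_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  m <- spec$dim[1]
  n <- spec$dim[2]
  k <- spec$n_frames
  areas <- pmax(spec$area_mean - 3 * spec$area_sd,
                stats::rnorm(spec$n_cells, spec$area_mean, spec$area_sd))
  radii <- sqrt(areas / pi)
  centers <- place_cells(spec, radii)
  # coherent tissue drift (AR(1), marginal sd = motion_sd) + per-cell jitter
  pos <- array(NA_real_, c(spec$n_cells, k, 2))
  pos[, 1, ] <- centers
  phi <- spec$motion_smooth
  drift <- stats::rnorm(2, 0, spec$motion_sd)
  for (f in 2:k) {
    drift <- phi * drift +
      stats::rnorm(2, 0, spec$motion_sd * sqrt(1 - phi^2))
    step <- matrix(drift, spec$n_cells, 2, byrow = TRUE) +
      matrix(stats::rnorm(spec$n_cells * 2, 0, spec$jitter_sd),
             spec$n_cells, 2)
    if (!is.null(spec$jump) && f == spec$jump$frame) {
      who <- if (is.null(spec$jump$cells)) seq_len(spec$n_cells)
             else spec$jump$cells
      step[who, 1] <- step[who, 1] + spec$jump$dx
      step[who, 2] <- step[who, 2] + spec$jump$dy
    }
    pos[, f, ] <- pos[, f - 1, ] + step
    pos[, f, 1] <- pmin(pmax(pos[, f, 1], radii + 1), n - 2 - radii)
    pos[, f, 2] <- pmin(pmax(pos[, f, 2], radii + 1), m - 2 - radii)
  }
  rendered <- matrix(TRUE, spec$n_cells, k)
  if (!is.null(spec$dropout)) {
    for (i in seq_along(spec$dropout)) {
      drop <- setdiff(spec$dropout[[i]], 1L)  # frame 1 always rendered
      rendered[i, drop] <- FALSE
    }
  }
  wave <- waveform_value(spec$cp, seq_len(k))
  bg340 <- round(spec$bg380 * spec$cp$baseline)
  lvl340 <- spec$cell_level * sqrt(wave)
  lvl380 <- spec$cell_level / sqrt(wave)
  s340 <- array(0, c(m, n, k))
  s380 <- array(0, c(m, n, k))
  w <- as.integer(round_half_up(2 * sqrt(spec$area_mean)))
  truth_cp <- matrix(NA_real_, spec$n_cells, k)
  for (f in seq_len(k)) {
    f340 <- matrix(bg340, m, n)
    f380 <- matrix(spec$bg380, m, n)
    for (i in seq_len(spec$n_cells)) {
      if (!rendered[i, f]) next
      f340 <- render_disk(f340, pos[i, f, 1], pos[i, f, 2], radii[i],
                          lvl340[f], bg340)
      f380 <- render_disk(f380, pos[i, f, 1], pos[i, f, 2], radii[i],
                          lvl380[f], spec$bg380)
    }
    clean_ratio <- quantize8(f340) / pmax(1, quantize8(f380))
    for (i in seq_len(spec$n_cells))
      if (rendered[i, f])
        truth_cp[i, f] <- extract_cp(clean_ratio, pos[i, f, ], w)
    if (spec$noise_sd > 0) {
      f340 <- f340 + matrix(stats::rnorm(m * n, 0, spec$noise_sd), m, n)
      f380 <- f380 + matrix(stats::rnorm(m * n, 0, spec$noise_sd), m, n)
    }
    s340[, , f] <- quantize8(f340)
    s380[, , f] <- quantize8(f380)
  }
  grid <- expand.grid(frame = seq_len(k), cell = seq_len(spec$n_cells))
  truth <- data.frame(
    cell = grid$cell, frame = grid$frame,
    x = pos[cbind(grid$cell, grid$frame, 1)],
    y = pos[cbind(grid$cell, grid$frame, 2)],
    rendered = rendered[cbind(grid$cell, grid$frame)])
  list(seq340 = frame_sequence(s340, "EX340", spec$period),
       seq380 = frame_sequence(s380, "EX380", spec$period),
       truth = truth,
       truth_cp = data.frame(cell = grid$cell, frame = grid$frame,
                             cp = truth_cp[cbind(grid$cell, grid$frame)]),
       waveform = wave, w = w)
}

#' Random transient dropout schedule
#'
#' Builds a per-cell dropout list for [phantom_spec()]: short runs of
#' consecutive missing frames are inserted at random until roughly
#' `rate` of each cell's frames (after frame 1) are missing.
#'
#' @param n_cells,n_frames phantom dimensions.
#' @param rate target fraction of missing frames per cell (default 0.1).
#' @param run_range integer range of run lengths (default 1:2; keep below
#'   the reliability limit for transient - as opposed to terminal -
#'   disappearance).
#' @param seed RNG seed.
#' @return list of integer vectors, one per cell.
#' @export
make_dropout_schedule <- function(n_cells, n_frames, rate = 0.1,
                                  run_range = 1:2, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) {
    target <- rate * (n_frames - 1)
    drop <- integer()
    guard <- 0
    while (length(drop) < target && guard < 100) {
      guard <- guard + 1
      len <- sample(run_range, 1)
      start <- sample(2:(n_frames - len + 1), 1)
      run <- start:(start + len - 1)
      # keep runs separated so consecutive-miss counts stay below RL
      if (!any(c(run, run - 1, run + 1) %in% drop)) drop <- c(drop, run)
    }
    sort(drop)
  })
}
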