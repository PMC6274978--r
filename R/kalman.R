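#' Jerk statistics from manually tracked positions
#'
#' Cell motion is modelled as constant acceleration driven by white jerk
#' (the third time-derivative of position). The jerk noise level is
#' estimated from position series: per series, the jerk is the third forward
#' difference of position divided by `period^3`; its sample standard
#' deviation (denominator n - 1) gives one per-cell sigma, and the module
#' estimate is the plain average of the per-cell sigmas, per axis.
#'
#' @param tracks list of data frames (or 2-column matrices) with columns
#'   `x`, `y`: one position per frame, in px. Each series needs >= 5 points.
#' @param period sampling interval in seconds (default 3).
#' @return an object of class `jerk_stats`: list with `sigma_Jx`, `sigma_Jy`,
#'   `n_cells`, `n_frames` (length of the shortest series).
#' @export
estimate_jerk_stats <- function(tracks, period = 3) {
  if (length(tracks) == 0) stop("no tracks supplied", call. = FALSE)
  per_cell <- vapply(tracks, function(tr) {
    tr <- as.data.frame(tr)
    if (nrow(tr) < 5)
      stop("each series needs at least 5 points", call. = FALSE)
    c(stats::sd(diff(tr$x, differences = 3) / period^3),
      stats::sd(diff(tr$y, differences = 3) / period^3))
  }, numeric(2))
  structure(
    list(sigma_Jx = mean(per_cell[1, ]), sigma_Jy = mean(per_cell[2, ]),
         n_cells = length(tracks),
         n_frames = min(vapply(tracks, function(t) nrow(as.data.frame(t)),
                               integer(1)))),
    class = "jerk_stats")
}

#' Default jerk and observation noise parameters
#'
#' Reference values estimated from manually tracked endothelial cells in
#' aorta preparations (jerk sigmas in px/s^3) and the small observation
#' sigmas (px) that keep corrected estimates pinned to the measured
#' centroids while still incorporating the process covariance.
#'
#' @return named list with `sigma_Jx`, `sigma_Jy`, `sigma_x`, `sigma_y`.
#' @export
default_kalman_params <- function() {
  list(sigma_Jx = 0.0269, sigma_Jy = 0.0993, sigma_x = 0.001, sigma_y = 0.001)
}

#' Assemble the constant-acceleration Kalman model
#'
#' State is the 6-vector \[x, x', x'', y, y', y''\] (px, px/s, px/s^2). The
#' transition matrix is block-diagonal with the constant-acceleration block
#' \[\[1, T, T^2/2\], \[0, 1, T\], \[0, 0, 1\]\] per axis; the observation
#' matrix picks out the two positions. Process noise enters through the jerk
#' vector `q = [T^3 sJx / 3, T^2 sJx / 2, T sJx, T^3 sJy / 3, T^2 sJy / 2,
#' T sJy]` with covariance `Q = q^T q` (a rank-one outer product, which
#' couples the axes), and the observation covariance is
#' `R = diag(sigma_x^2, sigma_y^2)`.
#'
#' The filter state is initialised at the first observed centroid with zero
#' velocity and acceleration, and `P0 = diag(sigma_x^2, sigma_v^2,
#' sigma_a^2, sigma_y^2, sigma_v^2, sigma_a^2)`: a zero-motion prior that
#' matches the slow cell movement, with moderately uninformative
#' velocity/acceleration variances.
#'
#' @param stats a `jerk_stats` object or a list with `sigma_Jx`, `sigma_Jy`
#'   (defaults to [default_kalman_params()]).
#' @param sigma_obs length-2 numeric, observation sigmas for x and y in px.
#' @param period sampling interval in seconds (default 3).
#' @param initial_position numeric `c(x, y)` in px.
#' @param sigma_v,sigma_a prior standard deviations for velocity (px/s) and
#'   acceleration (px/s^2), default 1.
#' @return an object of class `kalman_model`: list with `state`, `P`, `F`,
#'   `H`, `Q`, `R`, `T`.
#' @export
build_kalman <- function(stats = default_kalman_params(),
                         sigma_obs = c(0.001, 0.001), period = 3,
                         initial_position = c(0, 0),
                         sigma_v = 1, sigma_a = 1) {
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  if (any(c(stats$sigma_Jx, stats$sigma_Jy) < 0) || any(sigma_obs <= 0))
    stop("noise sigmas must be positive", call. = FALSE)
  T <- period
  blk <- matrix(c(1, T, T^2 / 2,
                  0, 1, T,
                  0, 0, 1), 3, 3, byrow = TRUE)
  F <- matrix(0, 6, 6)
  F[1:3, 1:3] <- blk
  F[4:6, 4:6] <- blk
  H <- matrix(0, 2, 6)
  H[1, 1] <- 1
  H[2, 4] <- 1
  q <- c(T^3 * stats$sigma_Jx / 3, T^2 * stats$sigma_Jx / 2, T * stats$sigma_Jx,
         T^3 * stats$sigma_Jy / 3, T^2 * stats$sigma_Jy / 2, T * stats$sigma_Jy)
  Q <- outer(q, q)
  R <- diag(sigma_obs^2)
  state <- c(initial_position[1], 0, 0, initial_position[2], 0, 0)
  P <- diag(c(sigma_obs[1]^2, sigma_v^2, sigma_a^2,
              sigma_obs[2]^2, sigma_v^2, sigma_a^2))
  structure(list(state = state, P = P, F = F, H = H, Q = Q, R = R, T = T),
            class = "kalman_model")
}

#' Rank of the observability matrix
#'
#' Stacks `H F^i` for i = 0..5 into a 12 x 6 matrix and returns its
#' numerical rank. Full rank (6) means position observations alone determine
#' the whole position/velocity/acceleration state, so the filter is usable.
#'
#' @param model a `kalman_model`.
#' @return integer rank.
#' @export
observability_rank <- function(model) {
  Fi <- diag(6)
  rows <- vector("list", 6)
  for (i in 1:6) {
    rows[[i]] <- model$H %*% Fi
    Fi <- Fi %*% model$F
  }
  qr(do.call(rbind, rows))$rank
}

#' Kalman time update
#'
#' Advances the state one sampling period (`state <- F state`,
#' `P <- F P F^T + Q`). The predicted position is available through
#' [kalman_position()].
#'
#' @param model a `kalman_model`.
#' @return the updated model.
#' @export
kalman_predict <- function(model) {
  model$state <- as.numeric(model$F %*% model$state)
  model$P <- model$F %*% model$P %*% t(model$F) + model$Q
  model
}

#' Kalman measurement update
#'
#' Standard gain/correction step with the position observation `c(x, y)`.
#' Uses the Joseph-form covariance update, which keeps `P` symmetric
#' positive semi-definite.
#'
#' @param model a `kalman_model` on which [kalman_predict()] has been called
#'   for this step.
#' @param observation numeric `c(x, y)` in px.
#' @return the updated model.
#' @export
kalman_correct <- function(model, observation) {
  H <- model$H
  S <- H %*% model$P %*% t(H) + model$R
  K <- model$P %*% t(H) %*% solve(S)
  innov <- observation - as.numeric(H %*% model$state)
  model$state <- model$state + as.numeric(K %*% innov)
  IKH <- diag(6) - K %*% H
  model$P <- IKH %*% model$P %*% t(IKH) + K %*% model$R %*% t(K)
  model
}

#' Current position estimate of a Kalman model
#' @param model a `kalman_model`.
#' @return numeric `c(x, y)` in px.
#' @export
kalman_position <- function(model) model$state[c(1, 4)]
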