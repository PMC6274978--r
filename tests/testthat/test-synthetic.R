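test_that("the sinusoid generator renders the analytic trajectory", {
  sim <- gen_sinusoid_test(peak_to_peak = 36, f = 4, n_frames = 100)
  expect_equal(max(sim$truth$y) - min(sim$truth$y), 36, tolerance = 0.01)
  expect_equal(diff(range(sim$truth$x)), 0)
  expect_equal(n_frames(sim$seq), 100)

  # rendered blob centroids match the formula within half a pixel
  thr <- (max(sim$seq$frames) + min(sim$seq$frames)) / 2
  for (i in c(1, 17, 50, 83)) {
    fr <- get_frame(sim$seq, i)
    idx <- which(fr > thr, arr.ind = TRUE)
    cx <- mean(idx[, "col"]) - 1
    cy <- mean(idx[, "row"]) - 1
    expect_lt(abs(cx - sim$truth$x[i]), 0.5)
    expect_lt(abs(cy - sim$truth$y[i]), 0.5)
  }

  still <- gen_sinusoid_test(f = 0, n_frames = 10)
  expect_equal(diff(range(still$truth$y)), 0)
  # stationary blob sits at y0 + A
  expect_equal(still$truth$y[1], (96 - 1) / 2 + 18)

  expect_error(gen_sinusoid_test(peak_to_peak = 200), "height")
  expect_error(gen_sinusoid_test(n_frames = 5), "10 frames")

  # dropout frames render no blob
  dropped <- gen_sinusoid_test(dropout_frames = 3:4, n_frames = 10)
  expect_equal(max(get_frame(dropped$seq, 3)), 20)
  expect_gt(max(get_frame(dropped$seq, 5)), 100)
})

test_that("trajectory MSE is the per-axis squared error", {
  a <- data.frame(x = 1:10, y = 11:20)
  expect_equal(unname(trajectory_mse(a, a)), c(0, 0))
  b <- a
  b$x <- b$x + 1
  expect_equal(unname(trajectory_mse(b, a)), c(1, 0))
  expect_error(trajectory_mse(a[1:3, ], a), "lengths")
})

test_that("phantoms are reproducible and honour their waveform", {
  spec <- phantom_spec(n_cells = 6, n_frames = 8, dim = c(128, 128), seed = 9)
  ph1 <- gen_phantom(spec)
  ph2 <- gen_phantom(spec)
  expect_identical(ph1$seq340$frames, ph2$seq340$frames)
  expect_identical(ph1$seq380$frames, ph2$seq380$frames)
  expect_identical(ph1$truth, ph2$truth)

  # noise-free ratio at a cell centre matches the analytic waveform to < 1%
  clean <- phantom_spec(n_cells = 4, n_frames = 10, dim = c(128, 128),
                        noise_sd = 0, motion_sd = 0, jitter_sd = 0,
                        cp = list(baseline = 0.85, peak_amp = 0.25,
                                  peak_frame = 4, plateau = 0.95, tau = 3),
                        seed = 10)
  ph <- gen_phantom(clean)
  ratio <- make_ratio_sequence(ph$seq340, ph$seq380)
  for (f in c(1, 4, 7)) {
    tr <- ph$truth[ph$truth$frame == f, ]
    for (i in seq_len(nrow(tr))) {
      got <- get_frame(ratio, f)[round(tr$y[i]) + 1, round(tr$x[i]) + 1]
      expect_lt(abs(got - ph$waveform[f]) / ph$waveform[f], 0.01)
    }
  }
  # ground-truth CP covers every rendered (cell, frame)
  expect_false(anyNA(ph$truth_cp$cp[ph$truth$rendered]))
})

test_that("a flat unit-ratio phantom yields mean CP of exactly 1", {
  spec <- phantom_spec(n_cells = 5, n_frames = 6, dim = c(128, 128),
                       noise_sd = 0, motion_sd = 0, jitter_sd = 0,
                       cp = list(baseline = 1, peak_amp = 0, peak_frame = 3,
                                 plateau = 1, tau = 5),
                       seed = 12)
  ph <- gen_phantom(spec)
  params <- segmentation_params(ph$w)
  lab <- segment_sequence(ph$seq340, params)
  ratio <- make_ratio_sequence(ph$seq340, ph$seq380)
  res <- run_tracking(lab, ratio, "all", params)
  s <- summarize_tracks(res)
  expect_equal(s$mean_cp, rep(1, nrow(s)))
  expect_identical(unique(s$status), "ONLINE")
})

test_that("an injury-style permanent dropout retires the track after RL", {
  dr <- vector("list", 6)
  dr[[2]] <- 4:12
  spec <- phantom_spec(n_cells = 6, n_frames = 12, dim = c(128, 128),
                       motion_sd = 0.2, dropout = dr, seed = 13)
  ph <- gen_phantom(spec)
  params <- segmentation_params(ph$w)
  lab <- segment_sequence(ph$seq340, params)
  ratio <- make_ratio_sequence(ph$seq340, ph$seq380)
  res <- run_tracking(lab, ratio, "all", params, rl = 3)
  statuses <- vapply(res$tracks, function(t) t$status, character(1))
  expect_equal(sum(statuses == "OFFLINE"), 1)
  off <- res$tracks[[which(statuses == "OFFLINE")]]
  # missing from frame 4, counter reaches 3 at frame 6
  expect_identical(off$history$status[6], "OFFLINE")
  expect_true(all(is.na(off$history$x[4:12])))
})

test_that("the dropout scheduler respects rate, range and separation", {
  dr <- make_dropout_schedule(10, 60, rate = 0.1, run_range = 1:2, seed = 3)
  expect_length(dr, 10)
  for (d in dr) {
    expect_true(all(d >= 2 & d <= 60))
    runs <- rle(diff(d) == 1)
    # no run of consecutive frames longer than 2
    expect_true(all(runs$lengths[runs$values] < 2))
    expect_gte(length(d), 0.08 * 59)
  }
})
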