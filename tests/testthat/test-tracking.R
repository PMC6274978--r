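# labeled_frame with arbitrary label values, for intersection fixtures
make_lf <- function(labels) {
  labs <- sort(setdiff(unique(as.vector(labels)), 0))
  comp <- do.call(rbind, lapply(labs, function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    data.frame(label = l, x = mean(idx[, "col"]) - 1,
               y = mean(idx[, "row"]) - 1, area = nrow(idx))
  }))
  if (is.null(comp))
    comp <- data.frame(label = integer(), x = numeric(), y = numeric(),
                       area = numeric())
  structure(list(binary = labels > 0, labels = labels, components = comp),
            class = "labeled_frame")
}

test_that("kernel intersection returns overlapping component labels", {
  prev <- matrix(0L, 12, 12)
  prev[4:6, 4:6] <- 14L
  cur <- matrix(0L, 12, 12)
  cur[5:8, 5:8] <- 22L
  got <- intersect_kernel(prev == 14, make_lf(cur))
  expect_identical(got, 22L)

  far <- matrix(0L, 12, 12)
  far[10:11, 10:11] <- 5L
  expect_length(intersect_kernel(prev == 14, make_lf(far)), 0)

  two <- matrix(0L, 12, 12)
  two[3:4, 3:8] <- 7L
  two[6:7, 3:8] <- 9L
  wide <- matrix(FALSE, 12, 12)
  wide[3:7, 5] <- TRUE
  expect_identical(intersect_kernel(wide, make_lf(two)), c(7L, 9L))
})

test_that("label resolution prefers intersection, then prediction", {
  cur <- matrix(0L, 20, 20)
  cur[2:5, 2:5] <- 1L
  cur[12:15, 12:15] <- 2L
  lf <- make_lf(cur)

  # a single candidate wins regardless of the prediction
  r <- resolve_label(2L, prediction = c(3, 3), lf, gate = 5)
  expect_identical(r$label, 2L)
  expect_identical(r$found_by, "INTERSECTION")

  # no candidates: containment at the predicted pixel
  r2 <- resolve_label(integer(), prediction = c(3.2, 2.8), lf, gate = 5)
  expect_identical(r2$label, 1L)
  expect_identical(r2$found_by, "KALMAN")

  # two candidates: nearest centroid within the gate (centroids 2.5, 12.5)
  r3 <- resolve_label(c(1L, 2L), prediction = c(7, 7), lf, gate = 10)
  expect_identical(r3$label, 1L)
  r3b <- resolve_label(c(1L, 2L), prediction = c(8, 8), lf, gate = 10)
  expect_identical(r3b$label, 2L)

  # nothing within the gate
  r4 <- resolve_label(integer(), prediction = c(19, 0), lf, gate = 2)
  expect_true(is.na(r4$label))
  expect_identical(r4$found_by, "NONE")
})

# stack of frames with one square cell present/absent per frame
square_stack <- function(present, at = c(10, 10), dim = c(32, 32)) {
  k <- length(present)
  arr <- array(0, c(dim, k))
  for (f in seq_len(k))
    if (present[f])
      arr[at[1]:(at[1] + 4), at[2]:(at[2] + 4), f] <- 200
  frame_sequence(arr, "EX340")
}

run_square <- function(present, rl = 3) {
  seq <- square_stack(present)
  params <- segmentation_params(8, open_radius = 1)
  lab <- lapply(seq_len(n_frames(seq)), function(i)
    label_components(get_frame(seq, i) > 100))
  ratio <- frame_sequence(array(1, dim(seq$frames)), "RATIO")
  suppressWarnings(run_tracking(lab, ratio, "all", params, rl = rl))
}

test_that("an always-present cell stays ONLINE with a zero counter", {
  res <- run_square(rep(TRUE, 10))
  tr <- res$tracks[[1]]
  expect_identical(tr$status, "ONLINE")
  expect_identical(tr$reliability, 0L)
  expect_true(all(tr$history$found_by == "INTERSECTION"))
  expect_equal(diff(range(tr$history$x)), 0)
  expect_true(all(res$rho$rho == 100))
})

test_that("a cell missing RL consecutive frames goes OFFLINE permanently", {
  # visible at frame 1, gone from frame 2 on; RL = 3 => OFFLINE at frame 4
  res <- run_square(c(TRUE, rep(FALSE, 6)))
  h <- res$tracks[[1]]$history
  expect_identical(h$status[1:4], c("ONLINE", "ONLINE", "ONLINE", "OFFLINE"))
  expect_true(all(is.na(h$status[5:7])))  # no longer tracked
  expect_true(all(is.na(h$x[2:7])))
  expect_identical(res$tracks[[1]]$status, "OFFLINE")
  # OFFLINE is absorbing even though the cell reappears
  res2 <- run_square(c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(res2$tracks[[1]]$status, "OFFLINE")
  expect_true(all(is.na(res2$tracks[[1]]$history$x[5:6])))
})

test_that("a transient disappearance below RL is survived and reset", {
  res <- run_square(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE), rl = 3)
  tr <- res$tracks[[1]]
  expect_identical(tr$status, "ONLINE")
  expect_identical(tr$reliability, 0L)
  expect_true(all(is.na(tr$history$x[3:4])))
  expect_false(anyNA(tr$history$x[5:6]))
})

test_that("tracking handles the minimal and empty cases", {
  res <- run_square(c(TRUE, TRUE))
  expect_equal(nrow(res$tracks[[1]]$history), 2)
  expect_false(anyNA(res$tracks[[1]]$history$x))

  seq <- square_stack(c(FALSE, FALSE))
  params <- segmentation_params(8)
  lab <- lapply(1:2, function(i) label_components(get_frame(seq, i) > 100))
  ratio <- frame_sequence(array(1, dim(seq$frames)), "RATIO")
  expect_warning(res2 <- run_tracking(lab, ratio, "all", params),
                 "nothing to track")
  expect_length(res2$tracks, 0)
})

test_that("seed-point selection picks the component under or nearest", {
  arr <- array(0, c(32, 32, 2))
  arr[5:9, 5:9, ] <- 200    # component at (6, 6) in 0-based centroid
  arr[20:24, 20:24, ] <- 200
  seq <- frame_sequence(arr, "EX340")
  lab <- lapply(1:2, function(i) label_components(get_frame(seq, i) > 100))
  ratio <- frame_sequence(array(1, c(32, 32, 2)), "RATIO")
  params <- segmentation_params(8)
  sel <- data.frame(x = c(6, 15), y = c(6, 15))  # inside first, near both
  res <- run_tracking(lab, ratio, sel, params)
  expect_length(res$tracks, 2)
  expect_equal(res$tracks[[1]]$history$x[1], 6)
  expect_identical(res$tracks[[1]]$cell_id, "A001")
})
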