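test_that("preprocessing leaves degenerate frames alone and removes salt", {
  params <- segmentation_params(24)  # w_median = 3
  const <- matrix(40, 16, 16)
  expect_equal(preprocess(const, params), const)

  salt <- matrix(10, 16, 16)
  salt[8, 8] <- 250
  out <- preprocess(salt, params)
  expect_equal(out, matrix(10, 16, 16))
})

test_that("median filter plus stretch matches the naive oracle", {
  set.seed(31)
  frame <- matrix(sample(0:255, 16 * 18, replace = TRUE), 16, 18)
  for (w in c(3, 4)) {
    params <- segmentation_params(8 * w)  # ties w_median to w
    expect_equal(params$w_median, w)
    filt <- naive_median_filter(frame, w)
    expected <- (filt - min(filt)) / (max(filt) - min(filt)) * 255
    expect_equal(preprocess(frame, params), expected)
  }
})

test_that("Niblack handles the uniform and single-bright-pixel cases", {
  expect_false(any(niblack_threshold(matrix(120, 20, 20), 5)))
  dark <- matrix(0, 20, 20)
  dark[10, 10] <- 200
  mask <- niblack_threshold(dark, 5)
  expect_true(mask[10, 10])
})

test_that("integral-image Niblack equals direct local statistics", {
  set.seed(32)
  for (rep in 1:20) {
    frame <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    for (w in c(7, 8)) {
      expect_identical(niblack_threshold(frame, w, k_T = 1),
                       naive_niblack(frame, w, 1))
    }
  }
  expect_error(niblack_threshold(matrix(0, 5, 5), 9), "larger")
})

test_that("binary conditioning composes opening, hole fill, dilation", {
  params <- segmentation_params(20)  # open r=3, dilate r=1
  speck <- matrix(FALSE, 32, 32)
  speck[10:11, 10:11] <- TRUE
  expect_false(any(condition_binary(speck, params)))

  holed <- disk_mask(c(40, 40), 19, 19, 10)
  holed[18:21, 18:21] <- FALSE
  out <- condition_binary(holed, params)
  expect_true(all(out[18:21, 18:21]))

  set.seed(33)
  blobs <- matrix(FALSE, 48, 48)
  for (i in 1:4) {
    cx <- sample(8:40, 1)
    cy <- sample(8:40, 1)
    blobs <- blobs | disk_mask(c(48, 48), cx, cy, sample(3:6, 1))
  }
  manual <- EBImage::opening(matrix(as.numeric(blobs), 48, 48),
                             EBImage::makeBrush(7, "disc"))
  manual <- EBImage::fillHull(manual)
  manual <- EBImage::dilate(manual, EBImage::makeBrush(3, "disc"))
  expect_equal(condition_binary(blobs, params),
               matrix(as.logical(manual > 0), 48, 48))
})

test_that("component labelling matches a flood-fill oracle", {
  two <- matrix(FALSE, 20, 20)
  two[2:5, 2:5] <- TRUE
  two[10:15, 10:13] <- TRUE
  lf <- label_components(two)
  expect_equal(nrow(lf$components), 2)
  expect_equal(sort(lf$components$area), c(16, 24))

  expect_equal(nrow(label_components(matrix(FALSE, 5, 5))$components), 0)

  set.seed(34)
  for (rep in 1:10) {
    mask <- matrix(runif(30 * 30) > 0.7, 30, 30)
    lf <- label_components(mask)
    oracle <- flood_fill_components(mask)
    expect_equal(max(lf$labels), max(oracle))
    expect_equal(sort(tabulate(lf$labels[lf$labels > 0])),
                 sort(tabulate(oracle[oracle > 0])))
    # identical partition: labels agree up to naming, here checked exactly
    expect_identical(lf$labels, oracle)
  }
})

test_that("component centroids lie inside their bounding boxes", {
  set.seed(35)
  mask <- matrix(runif(40 * 40) > 0.75, 40, 40)
  lf <- label_components(mask)
  for (l in lf$components$label) {
    idx <- which(lf$labels == l, arr.ind = TRUE)
    comp <- lf$components[lf$components$label == l, ]
    expect_gte(comp$y, min(idx[, "row"]) - 1)
    expect_lte(comp$y, max(idx[, "row"]) - 1)
    expect_gte(comp$x, min(idx[, "col"]) - 1)
    expect_lte(comp$x, max(idx[, "col"]) - 1)
  }
})

test_that("sequence segmentation is frame-wise independent", {
  set.seed(36)
  stack <- array(sample(0:255, 40 * 40 * 4, replace = TRUE), c(40, 40, 4))
  seq <- frame_sequence(stack, "EX340")
  params <- segmentation_params(12)
  out <- segment_sequence(seq, params)
  expect_length(out, 4)

  perm <- c(3, 1, 4, 2)
  out_perm <- segment_sequence(frame_sequence(stack[, , perm], "EX340"),
                               params)
  for (i in seq_along(perm))
    expect_identical(out_perm[[i]]$labels, out[[perm[i]]]$labels)

  zero <- segment_sequence(frame_sequence(array(0, c(20, 20, 2)), "EX340"),
                           params)
  expect_true(all(vapply(zero, function(l) nrow(l$components) == 0,
                         logical(1))))
  one <- segment_sequence(frame_sequence(array(stack[, , 1], c(40, 40, 1)),
                                         "EX340"), params)
  expect_length(one, 1)
})
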