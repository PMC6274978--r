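#' @useDynLib furatrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Frame sequence container
#'
#' A `frame_sequence` holds a stack of single-channel frames of identical
#' dimensions, the excitation channel they come from and the sampling period.
#' Raw channels (`"EX340"`, `"EX380"`) hold 8-bit intensities on the 0--255
#' scale; the `"RATIO"` channel holds real-valued pixelwise 340/380 quotients.
#'
#' @param frames numeric 3-D array, height x width x frames. A single matrix
#'   is promoted to a one-frame stack.
#' @param channel one of `"EX340"`, `"EX380"`, `"RATIO"`.
#' @param period sampling interval between frames in seconds (default 3).
#' @return an object of class `frame_sequence` with fields `frames`,
#'   `channel`, `pixel_kind` (`"uint8"` or `"real"`) and `period`.
#' @export
frame_sequence <- function(frames, channel = c("EX340", "EX380", "RATIO"),
                           period = 3) {
  channel <- match.arg(channel)
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an m x n x k array", call. = FALSE)
  if (channel == "RATIO") {
    if (!all(is.finite(frames)) || any(frames < 0))
      stop("RATIO frames must be finite and non-negative", call. = FALSE)
    pixel_kind <- "real"
  } else {
    if (any(frames < 0) || any(frames > 255))
      stop("raw channel values must lie in [0, 255]", call. = FALSE)
    pixel_kind <- "uint8"
  }
  structure(
    list(frames = frames, channel = channel, pixel_kind = pixel_kind,
         period = period),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %s: %d x %d px, %d frame(s), T = %g s\n",
              x$channel, d[1], d[2], d[3], x$period))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a [frame_sequence()].
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' Extract one frame as a matrix
#' @param seq a [frame_sequence()].
#' @param i frame index (1-based).
#' @return numeric matrix.
#' @export
get_frame <- function(seq, i) seq$frames[, , i]

list_tiff_files <- function(path_pattern) {
  if (length(path_pattern) == 1 && dir.exists(path_pattern)) {
    files <- list.files(path_pattern, pattern = "\\.tiff?$", full.names = TRUE,
                        ignore.case = TRUE)
  } else {
    files <- Sys.glob(path_pattern)
  }
  sort(files, method = "radix")
}

#' Load a TIFF image sequence
#'
#' Reads an excitation-channel image sequence either from a directory of
#' single-frame TIFF files (frame order = lexicographic filename order) or
#' from one or more multi-page TIFFs (frame order = page order within the
#' lexicographic file order). Grayscale 8-bit input is expected; deeper
#' integer input is rescaled to the 0--255 scale with a warning so that
#' calibrated thresholds stay comparable across acquisitions.
#'
#' @param path_pattern directory, file path or glob matching the TIFF input.
#' @param channel channel tag, `"EX340"` or `"EX380"`.
#' @param period sampling interval in seconds (default 3).
#' @return a [frame_sequence()] of the raw channel.
#' @export
load_tiff_sequence <- function(path_pattern, channel = c("EX340", "EX380"),
                               period = 3) {
  channel <- match.arg(channel)
  files <- list_tiff_files(path_pattern)
  if (length(files) == 0)
    stop("no TIFF files matched by '", path_pattern, "'", call. = FALSE)
  pages <- list()
  for (f in files) {
    img <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    if (!is.list(img)) img <- list(img)
    for (p in img) {
      if (length(dim(p)) == 3L) {
        if (dim(p)[3] > 1)
          stop("multi-channel TIFF not supported: ", f, call. = FALSE)
        p <- p[, , 1]
      }
      pages[[length(pages) + 1L]] <- p
    }
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mixed dimensions", call. = FALSE)
  stack <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (i in seq_along(pages)) stack[, , i] <- pages[[i]]
  if (max(stack) > 255) {
    depth <- if (max(stack) <= 65535) 65535 else max(stack)
    warning("input deeper than 8 bits; rescaling to 0-255", call. = FALSE)
    stack <- round(stack / depth * 255)
  }
  frame_sequence(stack, channel, period)
}

#' Write a frame sequence to TIFF
#'
#' Raw channels are written as 8-bit grayscale, the ratio channel as 32-bit
#' float. A multi-page file is written when `destination` ends in
#' `.tif`/`.tiff`, otherwise one zero-padded file per frame is written into
#' the directory `destination`.
#'
#' @param seq a [frame_sequence()].
#' @param destination output file or directory.
#' @return invisibly, the file path(s) written.
#' @export
write_tiff_sequence <- function(seq, destination) {
  k <- n_frames(seq)
  raw8 <- seq$channel != "RATIO"
  bits <- if (raw8) 8L else 32L
  norm <- function(m) if (raw8) m / 255 else m
  if (grepl("\\.tiff?$", destination, ignore.case = TRUE)) {
    pages <- lapply(seq_len(k), function(i) norm(get_frame(seq, i)))
    tiff::writeTIFF(pages, destination, bits.per.sample = bits)
    invisible(destination)
  } else {
    dir.create(destination, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(destination, sprintf("frame_%04d.tif", seq_len(k)))
    for (i in seq_len(k))
      tiff::writeTIFF(norm(get_frame(seq, i)), paths[i],
                      bits.per.sample = bits)
    invisible(paths)
  }
}

#' Build the pixelwise ratio sequence
#'
#' Divides each 340-nm frame by the corresponding 380-nm frame pixel by pixel
#' in real arithmetic. Frames are paired by index (the alternating
#' excitations are treated as simultaneous). Pixels whose 380-nm value is 0
#' yield ratio 0 rather than `NaN`/`Inf`, which keeps downstream profile
#' means finite; the number of such pixels is reported in a message. Inputs
#' are never modified.
#'
#' @param seq340,seq380 [frame_sequence()] objects of channels `"EX340"` and
#'   `"EX380"` with identical dimensions and frame counts.
#' @return a `"RATIO"` [frame_sequence()].
#' @export
make_ratio_sequence <- function(seq340, seq380) {
  stopifnot(inherits(seq340, "frame_sequence"),
            inherits(seq380, "frame_sequence"))
  if (seq340$channel != "EX340" || seq380$channel != "EX380")
    stop("expected EX340 and EX380 sequences", call. = FALSE)
  if (!identical(dim(seq340$frames), dim(seq380$frames)))
    stop("sequence dimensions differ", call. = FALSE)
  num <- seq340$frames
  den <- seq380$frames
  zero <- den == 0
  if (any(zero)) {
    message(sum(zero), " zero-denominator pixel(s) mapped to ratio 0")
    den[zero] <- 1
  }
  ratio <- num / den
  ratio[zero] <- 0
  frame_sequence(ratio, "RATIO", seq340$period)
}
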