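# Independent reference implementations used as oracles.

# sliding-window median, same border-cropped window convention as the
# package (lo = (w-1)/2 before, w/2 after), computed pixel by pixel
naive_median_filter <- function(img, w) {
  nr <- nrow(img)
  nc <- ncol(img)
  lo <- (w - 1) %/% 2
  hi <- w %/% 2
  out <- img
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rows <- max(1, i - lo):min(nr, i + hi)
      cols <- max(1, j - lo):min(nc, j + hi)
      out[i, j] <- stats::median(img[rows, cols])
    }
  }
  out
}

# Niblack by direct windowed summation (shift-and-accumulate, no integral
# images): population std, strict comparison, cropped borders
naive_niblack <- function(img, w, k) {
  nr <- nrow(img)
  nc <- ncol(img)
  lo <- (w - 1) %/% 2
  hi <- w %/% 2
  s1 <- matrix(0, nr, nc)
  s2 <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (di in -lo:hi) {
    for (dj in -lo:hi) {
      ri <- seq_len(nr) + di
      cj <- seq_len(nc) + dj
      ok_r <- which(ri >= 1 & ri <= nr)
      ok_c <- which(cj >= 1 & cj <= nc)
      v <- img[ri[ok_r], cj[ok_c], drop = FALSE]
      s1[ok_r, ok_c] <- s1[ok_r, ok_c] + v
      s2[ok_r, ok_c] <- s2[ok_r, ok_c] + v^2
      cnt[ok_r, ok_c] <- cnt[ok_r, ok_c] + 1
    }
  }
  m <- s1 / cnt
  s <- sqrt(pmax(s2 / cnt - m^2, 0))
  img > m + k * s
}

# 8-connected labelling by BFS flood fill, raster order of first pixel
flood_fill_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j] || lab[i, j] != 0) next
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di
          jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0) {
            lab[ii, jj] <- nxt
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# square ROI mean with the package's window convention, by explicit loop
naive_roi_mean <- function(frame, center, w) {
  cx <- floor(center[1] + 0.5)
  cy <- floor(center[2] + 0.5)
  lo <- (w - 1) %/% 2
  hi <- w %/% 2
  acc <- c()
  for (yy in (cy - lo):(cy + hi))
    for (xx in (cx - lo):(cx + hi))
      if (yy >= 0 && yy < nrow(frame) && xx >= 0 && xx < ncol(frame))
        acc <- c(acc, frame[yy + 1, xx + 1])
  mean(acc)
}

# small filled-disk mask (1-based matrix, centre in 0-based px coords)
disk_mask <- function(dim, cx, cy, r) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (i in seq_len(dim[1]))
    for (j in seq_len(dim[2]))
      if ((i - 1 - cy)^2 + (j - 1 - cx)^2 <= r^2) m[i, j] <- TRUE
  m
}

# positions whose third difference / T^3 is an exact white jerk draw
simulate_jerk_track <- function(p, sigma_j, period = 3) {
  jx <- rnorm(p - 3, 0, sigma_j)
  jy <- rnorm(p - 3, 0, sigma_j)
  base <- function(j) c(0, 0, 0, cumsum(cumsum(cumsum(j)))) * period^3
  data.frame(x = base(jx), y = base(jy))
}
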