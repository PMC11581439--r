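# Shared raster helpers.
#
# Image convention throughout the package: matrices are indexed [row, col]
# with row = y and col = x; pixel centres sit at integer coordinates and
# (x, y) positions are 0-based with the origin at the top-left pixel.

#' Sample an image at fractional positions by bilinear interpolation
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of 0-based coordinates (x along columns).
#' @return numeric vector of interpolated values; `NA` outside the image.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1 &
    (x0 + (fx > 0)) <= nc - 1 & (y0 + (fy > 0)) <= nr - 1
  out <- rep(NA_real_, length(x))
  if (!any(inside)) return(out)
  x0i <- x0[inside]; y0i <- y0[inside]; fxi <- fx[inside]; fyi <- fy[inside]
  x1i <- pmin(x0i + 1, nc - 1); y1i <- pmin(y0i + 1, nr - 1)
  idx <- function(yy, xx) yy + 1 + nr * xx   # column-major linear index
  v00 <- img[idx(y0i, x0i)]; v01 <- img[idx(y0i, x1i)]
  v10 <- img[idx(y1i, x0i)]; v11 <- img[idx(y1i, x1i)]
  out[inside] <- (1 - fyi) * ((1 - fxi) * v00 + fxi * v01) +
    fyi * ((1 - fxi) * v10 + fxi * v11)
  out
}

#' Separable Gaussian smoothing with zero padding
#' @keywords internal
gaussian_smooth <- function(m, sigma = 1) {
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad <- half
  z <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  z[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))] <- m
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  z[is.na(z)] <- 0
  z[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))]
}

#' 3x3 median filter with edge replication
#' @keywords internal
median_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]   # replicate-pad
  stack <- matrix(NA_real_, nr * nc, 9L)
  k <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1L
    stack[, k] <- as.vector(z[dy + seq_len(nr), dx + seq_len(nc)])
  }
  matrix(apply(stack, 1L, median), nr, nc)
}

#' Label 4-connected foreground components
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 = background, k > 0 = component k.
#' @keywords internal
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue
      queue <- integer(0)
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rn <- r + d[1]; cn <- cc + d[2]
        ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
        q <- (cn[ok] - 1L) * nr + rn[ok]
        q <- q[mask[q] & lab[q] == 0L]
        if (length(q)) {
          lab[q] <- cur
          queue <- c(queue, unique(q))
        }
      }
    }
  }
  lab
}
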