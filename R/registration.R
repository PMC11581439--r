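# Channel registration from bead fiducials.
#
# The two polarization halves share one camera chip but travel different
# optical paths, so they are misaligned by a fraction of the field. A
# field of sub-resolution fluorescent beads imaged in both channels gives
# point correspondences from which a rigid-ish transform (translation,
# similarity or affine) is estimated once per setup and then applied to
# every data frame.

#' Detect bead fiducials as subpixel spots
#'
#' Local maxima of a Gaussian-smoothed image above `threshold` are refined
#' to subpixel precision with an intensity-weighted centroid computed in a
#' local window after subtracting the window's minimum.
#'
#' @param image numeric matrix.
#' @param min_sigma,max_sigma expected spot size range (pixels); smoothing
#'   uses `min_sigma`, the centroid window spans `3 * max_sigma`.
#' @param threshold minimum smoothed peak amplitude (counts).
#' @param min_separation minimum distance between detections (pixels);
#'   defaults to `4 * min_sigma`. The brighter spot wins.
#' @return A `BeadSet`: data.frame with columns `x`, `y` (0-based subpixel
#'   coordinates) and `intensity` (raw peak counts).
#' @export
detect_beads <- function(image, min_sigma = 1.2, max_sigma = 3,
                         threshold, min_separation = 4 * min_sigma) {
  stopifnot(is.matrix(image), length(image) > 0)
  sm <- gaussian_smooth(image, min_sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  # local maximum over the 8-neighborhood
  is_max <- sm >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- matrix(-Inf, nr, nc)
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    shifted[ys, xs] <- sm[ys - dy, xs - dx]
    is_max <- is_max & (sm >= shifted)
  }
  peaks <- which(is_max, arr.ind = TRUE)
  if (nrow(peaks) == 0L)
    return(structure(data.frame(x = numeric(0), y = numeric(0),
                                intensity = numeric(0)), class = c("BeadSet", "data.frame")))
  win <- max(2L, ceiling(1.5 * max_sigma))
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    r0 <- peaks[i, 1]; c0 <- peaks[i, 2]
    ys <- max(1, r0 - win):min(nr, r0 + win)
    xs <- max(1, c0 - win):min(nc, c0 + win)
    patch <- image[ys, xs, drop = FALSE]
    wgt <- pmax(patch - min(patch), 0)
    tot <- sum(wgt)
    if (tot <= 0) return(c(c0 - 1, r0 - 1, image[r0, c0]))
    cx <- sum(wgt %*% (xs - 1)) / tot
    cy <- sum((ys - 1) %*% wgt) / tot
    c(cx, cy, image[r0, c0])
  })
  res <- do.call(rbind, res)
  beads <- data.frame(x = res[, 1], y = res[, 2], intensity = res[, 3])
  # greedy non-maximum suppression: keep the brighter of any close pair
  beads <- beads[order(-beads$intensity), ]
  keep <- rep(TRUE, nrow(beads))
  for (i in seq_len(nrow(beads))) {
    if (!keep[i]) next
    if (i < nrow(beads)) {
      j <- (i + 1):nrow(beads)
      d2 <- (beads$x[j] - beads$x[i])^2 + (beads$y[j] - beads$y[i])^2
      keep[j][d2 < min_separation^2] <- FALSE
    }
  }
  beads <- beads[keep, , drop = FALSE]
  rownames(beads) <- NULL
  structure(beads, class = c("BeadSet", "data.frame"))
}

# least-squares transform fit on matched point sets (moving -> fixed)
fit_point_transform <- function(fixed, moving, model) {
  n <- nrow(fixed)
  if (model == "translation") {
    d <- unname(colMeans(fixed) - colMeans(moving))
    A <- diag(2); b <- d
  } else if (model == "similarity") {
    # complex regression fixed ~ a * moving + t captures rotation + scale
    zf <- complex(real = fixed[, 1], imaginary = fixed[, 2])
    zm <- complex(real = moving[, 1], imaginary = moving[, 2])
    mzm <- mean(zm); mzf <- mean(zf)
    num <- sum(Conj(zm - mzm) * (zf - mzf))
    den <- sum(Mod(zm - mzm)^2)
    a <- if (den > 0) num / den else complex(real = 1)
    t <- mzf - a * mzm
    A <- matrix(c(Re(a), Im(a), -Im(a), Re(a)), 2, 2)
    b <- c(Re(t), Im(t))
  } else {                                   # affine
    X <- cbind(moving, 1)
    cf <- qr.solve(X, fixed)                 # 3 x 2
    A <- t(cf[1:2, , drop = FALSE])
    b <- as.numeric(cf[3, ])
  }
  list(A = A, b = b)
}

transform_points <- function(tr, pts) {
  sweep(pts %*% t(tr$A), 2, tr$b, "+")
}

#' Estimate the perpendicular-to-parallel channel transform
#'
#' Beads detected in both halves are matched by mutual nearest neighbor
#' within `search_radius`, then a robust consensus loop (random minimal
#' samples, inliers within `max_residual`) selects the correspondences and
#' the final transform is refit by least squares on all inliers.
#'
#' @param fixed,moving `BeadSet`s (or data.frames with `x`, `y`) from the
#'   reference (parallel) and moving (perpendicular) channels.
#' @param model `"translation"`, `"similarity"` (default) or `"affine"`.
#' @param max_residual inlier threshold (pixels).
#' @param search_radius matching radius (pixels).
#' @param n_samples consensus iterations.
#' @param seed RNG seed for the consensus loop (deterministic by default).
#' @return A `ChannelTransform`: list with `model`, `A` (2x2 matrix), `b`
#'   (length-2 offset), `residual_rms`, `n_inliers`, `n_matches`. Maps
#'   moving-channel (x, y) to fixed-channel coordinates.
#' @export
estimate_transform <- function(fixed, moving, model = c("similarity", "translation", "affine"),
                               max_residual = 1, search_radius = 20,
                               n_samples = 200, seed = 1L) {
  model <- match.arg(model)
  need <- c(translation = 1L, similarity = 2L, affine = 3L)[model]
  fx <- as.matrix(fixed[, c("x", "y")]); mv <- as.matrix(moving[, c("x", "y")])
  if (nrow(fx) < need || nrow(mv) < need)
    stop("too few beads for a ", model, " fit (need ", need, ")")
  # mutual nearest neighbors within the search radius
  d2 <- outer(mv[, 1], fx[, 1], "-")^2 + outer(mv[, 2], fx[, 2], "-")^2
  nn_m <- apply(d2, 1, which.min)             # for each moving, closest fixed
  nn_f <- apply(d2, 2, which.min)             # for each fixed, closest moving
  im <- seq_len(nrow(mv))
  mutual <- nn_f[nn_m[im]] == im & d2[cbind(im, nn_m[im])] <= search_radius^2
  mi <- im[mutual]; fi <- nn_m[im][mutual]
  if (length(mi) < need)
    stop("too few mutual matches (", length(mi), ") for a ", model,
         " fit; beads detected: fixed=", nrow(fx), " moving=", nrow(mv))
  M <- mv[mi, , drop = FALSE]; Fp <- fx[fi, , drop = FALSE]
  best <- NULL; best_n <- -1L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (it in seq_len(n_samples)) {
    pick <- sample(nrow(M), need)
    tr <- tryCatch(fit_point_transform(Fp[pick, , drop = FALSE],
                                       M[pick, , drop = FALSE], model),
                   error = function(e) NULL)
    if (is.null(tr)) next
    res <- sqrt(rowSums((transform_points(tr, M) - Fp)^2))
    n_in <- sum(res <= max_residual)
    if (n_in > best_n) { best_n <- n_in; best <- res <= max_residual }
  }
  if (is.null(best) || best_n < need)
    stop("consensus failed: ", best_n, " inliers of ", nrow(M), " matches")
  # refit on the consensus inliers, then iteratively trim correspondences
  # whose residual is far above the bulk (e.g. centroids biased by a
  # nearby spurious spot survive the coarse inlier threshold)
  keep <- best
  for (round in 1:3) {
    tr <- fit_point_transform(Fp[keep, , drop = FALSE],
                              M[keep, , drop = FALSE], model)
    res_all <- sqrt(rowSums((transform_points(tr, M) - Fp)^2))
    thr <- min(max(3 * stats::median(res_all[keep]), 1e-9), max_residual)
    new_keep <- res_all <= thr
    if (sum(new_keep) < need || identical(new_keep, keep)) break
    keep <- new_keep
  }
  res <- sqrt(rowSums((transform_points(tr, M[keep, , drop = FALSE]) -
                         Fp[keep, , drop = FALSE])^2))
  structure(list(model = model, A = tr$A, b = tr$b,
                 residual_rms = sqrt(mean(res^2)),
                 n_inliers = sum(keep), n_matches = nrow(M)),
            class = "ChannelTransform")
}

#' Identity channel transform
#' @return A `ChannelTransform` that leaves coordinates unchanged.
#' @export
identity_transform <- function() {
  structure(list(model = "translation", A = diag(2), b = c(0, 0),
                 residual_rms = 0, n_inliers = 0L, n_matches = 0L),
            class = "ChannelTransform")
}

#' Resample the perpendicular half onto the parallel grid
#'
#' Each parallel-grid pixel is filled by bilinear interpolation of the
#' perpendicular half at the inverse-transformed position; positions that
#' fall outside the field become `NA` and are excluded downstream.
#'
#' @param pair a `PolarizedFramePair`.
#' @param transform a `ChannelTransform` mapping perpendicular coordinates
#'   onto parallel coordinates.
#' @return The pair with a resampled `perpendicular` half and
#'   `registered = TRUE`.
#' @export
apply_transform <- function(pair, transform) {
  perp <- pair$perpendicular
  nr <- nrow(perp); nc <- ncol(perp)
  Ainv <- solve(transform$A)
  gx <- rep(0:(nc - 1), each = nr)
  gy <- rep(0:(nr - 1), nc)
  src <- cbind(gx - transform$b[1], gy - transform$b[2]) %*% t(Ainv)
  vals <- bilinear_sample(perp, src[, 1], src[, 2])
  pair$perpendicular <- matrix(vals, nr, nc)
  pair$registered <- TRUE
  pair
}

#' Save / load a channel transform as JSON
#'
#' A bead calibration is done once per setup; persisting it lets every
#' frame of a session reuse it.
#' @param transform a `ChannelTransform`.
#' @param path JSON file path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(model = transform$model,
                            A = as.numeric(transform$A), b = transform$b,
                            residual_rms = transform$residual_rms,
                            n_inliers = transform$n_inliers),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(model = j$model, A = matrix(j$A, 2, 2), b = j$b,
                 residual_rms = j$residual_rms,
                 n_inliers = j$n_inliers, n_matches = NA_integer_),
            class = "ChannelTransform")
}
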