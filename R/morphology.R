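# Cell morphology: volume and height maps from confocal Z-stacks, 2D
# shape metrics, geodesic-distance sector profiles of anisotropy across
# the cytoplasm, and nuclear intensity fractions.

#' Construct a thresholded volume stack
#' @param voxels 3D numeric array indexed [y, x, z].
#' @param voxel_size numeric length-3 (dx, dy, dz) in micrometers.
#' @param threshold binarization threshold (counts); `"otsu"` picks it
#'   automatically from the intensity histogram.
#' @return A `VolumeStack`.
#' @export
volume_stack <- function(voxels, voxel_size, threshold = "otsu") {
  stopifnot(length(dim(voxels)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(voxels)
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 threshold = threshold),
            class = "VolumeStack")
}

#' Otsu's automatic threshold
#' @param x numeric array of intensities.
#' @param n_bins histogram bins.
#' @return threshold value maximizing between-class variance.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Cell volume from a thresholded Z-stack
#'
#' Volume = number of suprathreshold voxels times the voxel volume.
#'
#' @param stack a `VolumeStack`.
#' @return volume in um^3 (0 with a warning for an empty stack).
#' @export
cell_volume <- function(stack) {
  n <- sum(stack$voxels >= stack$threshold)
  if (n == 0) warning("no voxels above threshold; volume is 0")
  n * prod(stack$voxel_size)
}

#' Local height map from a thresholded Z-stack
#'
#' height(x, y) = dz times the number of suprathreshold voxels in the
#' (x, y) column, i.e. the per-slice binarized stack summed over z.
#'
#' @param stack a `VolumeStack`.
#' @return A `HeightMap`: list with `height` (matrix, micrometers) and
#'   `voxel_size`.
#' @export
height_map <- function(stack) {
  bin <- stack$voxels >= stack$threshold
  h <- apply(bin, c(1, 2), sum) * stack$voxel_size[3]
  structure(list(height = h, voxel_size = stack$voxel_size),
            class = "HeightMap")
}

#' 2D shape metrics: area, perimeter and circularity
#'
#' Area counts mask pixels; the perimeter is the marching-squares contour
#' length of the mask after light Gaussian presmoothing (sigma 1 px),
#' which removes the staircase bias of a binary contour; circularity is
#' 4 pi Area / Perimeter^2 (1 for a disk).
#'
#' @param mask logical matrix with one connected component.
#' @param pixel_size pixel edge (micrometers).
#' @param smooth_sigma presmoothing width (px); 0 disables it.
#' @return A `ShapeMetrics`: list with `area` (um^2), `perimeter` (um),
#'   `circularity`.
#' @export
shape_metrics <- function(mask, pixel_size = 1, smooth_sigma = 1) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  ncomp <- max(label_components(mask))
  if (ncomp != 1L) stop("mask must have exactly one connected component (has ",
                        ncomp, ")")
  z <- mask + 0
  if (smooth_sigma > 0) z <- gaussian_smooth(z, smooth_sigma)
  zp <- matrix(0, nrow(z) + 2, ncol(z) + 2)
  zp[2:(nrow(z) + 1), 2:(ncol(z) + 1)] <- z
  cl <- grDevices::contourLines(seq_len(nrow(zp)), seq_len(ncol(zp)), zp,
                                levels = 0.5)
  per <- sum(vapply(cl, function(cc) {
    x <- c(cc$x, cc$x[1]); y <- c(cc$y, cc$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1))) * pixel_size
  area <- sum(mask) * pixel_size^2
  structure(list(area = area, perimeter = per,
                 circularity = 4 * pi * area / per^2),
            class = "ShapeMetrics")
}

#' Geodesic distance within a mask
#'
#' Shortest in-mask path length (8-neighborhood chamfer metric) from the
#' seed set; `NA` outside the mask, `Inf` for unreachable pixels.
#'
#' @param mask logical matrix of the allowed region.
#' @param seeds logical matrix of zero-distance pixels.
#' @return numeric matrix of distances (pixels).
#' @export
geodesic_distance <- function(mask, seeds) {
  stopifnot(identical(dim(mask), dim(seeds)))
  chamfer_geodesic(mask, seeds & mask)
}

#' Normalized anisotropy profile across geodesic distance sectors
#'
#' Every cytoplasmic pixel gets a normalized distance
#' f = d_nuc / (d_nuc + d_cell), where d_nuc and d_cell are geodesic
#' distances (within the cell mask) from the nucleus boundary and the
#' cell boundary; f spans 0 at the nucleus to 1 at the cell edge. Pixels
#' are binned into `n_sectors` equal-f bands and per-band means of r are
#' normalized to the innermost band.
#'
#' @param r_map an `AnisotropyMap` (or plain matrix of r values).
#' @param cell_mask,nucleus_mask logical matrices; nucleus inside cell.
#' @param n_sectors number of distance bands (default 5: 0-20% ... 80-100%).
#' @return A `SectorProfile` data.frame: `sector_lo`, `sector_hi`,
#'   `mean_r`, `mean_norm_r`, `n_pixels`.
#' @export
geodesic_sector_profile <- function(r_map, cell_mask, nucleus_mask,
                                    n_sectors = 5) {
  r <- if (inherits(r_map, "AnisotropyMap")) r_map$r else r_map
  stopifnot(identical(dim(r), dim(cell_mask)),
            identical(dim(r), dim(nucleus_mask)))
  if (any(nucleus_mask & !cell_mask)) stop("nucleus mask must lie inside the cell mask")
  cyto <- cell_mask & !nucleus_mask
  if (!any(cyto)) stop("empty cytoplasm")
  ncomp <- max(label_components(cyto))
  if (ncomp > 1L)
    warning("cytoplasm splits into ", ncomp, " components; processing all")
  d_nuc <- geodesic_distance(cell_mask, nucleus_mask)
  # cell-boundary seeds: cell pixels with an 8-neighbor outside the mask
  pad <- rbind(FALSE, cbind(FALSE, cell_mask, FALSE), FALSE)
  nbr_out <- matrix(FALSE, nrow(cell_mask), ncol(cell_mask))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nbr_out <- nbr_out | !pad[2:(nrow(cell_mask) + 1) + dy,
                              2:(ncol(cell_mask) + 1) + dx]
  }
  edge <- cell_mask & nbr_out
  d_cell <- geodesic_distance(cell_mask, edge)
  f <- d_nuc / (d_nuc + d_cell)
  sel <- cyto & is.finite(f) & is.finite(r)
  edges <- seq(0, 1, length.out = n_sectors + 1)
  band <- pmin(findInterval(f[sel], edges, rightmost.closed = TRUE), n_sectors)
  mean_r <- tapply(r[sel], factor(band, levels = seq_len(n_sectors)), mean)
  n_px <- tapply(rep(1, sum(sel)), factor(band, levels = seq_len(n_sectors)), sum)
  n_px[is.na(n_px)] <- 0
  # very thin geometries can leave the 0-band empty; normalize to the
  # innermost populated band
  base <- as.numeric(mean_r)[which(n_px > 0)[1]]
  structure(data.frame(sector_lo = edges[-length(edges)], sector_hi = edges[-1],
                       mean_r = as.numeric(mean_r),
                       mean_norm_r = as.numeric(mean_r) / base,
                       n_pixels = as.integer(n_px)),
            class = c("SectorProfile", "data.frame"))
}

#' Nuclear fraction of a fluorescence signal
#'
#' On the Z-slice with the largest nucleus area, the fraction of total
#' cell intensity that lies within the nucleus.
#'
#' @param stack 3D intensity array [y, x, z].
#' @param cell_mask,nucleus_mask 3D logical arrays of the same shape
#'   (per-slice masks).
#' @return fraction in [0, 1].
#' @export
nuclear_fraction <- function(stack, cell_mask, nucleus_mask) {
  stopifnot(identical(dim(stack), dim(cell_mask)),
            identical(dim(stack), dim(nucleus_mask)))
  areas <- apply(nucleus_mask, 3, sum)
  z <- which.max(areas)
  cell_int <- sum(stack[, , z][cell_mask[, , z]])
  if (cell_int <= 0) stop("zero cell intensity on the selected slice")
  sum(stack[, , z][nucleus_mask[, , z]]) / cell_int
}
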