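# Per-pixel steady-state anisotropy maps and per-cell modal statistics.
#
# r = (Ipar - g * Iperp) / (Ipar + 2 * g * Iperp), with g the per-pixel
# G-factor calibrated on a freely rotating dye (fluorescein, r ~ 0) so
# that instrumental polarization bias and optical nonuniformity cancel.
# Per cell, the mode of the kernel-smoothed r density is the crowding
# readout: it tracks the predominant cytoplasmic state and is robust to
# morphology-driven tails that bias the mean.

#' Compute a per-pixel G-factor map from fluorescein reference frames
#'
#' For a fully depolarized reference, g(x, y) is the ratio of the mean
#' parallel to the mean perpendicular intensity over the reference stack,
#' lightly regularized with a 3x3 median filter. Pixels whose mean
#' perpendicular signal sits below `noise_floor` are invalidated (NaN).
#'
#' @param reference_pairs list of registered `PolarizedFramePair`s.
#' @param noise_floor minimum mean perpendicular counts for a valid pixel.
#' @param median_filter apply the 3x3 median regularization (default TRUE).
#' @return A `GFactorMap`: list with `g` (matrix, NaN where invalid) and
#'   `source` description.
#' @export
compute_gfactor_map <- function(reference_pairs, noise_floor = 1,
                                median_filter = TRUE) {
  if (length(reference_pairs) == 0L) stop("empty reference stack")
  par_m <- Reduce(`+`, lapply(reference_pairs, `[[`, "parallel")) / length(reference_pairs)
  perp_m <- Reduce(`+`, lapply(reference_pairs, `[[`, "perpendicular")) / length(reference_pairs)
  stopifnot(identical(dim(par_m), dim(perp_m)))
  g <- par_m / perp_m
  g[!is.finite(g) | perp_m < noise_floor | g <= 0] <- NaN
  if (median_filter) {
    filled <- g
    filled[is.nan(filled)] <- stats::median(g[!is.nan(g)])
    gm <- median_filter3(filled)
    gm[is.nan(g)] <- NaN
    g <- gm
  }
  structure(list(g = g, source = sprintf("%d reference pair(s)", length(reference_pairs))),
            class = "GFactorMap")
}

#' Subtract a blank-media background frame
#'
#' Performed on the full dual-view frame before splitting, so each
#' polarization channel loses its own background and the channel ratio is
#' preserved. Differences are clipped at zero.
#'
#' @param frame,background `RawDualViewFrame`s of identical shape.
#' @return Background-subtracted `RawDualViewFrame`.
#' @export
subtract_background <- function(frame, background) {
  if (!identical(dim(frame$pixels), dim(background$pixels)))
    stop("frame and background shapes differ")
  out <- frame
  out$pixels <- pmax(frame$pixels - background$pixels, 0)
  out
}

#' Compute the per-pixel anisotropy map
#'
#' r = (Ipar - g Iperp) / (Ipar + 2 g Iperp). The validity mask combines
#' the intensity threshold window (by default applied to the parallel-
#' channel counts, the camera's native scale for the 15,000-50,000 window
#' on 16-bit data), G-factor validity and the registered field of view.
#'
#' @param pair a registered `PolarizedFramePair`.
#' @param g a `GFactorMap` (or scalar g value).
#' @param threshold_low,threshold_high intensity window (counts).
#' @param threshold_on `"parallel"` (default) or `"total"` — which
#'   intensity the window applies to.
#' @return An `AnisotropyMap`: list with `r`, `total_intensity`
#'   (Ipar + 2 g Iperp) and logical `valid`.
#' @export
compute_anisotropy_map <- function(pair, g, threshold_low = 15000,
                                   threshold_high = 50000,
                                   threshold_on = c("parallel", "total")) {
  threshold_on <- match.arg(threshold_on)
  if (!isTRUE(pair$registered))
    warning("frame pair is not registered; computing anyway")
  gm <- if (inherits(g, "GFactorMap")) g$g else g
  if (is.matrix(gm) && !identical(dim(gm), dim(pair$parallel)))
    stop("G-factor map shape differs from the frame pair")
  ipar <- pair$parallel; iperp <- pair$perpendicular
  denom <- ipar + 2 * gm * iperp
  r <- (ipar - gm * iperp) / denom
  gate <- if (threshold_on == "parallel") ipar else denom
  valid <- is.finite(r) & is.finite(gate) & denom != 0 &
    gate >= threshold_low & gate <= threshold_high
  r[!valid] <- NaN
  structure(list(r = r, total_intensity = denom, valid = valid),
            class = "AnisotropyMap")
}

#' Per-cell modal and mean anisotropy
#'
#' For each labeled cell, the mode is the argmax of a Gaussian-kernel
#' density of the valid r values evaluated on a fixed grid (default
#' 0 to 0.4 in steps of 1e-4, spanning all physiological EGFP values with
#' margin); the bandwidth defaults to Silverman's rule on the per-cell
#' sample.
#'
#' @param map an `AnisotropyMap`.
#' @param roi a `RoiMask` (or integer label matrix).
#' @param bandwidth kernel bandwidth, or `NULL` for Silverman's rule.
#' @param grid_range,grid_step density evaluation grid.
#' @param min_pixels minimum valid pixels per cell; smaller cells yield a
#'   warning and an NA record (never a silently dropped row).
#' @param pixel_size pixel edge length in micrometers (for `spread_area`).
#' @param timestamp acquisition time (s) recorded in each record.
#' @return data.frame of `CellAnisotropyRecord`s: `cell_id`, `modal_r`,
#'   `mean_r`, `n_pixels`, `spread_area`, `timestamp`.
#' @export
modal_anisotropy <- function(map, roi, bandwidth = NULL,
                             grid_range = c(0, 0.4), grid_step = 1e-4,
                             min_pixels = 200, pixel_size = 1,
                             timestamp = NA_real_) {
  labels <- if (inherits(roi, "RoiMask")) roi$labels else roi
  stopifnot(identical(dim(labels), dim(map$r)))
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  n_grid <- round(diff(grid_range) / grid_step) + 1L
  out <- lapply(ids, function(k) {
    x <- map$r[labels == k & map$valid]
    x <- x[is.finite(x)]
    if (length(x) < min_pixels) {
      warning("cell ", k, ": only ", length(x), " valid pixels (< ", min_pixels,
              "); modal_r set to NA")
      return(data.frame(cell_id = k, modal_r = NA_real_, mean_r = NA_real_,
                        n_pixels = length(x), spread_area = length(x) * pixel_size^2,
                        timestamp = timestamp))
    }
    bw <- if (is.null(bandwidth)) stats::bw.nrd0(x) else bandwidth
    if (!is.finite(bw) || bw <= 0) bw <- grid_step
    d <- stats::density(x, bw = bw, from = grid_range[1], to = grid_range[2],
                        n = n_grid)
    data.frame(cell_id = k, modal_r = d$x[which.max(d$y)], mean_r = mean(x),
               n_pixels = length(x), spread_area = length(x) * pixel_size^2,
               timestamp = timestamp)
  })
  do.call(rbind, out)
}

#' Percentage change of modal anisotropy over a time course
#'
#' For each cell, Delta-r%(t) = 100 (modal_r(t) - baseline) / baseline,
#' with the baseline the mean modal_r over the pre-treatment window.
#' Cells without any baseline point are excluded with a message.
#'
#' @param records data.frame with `cell_id`, `timestamp`, `modal_r`
#'   (rbind of [modal_anisotropy()] outputs across time points).
#' @param baseline_window length-2 numeric: timestamps (s) treated as
#'   pre-treatment baseline, inclusive.
#' @return list with `per_cell` (cell_id, timestamp, delta_r_pct) and
#'   `summary` (timestamp, mean_delta_r_pct, sd_delta_r_pct, n_cells).
#' @export
anisotropy_timecourse <- function(records, baseline_window) {
  stopifnot(all(c("cell_id", "timestamp", "modal_r") %in% names(records)))
  per_cell <- lapply(split(records, records$cell_id), function(rc) {
    base <- rc$modal_r[rc$timestamp >= baseline_window[1] &
                         rc$timestamp <= baseline_window[2]]
    base <- base[is.finite(base)]
    if (!length(base)) {
      message("cell ", rc$cell_id[1], ": no baseline point; excluded")
      return(NULL)
    }
    b <- mean(base)
    data.frame(cell_id = rc$cell_id, timestamp = rc$timestamp,
               delta_r_pct = 100 * (rc$modal_r - b) / b)
  })
  per_cell <- do.call(rbind, per_cell)
  rownames(per_cell) <- NULL
  sm <- do.call(rbind, lapply(split(per_cell, per_cell$timestamp), function(s) {
    data.frame(timestamp = s$timestamp[1],
               mean_delta_r_pct = mean(s$delta_r_pct, na.rm = TRUE),
               sd_delta_r_pct = sd(s$delta_r_pct, na.rm = TRUE),
               n_cells = sum(is.finite(s$delta_r_pct)))
  }))
  rownames(sm) <- NULL
  list(per_cell = per_cell, summary = sm)
}

#' Paired photobleach test for the homo-FRET regime
#'
#' In the homo-FRET regime, bleaching lowers the effective fluorophore
#' concentration, reduces energy migration and therefore *raises* r while
#' total intensity falls; outside it, r is bleach-invariant. Pre/post
#' records are paired by cell id; unmatched cells are reported.
#'
#' @param pre,post data.frames with `cell_id`, `modal_r` and
#'   `mean_intensity`.
#' @return list with `per_cell` (cell_id, delta_r_pct, delta_intensity_pct)
#'   and `summary` (means, SDs, n, n_unmatched).
#' @export
homo_fret_bleach_test <- function(pre, post) {
  common <- intersect(pre$cell_id, post$cell_id)
  n_unmatched <- length(union(pre$cell_id, post$cell_id)) - length(common)
  if (n_unmatched > 0)
    message(n_unmatched, " unmatched cell(s) excluded from the bleach test")
  a <- pre[match(common, pre$cell_id), ]
  b <- post[match(common, post$cell_id), ]
  per_cell <- data.frame(
    cell_id = common,
    delta_r_pct = 100 * (b$modal_r - a$modal_r) / a$modal_r,
    delta_intensity_pct = 100 * (b$mean_intensity - a$mean_intensity) / a$mean_intensity)
  list(per_cell = per_cell,
       summary = data.frame(
         mean_delta_r_pct = mean(per_cell$delta_r_pct),
         sd_delta_r_pct = sd(per_cell$delta_r_pct),
         mean_delta_intensity_pct = mean(per_cell$delta_intensity_pct),
         sd_delta_intensity_pct = sd(per_cell$delta_intensity_pct),
         n = length(common), n_unmatched = n_unmatched))
}
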