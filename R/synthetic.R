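# Synthetic-data generators: every input modality of the pipeline with
# known ground truth, built as the exact forward model of the matching
# analysis step so round trips are identities at zero noise. Each
# generator returns its `ground_truth` record alongside the data and is
# byte-deterministic for a given seed.

with_seed <- function(seed, expr) {
  force(seed)   # any RNG draws in the caller's seed expression happen first
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

#' Synthesize a dual-view polarization scene
#'
#' Inverts the anisotropy relation: Ipar = I (1 + 2r) / 3 + bg and
#' Iperp = I (1 - r) / (3 g) + bg, with the perpendicular half displaced
#' by `shift` before the two halves are assembled side by side, so the
#' registration + G-factor + anisotropy chain must undo exactly what was
#' imposed.
#'
#' @param r_field imposed anisotropy field (matrix, values in [-0.5, 1]).
#' @param intensity_field total intensity I (matrix, counts).
#' @param g_field imposed per-pixel G-factor (matrix or scalar).
#' @param background additive background per channel (counts).
#' @param shift (dx, dy) displacement of the perpendicular half (px);
#'   the true perpendicular-to-parallel transform is a translation by
#'   `-shift`.
#' @param noise `"none"` or `"poisson"`.
#' @param left_is_perpendicular frame layout convention.
#' @param bit_depth camera bit depth; values are clipped (with a warning
#'   reporting the clip count) at 2^bit_depth - 1.
#' @param seed RNG seed (used only when noise is Poisson).
#' @return list with `frame` (a `RawDualViewFrame`) and `ground_truth`
#'   (r_field, g_field, background, shift, transform, seed, n_clipped).
#' @export
synth_polarized_scene <- function(r_field, intensity_field, g_field = 1,
                                  background = 0, shift = c(0, 0),
                                  noise = c("none", "poisson"),
                                  left_is_perpendicular = TRUE,
                                  bit_depth = 16L, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(all(r_field >= -0.5 & r_field <= 1),
            identical(dim(r_field), dim(intensity_field)))
  if (!is.matrix(g_field)) g_field <- matrix(g_field, nrow(r_field), ncol(r_field))
  ipar <- intensity_field * (1 + 2 * r_field) / 3 + background
  iperp0 <- intensity_field * (1 - r_field) / (3 * g_field) + background
  # displace the perpendicular content by `shift` (sample at x - dx, y - dy)
  if (any(shift != 0)) {
    nr <- nrow(iperp0); nc <- ncol(iperp0)
    gx <- rep(0:(nc - 1), each = nr) - shift[1]
    gy <- rep(0:(nr - 1), nc) - shift[2]
    iperp <- matrix(bilinear_sample(iperp0, gx, gy), nr, nc)
    iperp[is.na(iperp)] <- background
  } else iperp <- iperp0
  if (noise == "poisson") {
    ipar <- with_seed(seed, matrix(rpois(length(ipar), ipar), nrow(ipar)))
    iperp <- with_seed(seed + 1L, matrix(rpois(length(iperp), iperp), nrow(iperp)))
  }
  maxv <- 2^bit_depth - 1
  n_clip <- sum(ipar > maxv) + sum(iperp > maxv)
  if (n_clip > 0) warning(n_clip, " pixel(s) clipped at the ", bit_depth, "-bit ceiling")
  ipar <- pmin(ipar, maxv); iperp <- pmin(iperp, maxv)
  px <- if (left_is_perpendicular) cbind(iperp, ipar) else cbind(ipar, iperp)
  list(frame = dual_view_frame(px, bit_depth),
       ground_truth = list(r_field = r_field, g_field = g_field,
                           background = background, shift = shift,
                           transform_translation = -shift,
                           noise = noise, seed = seed, n_clipped = n_clip))
}

#' Synthesize a bead fiducial image
#'
#' Gaussian spots at given subpixel positions on a constant baseline,
#' sampled at pixel centers.
#'
#' @param positions 2-column matrix of 0-based (x, y) spot centers.
#' @param shape (height, width) of the image in pixels.
#' @param sigma spot width (px).
#' @param amplitude peak amplitude (counts; recycled).
#' @param baseline constant offset (counts).
#' @param noise `"none"` or `"poisson"`.
#' @param seed RNG seed.
#' @return list with `image` (matrix) and `ground_truth` (positions ...).
#' @export
synth_bead_image <- function(positions, shape = c(256, 256), sigma = 1.5,
                             amplitude = 5000, baseline = 100,
                             noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  positions <- as.matrix(positions)
  amplitude <- rep_len(amplitude, nrow(positions))
  img <- matrix(baseline, shape[1], shape[2])
  xs <- 0:(shape[2] - 1); ys <- 0:(shape[1] - 1)
  for (i in seq_len(nrow(positions))) {
    gx <- exp(-(xs - positions[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - positions[i, 2])^2 / (2 * sigma^2))
    img <- img + amplitude[i] * outer(gy, gx)
  }
  if (noise == "poisson")
    img <- with_seed(seed, matrix(rpois(length(img), img), nrow(img)))
  list(image = img,
       ground_truth = list(positions = positions, sigma = sigma,
                           amplitude = amplitude, baseline = baseline,
                           noise = noise, seed = seed))
}

#' Synthesize a 3D cell phantom with analytic volume
#'
#' Shapes: `"ellipsoid"` (semi-axes `axes_um`), `"hemisphere"` (radius
#' `radius_um`, flat side down) and `"spread_cell"` (hemispherical dome
#' plus a thin 0.5 um lamella ring, emulating the geometry of an adherent
#' fibroblast). An ellipsoidal nucleus can be embedded.
#'
#' @param shape phantom geometry.
#' @param voxel_size (dx, dy, dz) micrometers.
#' @param radius_um scalar radius (hemisphere, spread_cell dome).
#' @param axes_um semi-axes (a, b, c) for the ellipsoid.
#' @param lamella_radius_um outer radius of the spread-cell lamella.
#' @param lamella_height_um lamella thickness (default 0.5 um).
#' @param nucleus optional list(center_um, axes_um) for the nucleus.
#' @param fov_um (x, y, z) extent of the field (defaults fit the shape).
#' @return list with `stack` (a `VolumeStack` of 0/1 intensities),
#'   `roi` (a `RoiMask` from the mid-plane projection) and `ground_truth`
#'   (analytic `volume_um3`, height function parameters, masks).
#' @export
synth_cell_phantom <- function(shape = c("ellipsoid", "hemisphere", "spread_cell"),
                               voxel_size = c(0.2, 0.2, 0.2),
                               radius_um = 5, axes_um = c(10, 8, 3),
                               lamella_radius_um = 2 * radius_um,
                               lamella_height_um = 0.5,
                               nucleus = NULL, fov_um = NULL) {
  shape <- match.arg(shape)
  dx <- voxel_size[1]; dy <- voxel_size[2]; dz <- voxel_size[3]
  if (is.null(fov_um)) {
    ext <- switch(shape,
                  ellipsoid = c(2.5 * axes_um[1], 2.5 * axes_um[2], 2.5 * axes_um[3]),
                  hemisphere = c(2.5 * radius_um, 2.5 * radius_um, 1.5 * radius_um),
                  spread_cell = c(2.5 * lamella_radius_um, 2.5 * lamella_radius_um,
                                  1.5 * radius_um))
    fov_um <- ext
  }
  nx <- ceiling(fov_um[1] / dx); ny <- ceiling(fov_um[2] / dy)
  nz <- ceiling(fov_um[3] / dz)
  cx <- fov_um[1] / 2; cy <- fov_um[2] / 2
  xs <- (seq_len(nx) - 0.5) * dx; ys <- (seq_len(ny) - 0.5) * dy
  zs <- (seq_len(nz) - 0.5) * dz
  vox <- array(0, c(ny, nx, nz))
  X <- matrix(xs, ny, nx, byrow = TRUE); Y <- matrix(ys, ny, nx)
  inside2d <- function(z) {
    switch(shape,
           ellipsoid = ((X - cx) / axes_um[1])^2 + ((Y - cy) / axes_um[2])^2 +
             ((z - fov_um[3] / 2) / axes_um[3])^2 <= 1,
           hemisphere = (X - cx)^2 + (Y - cy)^2 + z^2 <= radius_um^2,
           spread_cell = {
             dome <- (X - cx)^2 + (Y - cy)^2 + z^2 <= radius_um^2
             lam <- (X - cx)^2 + (Y - cy)^2 <= lamella_radius_um^2 &
               z <= lamella_height_um
             dome | lam
           })
  }
  for (k in seq_len(nz)) vox[, , k] <- inside2d(zs[k]) + 0
  vol_analytic <- switch(shape,
                         ellipsoid = 4 * pi * prod(axes_um) / 3,
                         hemisphere = 2 * pi * radius_um^3 / 3,
                         # dome + lamella ring, minus the dome slab the ring overlaps
                         spread_cell = 2 * pi * radius_um^3 / 3 +
                           pi * lamella_height_um * (lamella_radius_um^2 - radius_um^2) +
                           pi * lamella_height_um^3 / 3)
  cell2d <- apply(vox, c(1, 2), max) > 0
  nuc2d <- matrix(FALSE, ny, nx)
  if (!is.null(nucleus)) {
    nc_ <- nucleus$center_um; na_ <- nucleus$axes_um
    for (k in seq_len(nz)) {
      m <- ((X - nc_[1]) / na_[1])^2 + ((Y - nc_[2]) / na_[2])^2 +
        ((zs[k] - nc_[3]) / na_[3])^2 <= 1
      nuc2d <- nuc2d | m
    }
    nuc2d <- nuc2d & cell2d
  }
  labels <- matrix(0L, ny, nx); labels[cell2d] <- 1L
  nlab <- matrix(0L, ny, nx); nlab[nuc2d] <- 1L
  list(stack = volume_stack(vox, voxel_size, threshold = 0.5),
       roi = roi_mask(labels, if (!is.null(nucleus)) nlab else NULL),
       ground_truth = list(shape = shape, volume_um3 = vol_analytic,
                           radius_um = radius_um, axes_um = axes_um,
                           voxel_size = voxel_size, fov_um = fov_um,
                           cell_mask = cell2d, nucleus_mask = nuc2d))
}

#' Synthesize forward-model traces (FCS, FRAP, decays)
#'
#' Exact forward model of the matching fit equation plus the stated noise
#' (multiplicative Gaussian for FCS/FRAP curves, Poisson for
#' photon-counting decays).
#'
#' @param modality `"fcs"`, `"frap"`, `"anisotropy_decay"` or
#'   `"lifetime_decay"`.
#' @param params named list of forward-model parameters (defaults match
#'   the dilute-EGFP study conditions: FCS N = 35.714, tau_d = 170e-6 s,
#'   S = 3.633; FRAP D = 0.25 um^2/s, w = 1 um, mobile fraction 0.8,
#'   bleach depth 0.3; anisotropy decay r0 = 0.38, theta_c = 16 ns;
#'   lifetime tau = 2.6 ns, amplitude 1e4 counts).
#' @param noise relative noise level (0 = exact; FCS/FRAP: multiplicative
#'   Gaussian sigma; decays: Poisson on `counts_scale` x model).
#' @param seed RNG seed.
#' @param n_points trace length.
#' @return list with `data` (curve/trace of the shape the matching fit
#'   expects) and `ground_truth`.
#' @export
synth_traces <- function(modality = c("fcs", "frap", "anisotropy_decay",
                                      "lifetime_decay"),
                         params = list(), noise = 0, seed = 1L,
                         n_points = 200) {
  modality <- match.arg(modality)
  if (modality == "fcs") {
    p <- utils::modifyList(list(nmol = 35.714, tau_d = 170e-6, triplet_f = 0,
                                tau_f = 2e-6, anomaly = 1, structure_s = 3.633),
                           params)
    lag <- 10^seq(-6, 0, length.out = n_points)
    g <- fcs_model(lag, p$nmol, p$tau_d, p$triplet_f, p$tau_f, p$anomaly,
                   p$structure_s)
    if (noise > 0)
      g <- with_seed(seed, 1 + (g - 1) * (1 + rnorm(length(g), 0, noise)))
    return(list(data = structure(data.frame(lag = lag, gvalue = g),
                                 class = c("CorrelationCurve", "data.frame")),
                ground_truth = c(p, list(noise = noise, seed = seed))))
  }
  if (modality == "frap") {
    p <- utils::modifyList(list(dcoeff = 0.25, spot_radius = 1,
                                mobile_fraction = 0.8, f0 = 0.3, t_max = NULL),
                           params)
    tau_d <- p$spot_radius^2 / (4 * p$dcoeff)
    t_max <- if (is.null(p$t_max)) 20 * tau_d else p$t_max
    t <- seq(0, t_max, length.out = n_points)
    f_inf <- p$f0 + p$mobile_fraction * (1 - p$f0)
    y <- p$f0 + (f_inf - p$f0) * frap_disk_recovery(t, tau_d)
    if (noise > 0)
      y <- with_seed(seed, y * (1 + rnorm(length(y), 0, noise)))
    return(list(data = structure(data.frame(t = t, intensity = y,
                                            spot_radius = p$spot_radius),
                                 class = c("RecoveryTrace", "data.frame")),
                ground_truth = c(p, list(tau_d = tau_d, f_inf = f_inf,
                                         noise = noise, seed = seed))))
  }
  if (modality == "anisotropy_decay") {
    p <- utils::modifyList(list(r0 = 0.38, theta_c = 16, t_max = 50,
                                counts_scale = 1e4), params)
    t <- seq(0, p$t_max, length.out = n_points)
    r <- p$r0 * exp(-t / p$theta_c)
    if (noise > 0) {
      # emulate photon statistics: r estimated from counts_scale photons
      r <- with_seed(seed, r + rnorm(length(r), 0, noise * p$r0))
    }
    return(list(data = decay_trace(t, r, "anisotropy"),
                ground_truth = c(p, list(noise = noise, seed = seed))))
  }
  p <- utils::modifyList(list(tau = 2.6, amplitude = 1e4, offset = 0,
                              t_max = 25), params)
  t <- seq(0, p$t_max, length.out = n_points)
  y <- p$amplitude * exp(-t / p$tau) + p$offset
  if (noise > 0) y <- with_seed(seed, rpois(length(y), y))
  list(data = decay_trace(t, y, "intensity"),
       ground_truth = c(p, list(noise = noise, seed = seed)))
}

#' Synthesize single-particle trajectories
#'
#' Gaussian increments of variance 2 D dt per axis; `"drift"` adds v dt
#' along x; `"confined"` reflects at the walls of a square box.
#'
#' @param model `"brownian"`, `"drift"` or `"confined"`.
#' @param d_coeff diffusion coefficient (um^2/s).
#' @param v drift speed (um/s).
#' @param box box half-width (um) for the confined model.
#' @param n_tracks,n_steps,dt ensemble shape and frame interval (s).
#' @param seed RNG seed.
#' @return list with `tracks` (data.frame: particle_id, t, x, y) and
#'   `ground_truth`.
#' @export
synth_trajectories <- function(model = c("brownian", "drift", "confined"),
                               d_coeff = 1, v = 0, box = 1,
                               n_tracks = 10, n_steps = 1000, dt = 0.01,
                               seed = 1L) {
  model <- match.arg(model)
  sdstep <- sqrt(2 * d_coeff * dt)
  tracks <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_tracks), function(id) {
      dx <- rnorm(n_steps, if (model == "drift") v * dt else 0, sdstep)
      dy <- rnorm(n_steps, 0, sdstep)
      x <- cumsum(c(0, dx)); y <- cumsum(c(0, dy))
      if (model == "confined") {
        reflect <- function(p) {
          # fold positions into [-box, box] by reflection
          p <- (p + box) %% (4 * box)
          ifelse(p > 2 * box, 4 * box - p, p) - box
        }
        x <- reflect(x); y <- reflect(y)
      }
      data.frame(particle_id = id, t = (0:n_steps) * dt, x = x, y = y)
    }))
  })
  list(tracks = tracks,
       ground_truth = list(model = model, d_coeff = d_coeff, v = v, box = box,
                           n_tracks = n_tracks, n_steps = n_steps, dt = dt,
                           seed = seed))
}

#' Synthesize an osmotic volume-crowding series
#'
#' Volume follows the Boyle-van't Hoff line
#' V / V_iso = v_inactive_frac + (1 - v_inactive_frac) x with
#' x = Pi_iso / Pi; anisotropy follows the concentration-dilution law
#' r(V) = (r_iso - alpha_r)(V_iso / V) + alpha_r plus an optional imposed
#' deviation.
#'
#' @param v_iso isotonic volume (um^3).
#' @param v_inactive_frac osmotically inactive fraction of V_iso.
#' @param r_iso isotonic modal anisotropy.
#' @param alpha_r zero-crowder anisotropy.
#' @param excess_list excess osmolarities (mM; 0 is added if absent).
#' @param iso_osmolarity total isotonic osmolarity (mOsm).
#' @param deviation_term added to r per condition (scalar or vector).
#' @param noise relative Gaussian noise on volume and r.
#' @param seed RNG seed.
#' @return list with `series` (an `OsmoticSeries`) and `ground_truth`.
#' @export
synth_osmotic_series <- function(v_iso = 2000, v_inactive_frac = 0.3,
                                 r_iso = 0.20, alpha_r = 0.169,
                                 excess_list = c(0, 100, 200, 300, 450, 600),
                                 iso_osmolarity = 300, deviation_term = 0,
                                 noise = 0, seed = 1L) {
  if (!any(excess_list == 0)) excess_list <- c(0, excess_list)
  x <- iso_osmolarity / (iso_osmolarity + excess_list)
  vol <- v_iso * (v_inactive_frac + (1 - v_inactive_frac) * x)
  r <- (r_iso - alpha_r) * (v_iso / vol) + alpha_r + deviation_term
  if (noise > 0) {
    vol <- with_seed(seed, vol * (1 + rnorm(length(vol), 0, noise)))
    r <- with_seed(seed + 1L, r * (1 + rnorm(length(r), 0, noise)))
  }
  list(series = osmotic_series(excess_list, vol, r, iso_osmolarity),
       ground_truth = list(v_iso = v_iso, v_inactive_frac = v_inactive_frac,
                           r_iso = r_iso, alpha_r = alpha_r,
                           iso_osmolarity = iso_osmolarity,
                           deviation_term = deviation_term,
                           noise = noise, seed = seed))
}

#' Concentric-disk masks for sector-profile tests
#' @param shape (rows, cols).
#' @param center (x, y), 0-based; defaults to the image center.
#' @param cell_radius,nucleus_radius pixels.
#' @return list with logical `cell_mask`, `nucleus_mask` and a radius map.
#' @export
synth_concentric_disks <- function(shape = c(201, 201), center = NULL,
                                   cell_radius = 90, nucleus_radius = 20) {
  if (is.null(center)) center <- (rev(shape) - 1) / 2
  X <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  Y <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  rad <- sqrt((X - center[1])^2 + (Y - center[2])^2)
  list(cell_mask = rad <= cell_radius, nucleus_mask = rad <= nucleus_radius,
       radius = rad)
}
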