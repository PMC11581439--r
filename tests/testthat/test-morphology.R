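# Volume, height maps, shape metrics, geodesic sector profiles and
# nuclear fractions.

test_that("cell volume counts suprathreshold voxels times voxel volume", {
  vox <- array(0, c(4, 4, 3))
  st0 <- volume_stack(vox, c(0.1, 0.1, 0.1), threshold = 0.5)
  expect_warning(v0 <- cell_volume(st0), "no voxels")
  expect_equal(v0, 0)

  vox[1:2, 1:3, 1:2] <- 1   # 12 voxels
  st <- volume_stack(vox, c(0.1, 0.1, 0.1), threshold = 0.5)
  expect_equal(cell_volume(st), 12 * 0.001, tolerance = 1e-12)
})

test_that("a digitized sphere is within 3% of 4/3 pi r^3 and volumes are additive", {
  ph <- synth_cell_phantom("ellipsoid", voxel_size = c(0.1, 0.1, 0.1),
                           axes_um = c(5, 5, 5))
  v <- cell_volume(ph$stack)
  expect_equal(ph$ground_truth$volume_um3, 4 * pi * 125 / 3, tolerance = 1e-12)
  expect_equal(v, 523.6, tolerance = 0.03)

  # disjoint union: volume of a stack holding two separated boxes
  vox <- array(0, c(10, 20, 4))
  vox[2:4, 2:5, 1:2] <- 1          # 24 voxels
  vox[7:9, 12:19, 3:4] <- 1        # 48 voxels
  st <- volume_stack(vox, c(0.2, 0.2, 0.4), threshold = 0.5)
  expect_equal(cell_volume(st), (24 + 48) * 0.2 * 0.2 * 0.4, tolerance = 1e-12)
})

test_that("height maps integrate to the volume exactly and match analytic profiles", {
  # uniform slab: 10 suprathreshold slices at dz = 0.4 -> height 4 um
  vox <- array(1, c(6, 8, 10))
  st <- volume_stack(vox, c(0.1, 0.1, 0.4), threshold = 0.5)
  hm <- height_map(st)
  expect_true(all(hm$height == 4))
  expect_equal(sum(hm$height) * 0.1 * 0.1, cell_volume(st), tolerance = 1e-12)

  # hemisphere phantom: column heights within one voxel of sqrt(R^2 - rho^2)
  ph <- synth_cell_phantom("hemisphere", voxel_size = c(0.1, 0.1, 0.1),
                           radius_um = 4)
  hm2 <- height_map(ph$stack)
  expect_equal(sum(hm2$height) * 0.01, cell_volume(ph$stack), tolerance = 1e-12)
  fov <- ph$ground_truth$fov_um
  nx <- ncol(hm2$height); ny <- nrow(hm2$height)
  xs <- (seq_len(nx) - 0.5) * 0.1 - fov[1] / 2
  ys <- (seq_len(ny) - 0.5) * 0.1 - fov[2] / 2
  rho <- sqrt(outer(ys^2, xs^2, "+"))
  analytic <- ifelse(rho <= 4, sqrt(pmax(4^2 - rho^2, 0)), 0)
  inside <- rho <= 3.8   # avoid the grazing rim where the analytic slope diverges
  expect_lt(max(abs(hm2$height - analytic)[inside]), 0.15)
  # empty columns are zero
  expect_true(all(hm2$height[rho > 4.2] == 0))
})

test_that("shape metrics reproduce closed-form circularities", {
  d <- synth_concentric_disks(shape = c(201, 201), cell_radius = 50)
  sm <- shape_metrics(d$cell_mask)
  expect_equal(sm$circularity, 1, tolerance = 0.05)
  expect_equal(sm$area, sum(d$cell_mask))

  sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
  expect_equal(shape_metrics(sq)$circularity, pi / 4, tolerance = 0.05)

  rect <- matrix(FALSE, 120, 24); rect[11:110, 11:14] <- TRUE
  expect_equal(shape_metrics(rect)$circularity, 4 * pi * 400 / 208^2,
               tolerance = 0.05)

  # pixel size scales area and perimeter but not circularity
  sm2 <- shape_metrics(sq, pixel_size = 0.5)
  expect_equal(sm2$area, shape_metrics(sq)$area * 0.25)
  expect_equal(sm2$circularity, shape_metrics(sq)$circularity)

  expect_error(shape_metrics(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 10, 10); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(shape_metrics(two), "one connected component")
})

test_that("geodesic distances respect the mask (C-shape forces the long way round)", {
  mask <- matrix(FALSE, 40, 40)
  mask[5:35, 5:35] <- TRUE
  mask[18:22, 10:35] <- FALSE   # slit from the right: a C shape
  seeds <- matrix(FALSE, 40, 40); seeds[10, 30] <- TRUE
  d <- geodesic_distance(mask, seeds)
  expect_true(is.na(d[1, 1]))                      # outside mask
  expect_equal(d[10, 30], 0)
  euclid <- sqrt((30 - 10)^2 + (30 - 30)^2)
  expect_gt(d[30, 30], 2 * euclid)                 # must detour around the slit
})

test_that("sector profiles are flat for constant fields on awkward masks", {
  # C-shaped cell with offset nucleus
  cmask <- matrix(FALSE, 80, 80)
  X <- matrix(0:79, 80, 80, byrow = TRUE); Y <- matrix(0:79, 80, 80)
  rad <- sqrt((X - 40)^2 + (Y - 40)^2)
  cmask[rad <= 35] <- TRUE
  cmask[Y >= 36 & Y <= 44 & X >= 40] <- FALSE
  nmask <- rad <= 8 & cmask
  suppressWarnings(sp <- geodesic_sector_profile(matrix(0.2, 80, 80), cmask, nmask, 5))
  expect_equal(sp$mean_norm_r, rep(1, 5), tolerance = 1e-12)

  # star-shaped mask
  ang <- atan2(Y - 40, X - 40)
  star <- rad <= 20 + 12 * cos(5 * ang)
  nstar <- rad <= 6
  suppressWarnings(sp2 <- geodesic_sector_profile(matrix(0.31, 80, 80), star, nstar, 5))
  pop <- sp2$n_pixels > 0   # thin lobes may leave inner bands unpopulated
  expect_gte(sum(pop), 3)
  expect_equal(sp2$mean_norm_r[pop], rep(1, sum(pop)), tolerance = 1e-12)
})

test_that("sector profiles reproduce an imposed radial gradient on concentric disks", {
  d <- synth_concentric_disks(shape = c(201, 201), cell_radius = 100,
                              nucleus_radius = 20)
  # linear gradient from 0.18 at the nucleus boundary to 0.23 at the edge
  f_true <- pmin(pmax((d$radius - 20) / 80, 0), 1)
  rmap <- 0.18 + 0.05 * f_true
  sp <- geodesic_sector_profile(rmap, d$cell_mask, d$nucleus_mask, 5)
  expect_equal(nrow(sp), 5)
  expect_equal(sp$sector_lo, c(0, 0.2, 0.4, 0.6, 0.8))
  centers <- (sp$sector_lo + sp$sector_hi) / 2
  expected <- 0.18 + 0.05 * centers
  expect_equal(sp$mean_r, expected, tolerance = 0.02 * max(expected) / min(expected))
  expect_equal(sp$mean_norm_r, expected / expected[1], tolerance = 0.02)
  expect_error(geodesic_sector_profile(rmap, d$nucleus_mask, d$cell_mask),
               "inside")
})

test_that("nuclear fraction uses the largest-nucleus slice and sums intensities", {
  stack <- array(0, c(20, 20, 3))
  cellm <- array(FALSE, c(20, 20, 3)); nucm <- array(FALSE, c(20, 20, 3))
  cellm[3:18, 3:18, ] <- TRUE
  nucm[8:12, 8:12, 2] <- TRUE     # largest nucleus on slice 2
  nucm[9:11, 9:11, 1] <- TRUE
  # all intensity inside the nucleus on slice 2
  stack[8:12, 8:12, 2] <- 7
  expect_equal(nuclear_fraction(stack, cellm, nucm), 1)

  # uniform intensity, nucleus = half the cell area
  stack2 <- array(0, c(20, 20, 3)); stack2[, , 2] <- 1
  cellm2 <- array(FALSE, c(20, 20, 3)); cellm2[1:10, 1:20, 2] <- TRUE
  nucm2 <- array(FALSE, c(20, 20, 3)); nucm2[1:10, 1:10, 2] <- TRUE
  expect_equal(nuclear_fraction(stack2, cellm2, nucm2), 0.5)

  # imposed translocation: 70% of the signal inside the nucleus
  stack3 <- array(0, c(20, 20, 3))
  stack3[, , 2][cellm2[, , 2]] <- 30 / sum(cellm2[, , 2] & !nucm2[, , 2])
  stack3[, , 2][nucm2[, , 2]] <- 70 / sum(nucm2[, , 2])
  expect_equal(nuclear_fraction(stack3, cellm2, nucm2), 0.7, tolerance = 0.01)

  empty <- array(0, c(20, 20, 3))
  expect_error(nuclear_fraction(empty, cellm2, nucm2), "zero cell intensity")
})

test_that("Otsu threshold separates a bimodal stack", {
  set.seed(61)
  x <- c(rnorm(5000, 100, 10), rnorm(2000, 800, 50))
  th <- otsu_threshold(x)
  expect_gt(th, 130); expect_lt(th, 700)          # clear of the low mode
  expect_equal(mean(x > th), 2 / 7, tolerance = 0.02)
})
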