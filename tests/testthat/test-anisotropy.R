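# G-factor calibration, background subtraction, per-pixel anisotropy and
# per-cell modal statistics.

test_that("G-factor map reproduces imposed channel ratios", {
  pair_eq <- structure(list(parallel = matrix(1000, 20, 30),
                            perpendicular = matrix(1000, 20, 30),
                            registered = TRUE), class = "PolarizedFramePair")
  g1 <- compute_gfactor_map(list(pair_eq))
  expect_equal(g1$g, matrix(1, 20, 30), tolerance = 1e-12, ignore_attr = TRUE)

  pair_2x <- pair_eq; pair_2x$parallel <- matrix(2000, 20, 30)
  g2 <- compute_gfactor_map(list(pair_2x))
  expect_equal(unique(as.vector(g2$g)), 2)

  expect_error(compute_gfactor_map(list()), "empty")
})

test_that("a vignetted G field is recovered within 1% from noisy references", {
  nr <- 60; nc <- 80
  gtrue <- make_g_field(nr, nc)
  set.seed(31)
  refs <- lapply(1:8, function(i) {
    iperp <- matrix(20000, nr, nc)
    structure(list(parallel = matrix(rpois(nr * nc, gtrue * iperp), nr, nc),
                   perpendicular = matrix(rpois(nr * nc, iperp), nr, nc),
                   registered = TRUE), class = "PolarizedFramePair")
  })
  gm <- compute_gfactor_map(refs)
  expect_lt(max(abs(gm$g - gtrue) / gtrue), 0.01)
})

test_that("low-signal pixels are invalidated in the G map", {
  perp <- matrix(1000, 10, 10); perp[3, 4] <- 0
  pair <- structure(list(parallel = matrix(1000, 10, 10), perpendicular = perp,
                         registered = TRUE), class = "PolarizedFramePair")
  gm <- compute_gfactor_map(list(pair), noise_floor = 1)
  expect_true(is.nan(gm$g[3, 4]))
  expect_false(anyNA(gm$g[-33]))
})

test_that("background subtraction is pixel-wise, clipped at zero, shape-checked", {
  fr <- dual_view_frame(matrix(100, 4, 6))
  bg30 <- dual_view_frame(matrix(30, 4, 6))
  expect_true(all(subtract_background(fr, bg30)$pixels == 70))
  expect_true(all(subtract_background(fr, fr)$pixels == 0))
  expect_identical(subtract_background(fr, dual_view_frame(matrix(0, 4, 6)))$pixels,
                   fr$pixels)
  big <- dual_view_frame(matrix(200, 4, 6))
  expect_true(all(subtract_background(fr, big)$pixels == 0))  # clipped
  expect_error(subtract_background(fr, dual_view_frame(matrix(0, 4, 8))), "differ")
})

test_that("the anisotropy relation gives hand-computed values and thresholds gate validity", {
  mk_pair <- function(ipar, iperp) structure(
    list(parallel = matrix(ipar, 2, 2), perpendicular = matrix(iperp, 2, 2),
         registered = TRUE), class = "PolarizedFramePair")
  # Ipar = Iperp, g = 1 -> r = 0
  am0 <- compute_anisotropy_map(mk_pair(20000, 20000), 1)
  expect_equal(unique(as.vector(am0$r)), 0)
  # Ipar = 150, Iperp = 100, g = 1 -> r = 50/350
  am1 <- compute_anisotropy_map(mk_pair(150, 100), 1, threshold_low = 0,
                                threshold_high = 1e6)
  expect_equal(unique(as.vector(am1$r)), 50 / 350, tolerance = 1e-12)
  # default window rejects a parallel count outside 15000-50000
  am2 <- compute_anisotropy_map(mk_pair(60000, 40000), 1)
  expect_false(any(am2$valid))
  am3 <- compute_anisotropy_map(mk_pair(20000, 15000), 1)
  expect_true(all(am3$valid))
})

test_that("imposed (r*, g*) fields round-trip to 1e-10 and r is scale-invariant", {
  nr <- 50; nc <- 60
  rstar <- make_r_field(nr, nc)
  gstar <- make_g_field(nr, nc)
  I <- matrix(30000, nr, nc)
  ipar <- I * (1 + 2 * rstar) / 3
  iperp <- I * (1 - rstar) / (3 * gstar)
  pair <- structure(list(parallel = ipar, perpendicular = iperp, registered = TRUE),
                    class = "PolarizedFramePair")
  gm <- structure(list(g = gstar, source = "imposed"), class = "GFactorMap")
  am <- compute_anisotropy_map(pair, gm, 0, 1e9)
  expect_lt(max(abs(am$r - rstar)), 1e-10)

  # multiplying both channels by a positive constant leaves r unchanged
  pair2 <- pair; pair2$parallel <- 3.7 * ipar; pair2$perpendicular <- 3.7 * iperp
  am2 <- compute_anisotropy_map(pair2, gm, 0, 1e9)
  expect_equal(am2$r, am$r, tolerance = 1e-12)
})

test_that("modal anisotropy finds the dominant population, not the mean", {
  set.seed(32)
  # 90% of pixels at 0.20, 10% at 0.30 (tight subpopulations)
  n <- 10000
  vals <- c(rnorm(0.9 * n, 0.20, 0.004), rnorm(0.1 * n, 0.30, 0.004))
  r <- matrix(vals, 100, 100)
  am <- structure(list(r = r, valid = matrix(TRUE, 100, 100)),
                  class = "AnisotropyMap")
  rec <- modal_anisotropy(am, matrix(1L, 100, 100))
  expect_equal(rec$modal_r, 0.20, tolerance = 0.01)
  expect_equal(rec$mean_r, 0.21, tolerance = 0.01)

  # constant field: mode equals the value to within the grid step
  am2 <- structure(list(r = matrix(0.25, 30, 30), valid = matrix(TRUE, 30, 30)),
                   class = "AnisotropyMap")
  rec2 <- modal_anisotropy(am2, matrix(1L, 30, 30), bandwidth = 0.005,
                           min_pixels = 100)
  expect_equal(rec2$modal_r, 0.25, tolerance = 2e-4)
})

test_that("mode of a symmetric unimodal sample matches its mean within kernel tolerance", {
  set.seed(33)
  r <- matrix(rnorm(1e4, 0.22, 0.01), 100, 100)
  am <- structure(list(r = r, valid = matrix(TRUE, 100, 100)),
                  class = "AnisotropyMap")
  rec <- modal_anisotropy(am, matrix(1L, 100, 100))
  expect_lt(abs(rec$modal_r - 0.22), 0.002)
  expect_lt(abs(rec$modal_r - rec$mean_r), 0.002)
})

test_that("cells below the pixel minimum are kept as NA records with a warning", {
  r <- matrix(0.2, 20, 20)
  lab <- matrix(1L, 20, 20); lab[1:3, 1:3] <- 2L
  am <- structure(list(r = r, valid = matrix(TRUE, 20, 20)),
                  class = "AnisotropyMap")
  expect_warning(rec <- modal_anisotropy(am, lab, min_pixels = 200,
                                         bandwidth = 0.01), "valid pixels")
  expect_equal(nrow(rec), 2)
  expect_true(is.na(rec$modal_r[rec$cell_id == 2]))
  expect_equal(rec$modal_r[rec$cell_id == 1], 0.2, tolerance = 1e-3)
})

test_that("timecourse percentages are relative to each cell's baseline", {
  rec <- data.frame(cell_id = rep(1:2, each = 3),
                    timestamp = rep(c(0, 600, 1200), 2),
                    modal_r = c(0.20, 0.22, 0.20, 0.25, 0.25, 0.30))
  tc <- anisotropy_timecourse(rec, baseline_window = c(0, 0))
  expect_equal(tc$per_cell$delta_r_pct,
               c(0, 10, 0, 0, 0, 20), tolerance = 1e-12)
  expect_equal(tc$summary$mean_delta_r_pct, c(0, 5, 10), tolerance = 1e-12)
  # constant series -> identically zero
  const <- data.frame(cell_id = 1, timestamp = c(0, 1, 2), modal_r = 0.2)
  expect_true(all(anisotropy_timecourse(const, c(0, 0))$per_cell$delta_r_pct == 0))
})

test_that("bleach test pairs cells and reports both percentage changes", {
  pre <- data.frame(cell_id = 1:3, modal_r = c(0.20, 0.20, 0.21),
                    mean_intensity = c(1000, 2000, 1500))
  post <- data.frame(cell_id = c(1, 2), modal_r = c(0.20, 0.216),
                     mean_intensity = c(500, 1400))
  expect_message(bt <- homo_fret_bleach_test(pre, post), "unmatched")
  expect_equal(nrow(bt$per_cell), 2)
  expect_equal(bt$per_cell$delta_r_pct, c(0, 8), tolerance = 1e-9)
  expect_equal(bt$per_cell$delta_intensity_pct, c(-50, -30), tolerance = 1e-9)
  expect_equal(bt$summary$n_unmatched, 1)
})
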