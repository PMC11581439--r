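# Decay fitting, Perrin / Strickler-Berg relations, phasor coordinates
# and the crowder calibration.

test_that("noiseless mono-exponential decays are recovered essentially exactly", {
  a <- synth_traces("anisotropy_decay", params = list(r0 = 0.38, theta_c = 16))
  fa <- fit_anisotropy_decay(a$data)
  expect_equal(fa$r0, 0.38, tolerance = 1e-8)
  expect_equal(fa$theta_c, 16, tolerance = 1e-8)
  expect_false(fa$non_rotating)

  l <- synth_traces("lifetime_decay", params = list(tau = 2.6))
  fl <- fit_lifetime_decay(l$data)
  expect_equal(fl$tau, 2.6, tolerance = 1e-8)
})

test_that("a constant offset leaves the fitted lifetime unchanged within 1%", {
  l0 <- synth_traces("lifetime_decay", params = list(tau = 2.6, offset = 0))
  l50 <- synth_traces("lifetime_decay", params = list(tau = 2.6, offset = 50))
  expect_equal(fit_lifetime_decay(l50$data)$tau,
               fit_lifetime_decay(l0$data)$tau, tolerance = 0.01)
  expect_equal(fit_lifetime_decay(l50$data)$offset, 50, tolerance = 1e-6)
})

test_that("a two-component decay yields an intermediate tau and structured residuals", {
  t <- seq(0, 25, length.out = 300)
  y <- 7000 * exp(-t / 1.5) + 3000 * exp(-t / 4)
  fit <- fit_lifetime_decay(decay_trace(t, y, "intensity"), fit_offset = FALSE)
  expect_gt(fit$tau, 1.5)
  expect_lt(fit$tau, 4)
  # residuals show serial structure (runs), unlike white noise
  expect_gt(abs(stats::cor(fit$residual[-1], fit$residual[-length(fit$residual)])), 0.5)
})

test_that("a flat anisotropy trace is flagged non-rotating", {
  flat <- decay_trace(seq(0, 50, length.out = 100), rep(0.3, 100), "anisotropy")
  fit <- fit_anisotropy_decay(flat)
  expect_true(fit$non_rotating)
  expect_equal(fit$theta_c, Inf)
  expect_equal(fit$r0, 0.3)
})

test_that("the Perrin relation matches its limits and hand arithmetic", {
  expect_equal(perrin_steady_state(0.38, 0, 14), 0.38)            # no rotation during emission
  expect_equal(perrin_steady_state(0.38, 14, 14), 0.19)           # tau = theta_c halves r
  expect_equal(perrin_steady_state(0.38, 2.6, 14), 0.38 / (1 + 2.6 / 14),
               tolerance = 1e-12)
  expect_equal(perrin_steady_state(0.38, 2.6, 14), 0.32049, tolerance = 1e-4)
  expect_error(perrin_steady_state(0.38, 2.6, 0), "positive")
})

test_that("Perrin round trip: fitted decay parameters reproduce the forward steady-state r", {
  a <- synth_traces("anisotropy_decay", params = list(r0 = 0.36, theta_c = 14))
  fa <- fit_anisotropy_decay(a$data)
  tau <- 2.6
  expect_equal(perrin_steady_state(fa$r0, tau, fa$theta_c),
               perrin_steady_state(0.36, tau, 14), tolerance = 1e-7)
})

test_that("map reconstruction is pixel-wise Perrin with an exact global scale", {
  r0m <- matrix(0.38, 5, 6); taum <- matrix(2.6, 5, 6); thm <- matrix(14, 5, 6)
  rec <- reconstruct_anisotropy_map(r0m, taum, thm)
  expect_equal(unique(as.vector(rec)), perrin_steady_state(0.38, 2.6, 14))
  expect_equal(reconstruct_anisotropy_map(r0m, taum, thm, scale = 0.9), 0.9 * rec)
  expect_error(reconstruct_anisotropy_map(r0m, taum, matrix(14, 6, 5)), "shape")
  # least-squares scale recovers an imposed instrumental factor
  expect_equal(instrumental_scale(0.93 * rec, rec), 0.93, tolerance = 1e-12)
})

test_that("Strickler-Berg scaling follows (n_ref/n_new)^2 and inverts", {
  expect_equal(strickler_berg_scale(2.6, 1.33, 1.33), 2.6)
  expect_equal(strickler_berg_scale(2.6, 1.33, 1.40), 2.6 * (1.33 / 1.40)^2,
               tolerance = 1e-12)
  expect_equal(strickler_berg_scale(2.6, 1.33, 1.40), 2.3465, tolerance = 1e-4)
  expect_equal(strickler_berg_scale(2.6, 1.33, 2 * 1.33), 2.6 / 4)
  expect_equal(strickler_berg_scale(strickler_berg_scale(2.6, 1.33, 1.4), 1.4, 1.33),
               2.6, tolerance = 1e-12)
})

test_that("phasors of mono-exponentials sit on the universal semicircle", {
  omega <- 2 * pi / 12.5
  for (tau in c(0.5, 1, 2.6, 4)) {
    # fine midpoint binning over a window long enough to kill truncation
    dt <- 1e-3
    t <- seq(dt / 2, 60 * tau, by = dt)
    trace <- decay_trace(t, exp(-t / tau), "intensity")
    ph <- phasor_transform(trace, omega)
    cf <- phasor_of_lifetime(tau, omega)
    expect_equal(ph$gcoord, cf$gcoord, tolerance = 1e-6)
    expect_equal(ph$scoord, cf$scoord, tolerance = 1e-6)
    expect_equal((ph$gcoord - 0.5)^2 + ph$scoord^2, 0.25, tolerance = 1e-6)
  }
})

test_that("a delta-like decay sits at (1, 0) and mixtures lie on the chord", {
  omega <- 2 * pi / 12.5
  dt <- 1e-3; t <- seq(dt / 2, 80, by = dt)
  near_delta <- phasor_transform(decay_trace(t, exp(-t / 1e-3), "intensity"), omega)
  expect_equal(near_delta$gcoord, 1, tolerance = 1e-2)
  expect_equal(near_delta$scoord, 0, tolerance = 1e-2)

  p1 <- phasor_of_lifetime(1, omega); p2 <- phasor_of_lifetime(4, omega)
  mix <- phasor_transform(decay_trace(t, exp(-t / 1) + exp(-t / 4), "intensity"), omega)
  # intensity weights: each component contributes proportionally to its area (tau)
  w1 <- 1 / (1 + 4); w2 <- 4 / (1 + 4)
  expect_equal(mix$gcoord, w1 * p1$gcoord + w2 * p2$gcoord, tolerance = 1e-5)
  expect_equal(mix$scoord, w1 * p1$scoord + w2 * p2$scoord, tolerance = 1e-5)
  expect_error(phasor_transform(decay_trace(1:5, rep(0, 5), "intensity")), "zero")
})

test_that("crowder calibration recovers an exact line and tolerates noise", {
  r <- seq(0.17, 0.23, by = 0.01)
  conc <- 10 * (r - 0.17)
  cal <- calibrate_crowder(conc, r)
  expect_equal(cal$m, 10, tolerance = 1e-9)
  expect_equal(cal$alpha_r, 0.17, tolerance = 1e-9)
  expect_equal(crowder_concentration(cal, 0.17), 0, tolerance = 1e-9)
  expect_equal(crowder_concentration(cal, r), conc, tolerance = 1e-9)

  set.seed(41)
  errs <- replicate(50, {
    rn <- r + rnorm(length(r), 0, 0.001)
    c(calibrate_crowder(conc, rn)$m, calibrate_crowder(conc, rn)$alpha_r)
  })
  expect_equal(mean(errs[1, ]), 10, tolerance = 0.05)
  expect_equal(mean(errs[2, ]), 0.17, tolerance = 0.05 * 0.17)
  expect_error(calibrate_crowder(c(1, 1, 1), c(0.1, 0.2, 0.3)), "degenerate")
})
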