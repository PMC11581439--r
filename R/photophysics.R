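# Time-resolved photophysics: anisotropy and lifetime decay fits, the
# Perrin and Strickler-Berg relations, phasor coordinates and the linear
# crowder calibration of steady-state anisotropy.

#' Construct a decay trace
#' @param t time axis (ns), strictly increasing.
#' @param counts per-bin values (photon counts for intensity traces,
#'   anisotropy values for anisotropy traces).
#' @param kind `"intensity"` or `"anisotropy"`.
#' @return A `DecayTrace` data.frame.
#' @export
decay_trace <- function(t, counts, kind = c("intensity", "anisotropy")) {
  kind <- match.arg(kind)
  stopifnot(length(t) == length(counts), all(diff(t) > 0))
  if (kind == "intensity" && any(counts < 0))
    stop("intensity counts must be nonnegative")
  structure(data.frame(t = t, counts = counts),
            class = c("DecayTrace", "data.frame"), kind = kind)
}

#' Fit a mono-exponential anisotropy decay r(t) = r0 exp(-t / theta_c)
#'
#' Fitted directly on the r(t) curve by unweighted least squares. A trace
#' with no measurable decay over its window is flagged `non_rotating`
#' (theta_c = Inf) instead of chasing a divergent fit.
#'
#' @param trace an anisotropy `DecayTrace`.
#' @param fit_start fit from this time onward (ns).
#' @return An `AnisotropyDecayFit`: list with `r0`, `theta_c` (ns),
#'   `residual` series and `non_rotating` flag.
#' @export
fit_anisotropy_decay <- function(trace, fit_start = 0) {
  stopifnot(identical(attr(trace, "kind"), "anisotropy"))
  sel <- trace$t >= fit_start
  if (sum(sel) < 20) stop("need at least 20 bins after fit_start")
  t <- trace$t[sel]; r <- trace$counts[sel]
  pos <- r > 0
  if (sum(pos) < 3) stop("too few positive anisotropy values to fit")
  lf <- lm(log(r[pos]) ~ t[pos])
  slope <- coef(lf)[2]
  if (!is.finite(slope) || slope >= -1e-12 / max(t)) {
    return(structure(list(r0 = mean(r), theta_c = Inf,
                          residual = r - mean(r), non_rotating = TRUE),
                     class = "AnisotropyDecayFit"))
  }
  start <- list(r0 = unname(exp(coef(lf)[1])), theta_c = unname(-1 / slope))
  fit <- minpack.lm::nlsLM(r ~ r0 * exp(-t / theta_c), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  structure(list(r0 = unname(cf["r0"]), theta_c = unname(cf["theta_c"]),
                 residual = unname(residuals(fit)), non_rotating = FALSE),
            class = "AnisotropyDecayFit")
}

#' Fit a mono-exponential intensity decay A exp(-t / tau) + offset
#'
#' Tail fit after the excitation peak. A two-component decay still returns
#' a single intermediate tau; structured residuals (returned for
#' inspection) are the caller's cue that one exponential is not enough.
#'
#' @param trace an intensity `DecayTrace`.
#' @param fit_start start of the tail-fit window (ns).
#' @param fit_offset fit a constant background term (default TRUE).
#' @return A `LifetimeFit`: list with `tau` (ns), `amplitude`, `offset`,
#'   `residual`.
#' @export
fit_lifetime_decay <- function(trace, fit_start = 0, fit_offset = TRUE) {
  stopifnot(identical(attr(trace, "kind"), "intensity"))
  sel <- trace$t >= fit_start
  t <- trace$t[sel]; y <- trace$counts[sel]
  if (length(t) < 5) stop("too few bins after fit_start")
  off0 <- if (fit_offset) min(y) else 0
  ypos <- pmax(y - off0, max(y) * 1e-6)
  lf <- lm(log(ypos) ~ t)
  tau0 <- max(-1 / coef(lf)[2], diff(range(t)) / 100)
  start <- list(A = max(y) - off0, tau = unname(tau0))
  if (fit_offset) {
    fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau) + offset,
                             start = c(start, offset = off0),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau), start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- coef(fit)
  structure(list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
                 offset = if (fit_offset) unname(cf["offset"]) else 0,
                 residual = unname(residuals(fit))),
            class = "LifetimeFit")
}

#' Perrin relation: steady-state anisotropy from lifetime and rotation
#'
#' r = r0 / (1 + tau / theta_c): emission that outlives rotational
#' memory (tau >> theta_c) is depolarized; slow rotors keep r near r0.
#'
#' @param r0 intrinsic anisotropy (no rotation during emission).
#' @param tau fluorescence lifetime (ns).
#' @param theta_c rotational correlation time (ns), > 0.
#' @return steady-state anisotropy.
#' @export
perrin_steady_state <- function(r0, tau, theta_c) {
  if (any(theta_c <= 0)) stop("theta_c must be positive")
  r0 / (1 + tau / theta_c)
}

#' Rotational correlation time from the Stokes-Einstein-Debye relation
#'
#' theta_c = eta V / (kB T), with eta the solution viscosity (Pa s),
#' V the hydrodynamic volume (m^3) and T the temperature (K).
#' @param eta viscosity (Pa s).
#' @param vol_h hydrodynamic volume (m^3).
#' @param temperature K.
#' @return theta_c in ns.
#' @export
rotational_correlation_time <- function(eta, vol_h, temperature = 298.15) {
  stopifnot(eta > 0, vol_h > 0, temperature > 0)
  kb <- 1.380649e-23
  eta * vol_h / (kb * temperature) * 1e9
}

#' Reconstruct a steady-state anisotropy map via the Perrin relation
#'
#' Pixel-wise Perrin evaluation of co-registered r0, tau and theta_c maps,
#' times an optional global instrumental scale factor that absorbs the
#' transmission difference between the time-resolved (confocal) and
#' steady-state (wide-field) detection paths.
#'
#' @param r0_map,tau_map,theta_map numeric matrices of identical shape.
#' @param scale global multiplicative correction (default 1).
#' @return matrix of reconstructed r values.
#' @export
reconstruct_anisotropy_map <- function(r0_map, tau_map, theta_map, scale = 1) {
  if (!identical(dim(r0_map), dim(tau_map)) ||
      !identical(dim(r0_map), dim(theta_map)))
    stop("maps must share one shape")
  scale * r0_map / (1 + tau_map / theta_map)
}

#' Estimate the global instrumental scale between two anisotropy maps
#' @param measured,reconstructed matrices on common valid pixels.
#' @return least-squares scalar: measured ~ scale * reconstructed.
#' @export
instrumental_scale <- function(measured, reconstructed) {
  ok <- is.finite(measured) & is.finite(reconstructed)
  sum(measured[ok] * reconstructed[ok]) / sum(reconstructed[ok]^2)
}

#' Strickler-Berg scaling of lifetime with refractive index
#'
#' The radiative rate grows as n^2, so tau scales as 1/n^2:
#' tau_new = tau_ref (n_ref / n_new)^2.
#'
#' @param tau_ref reference lifetime (ns).
#' @param n_ref,n_new refractive indices (> 1).
#' @return scaled lifetime (ns).
#' @export
strickler_berg_scale <- function(tau_ref, n_ref, n_new) {
  if (any(c(n_ref, n_new) <= 1)) stop("refractive indices must exceed 1")
  tau_ref * (n_ref / n_new)^2
}

#' Phasor coordinates of a decay trace
#'
#' Fit-free first-harmonic projection: g = sum I cos(wt) / sum I,
#' s = sum I sin(wt) / sum I over the recorded bins. Every
#' mono-exponential decay lands on the universal semicircle
#' (g - 1/2)^2 + s^2 = 1/4; mixtures fall on chords inside it.
#'
#' @param trace an intensity `DecayTrace`.
#' @param omega angular frequency (rad/ns); default 2 pi / T with T the
#'   trace window (first-harmonic convention).
#' @return A `PhasorPoint`: list with `gcoord`, `scoord`, `omega`.
#' @export
phasor_transform <- function(trace, omega = NULL) {
  stopifnot(identical(attr(trace, "kind"), "intensity"))
  tot <- sum(trace$counts)
  if (tot <= 0) stop("zero total intensity; phasor undefined")
  if (is.null(omega)) omega <- 2 * pi / diff(range(trace$t))
  structure(list(gcoord = sum(trace$counts * cos(omega * trace$t)) / tot,
                 scoord = sum(trace$counts * sin(omega * trace$t)) / tot,
                 omega = omega),
            class = "PhasorPoint")
}

#' Closed-form phasor of a mono-exponential lifetime
#' @param tau lifetime (ns).
#' @param omega angular frequency (rad/ns).
#' @return list with `gcoord`, `scoord` on the universal semicircle.
#' @export
phasor_of_lifetime <- function(tau, omega) {
  wt <- omega * tau
  list(gcoord = 1 / (1 + wt^2), scoord = wt / (1 + wt^2))
}

#' Calibrate anisotropy against crowder concentration
#'
#' Fits the linear relation r = c / m + alpha_r by ordinary least squares,
#' so concentration can be read back as MMC = m * r - m * alpha_r; alpha_r
#' is the anisotropy of the probe at zero crowder.
#'
#' @param concentrations crowder concentrations (mM), >= 3 distinct.
#' @param r_values matching anisotropy values.
#' @param crowder species label.
#' @return A `CrowderCalibration`: list with `m` (mM per anisotropy unit),
#'   `alpha_r`, `r_squared`, `crowder`.
#' @export
calibrate_crowder <- function(concentrations, r_values, crowder = "unknown") {
  stopifnot(length(concentrations) == length(r_values))
  if (length(concentrations) < 3) stop("need at least 3 calibration points")
  if (length(unique(concentrations)) < 2) stop("degenerate concentration axis")
  fit <- lm(r_values ~ concentrations)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0) stop("no anisotropy response to crowder")
  ss_tot <- sum((r_values - mean(r_values))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  structure(list(m = 1 / slope, alpha_r = unname(coef(fit)[1]),
                 r_squared = r2, crowder = crowder),
            class = "CrowderCalibration")
}

#' Convert anisotropy to crowder concentration with a calibration
#' @param calibration a `CrowderCalibration`.
#' @param r anisotropy value(s).
#' @return concentration(s), mM.
#' @export
crowder_concentration <- function(calibration, r) {
  calibration$m * r - calibration$m * calibration$alpha_r
}
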