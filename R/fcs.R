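# Fluorescence correlation spectroscopy: the 3D (anomalous) diffusion
# autocorrelation model with triplet term, curve fitting, and the
# amplitude -> number density -> molar concentration chain through the
# confocal observation volume.

#' Confocal observation geometry
#'
#' Radii are 1/e^2 half-axes of the Gaussian-Lorentzian focus. The
#' effective ellipsoidal volume is (pi/2)^(3/2) wxy^2 wz, the convention
#' under which the theoretical radii for 488 nm / NA 1.2 / n 1.33 give
#' 0.109 fL.
#'
#' @param omega_xy lateral 1/e^2 radius (micrometers).
#' @param omega_z axial 1/e^2 radius (micrometers).
#' @param wavelength,num_aperture,ref_index optional provenance fields.
#' @return A `ConfocalGeometry`: adds `structure_s` = wz/wxy and `v_eff`
#'   in femtoliters.
#' @export
confocal_geometry <- function(omega_xy, omega_z, wavelength = NA,
                              num_aperture = NA, ref_index = NA) {
  stopifnot(omega_xy > 0, omega_z > omega_xy)
  structure(list(omega_xy = omega_xy, omega_z = omega_z,
                 wavelength = wavelength, num_aperture = num_aperture,
                 ref_index = ref_index,
                 structure_s = omega_z / omega_xy,
                 v_eff = effective_volume(omega_xy, omega_z)),
            class = "ConfocalGeometry")
}

#' Diffraction-limited beam radii
#'
#' wxy = 0.61 lambda / NA (lateral), wz = 2 n lambda / NA^2 (axial).
#'
#' @param wavelength micrometers.
#' @param num_aperture objective NA (< ref_index).
#' @param ref_index immersion/sample refractive index.
#' @return list with `omega_xy`, `omega_z` in micrometers.
#' @export
theoretical_beam_radii <- function(wavelength, num_aperture, ref_index) {
  stopifnot(wavelength > 0, num_aperture > 0, ref_index > num_aperture)
  list(omega_xy = 0.61 * wavelength / num_aperture,
       omega_z = 2 * ref_index * wavelength / num_aperture^2)
}

#' Effective confocal volume in femtoliters
#'
#' v = (pi/2)^(3/2) wxy^2 wz with radii as 1/e^2 half-axes in
#' micrometers (1 um^3 = 1 fL).
#' @param omega_xy,omega_z radii (micrometers).
#' @return volume (fL).
#' @export
effective_volume <- function(omega_xy, omega_z) {
  stopifnot(omega_xy > 0, omega_z > 0)
  (pi / 2)^(3 / 2) * omega_xy^2 * omega_z
}

#' FCS autocorrelation model for 3D anomalous diffusion with triplet
#'
#' G(tau) = 1 + (1/N) [(1 - F + F exp(-tau/tau_f)) / (1 - F)]
#'              [1 + (tau/tau_d)^alpha]^-1
#'              [1 + (1/S^2)(tau/tau_d)^alpha]^-1/2
#'
#' @param lag lag times (s).
#' @param nmol mean molecules in the focus, > 0.
#' @param tau_d diffusion time (s).
#' @param triplet_f triplet fraction in [0, 1).
#' @param tau_f triplet correlation time (s).
#' @param anomaly diffusion anomaly exponent alpha (1 = free diffusion).
#' @param structure_s aspect ratio S = wz/wxy, > 1.
#' @return G(tau) values.
#' @export
fcs_model <- function(lag, nmol, tau_d, triplet_f = 0, tau_f = 1e-6,
                      anomaly = 1, structure_s = 3.633) {
  stopifnot(nmol > 0, tau_d > 0, triplet_f >= 0, triplet_f < 1,
            structure_s > 1)
  x <- (lag / tau_d)^anomaly
  trip <- (1 - triplet_f + triplet_f * exp(-lag / tau_f)) / (1 - triplet_f)
  1 + (1 / nmol) * trip / (1 + x) / sqrt(1 + x / structure_s^2)
}

#' Fit an FCS autocorrelation curve
#'
#' Nonlinear least squares for (N, tau_d), with the anomaly exponent fixed
#' at 1 and the triplet fraction fixed at 0 by default (the treatment used
#' for dilute EGFP solutions); either can be freed. S is fixed from the
#' confocal geometry.
#'
#' @param curve data.frame with `lag` (s, strictly increasing) and
#'   `gvalue` columns, or a `CorrelationCurve`.
#' @param fix_anomaly keep alpha = 1 (default TRUE).
#' @param fix_triplet_zero keep F = 0 (default TRUE).
#' @param structure_s aspect ratio S (default 3.633 = 0.901/0.248).
#' @return An `FcsFit`: list with `nmol`, `tau_d`, `triplet_f`, `tau_f`,
#'   `anomaly`, `structure_s`, `g0` (fitted zero-lag amplitude),
#'   `residual`.
#' @export
fit_fcs <- function(curve, fix_anomaly = TRUE, fix_triplet_zero = TRUE,
                    structure_s = 3.633) {
  lag <- curve$lag; g <- curve$gvalue
  stopifnot(length(lag) >= 10, all(diff(lag) > 0), all(lag > 0))
  amp0 <- max(g) - 1
  if (amp0 <= 1e-12) stop("no correlation amplitude: curve is flat at 1")
  n0 <- 1 / amp0
  half <- 1 + amp0 / 2
  tau0 <- lag[which.min(abs(g - half))]
  if (fix_anomaly && fix_triplet_zero) {
    fit <- minpack.lm::nlsLM(
      g ~ fcs_model(lag, nmol, tau_d, structure_s = structure_s),
      start = list(nmol = n0, tau_d = tau0),
      lower = c(1e-9, min(lag) / 10), upper = c(Inf, max(lag) * 10),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else if (fix_anomaly) {
    fit <- minpack.lm::nlsLM(
      g ~ fcs_model(lag, nmol, tau_d, triplet_f, tau_f, structure_s = structure_s),
      start = list(nmol = n0, tau_d = tau0, triplet_f = 0.1, tau_f = min(lag) * 5),
      lower = c(1e-9, min(lag) / 10, 0, min(lag) / 100),
      upper = c(Inf, max(lag) * 10, 0.999, max(lag)),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else if (fix_triplet_zero) {
    fit <- minpack.lm::nlsLM(
      g ~ fcs_model(lag, nmol, tau_d, anomaly = anomaly, structure_s = structure_s),
      start = list(nmol = n0, tau_d = tau0, anomaly = 1),
      lower = c(1e-9, min(lag) / 10, 0.1), upper = c(Inf, max(lag) * 10, 2),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    fit <- minpack.lm::nlsLM(
      g ~ fcs_model(lag, nmol, tau_d, triplet_f, tau_f, anomaly, structure_s),
      start = list(nmol = n0, tau_d = tau0, triplet_f = 0.1,
                   tau_f = min(lag) * 5, anomaly = 1),
      lower = c(1e-9, min(lag) / 10, 0, min(lag) / 100, 0.1),
      upper = c(Inf, max(lag) * 10, 0.999, max(lag), 2),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- as.list(coef(fit))
  out <- list(nmol = cf$nmol, tau_d = cf$tau_d,
              triplet_f = if (is.null(cf$triplet_f)) 0 else cf$triplet_f,
              tau_f = if (is.null(cf$tau_f)) NA_real_ else cf$tau_f,
              anomaly = if (is.null(cf$anomaly)) 1 else cf$anomaly,
              structure_s = structure_s,
              g0 = 1 + 1 / cf$nmol,
              residual = unname(residuals(fit)))
  class(out) <- "FcsFit"
  out
}

#' Number density from the zero-lag amplitude
#'
#' N = 1 / (G0 - 1): the relative fluctuation amplitude is inverse to the
#' mean occupancy of the focus.
#' @param g0 zero-lag autocorrelation, > 1.
#' @return mean molecules in the focus.
#' @export
number_density_from_g0 <- function(g0) {
  if (any(g0 <= 1)) stop("g0 must exceed 1")
  1 / (g0 - 1)
}

#' Molar concentration from occupancy and focal volume
#'
#' C = N / (N_Avogadro V).
#' @param nmol mean molecules in the focus.
#' @param v_eff focal volume (fL).
#' @return concentration in mol/L.
#' @export
concentration_from_counts <- function(nmol, v_eff) {
  stopifnot(nmol > 0, v_eff > 0)
  nmol / (6.02214076e23 * v_eff * 1e-15)
}

#' Diffusion coefficient from the FCS diffusion time
#'
#' D = wxy^2 / (4 tau_d).
#' @param omega_xy lateral radius (micrometers).
#' @param tau_d diffusion time (s).
#' @return D in um^2/s.
#' @export
fcs_diffusion_coeff <- function(omega_xy, tau_d) {
  stopifnot(omega_xy > 0, tau_d > 0)
  omega_xy^2 / (4 * tau_d)
}
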