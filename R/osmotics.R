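# Osmotic volume-crowding modeling: Boyle-van't Hoff normalization and
# constrained line fit, the concentration-dilution law and deviations
# from it, and the regulatory volume increase (RVI) index.

#' Construct an osmotic series
#' @param osmolarity_excess excess osmolarity per condition (mM; 0 =
#'   isotonic, which must be present).
#' @param volume cell volumes (um^3).
#' @param modal_r modal anisotropy per condition.
#' @param iso_osmolarity total isotonic osmolarity (mOsm; default 300).
#' @return An `OsmoticSeries` data.frame with the isotonic total stored as
#'   an attribute.
#' @export
osmotic_series <- function(osmolarity_excess, volume, modal_r = NA_real_,
                           iso_osmolarity = 300) {
  stopifnot(length(osmolarity_excess) == length(volume))
  if (!any(osmolarity_excess == 0)) stop("isotonic entry (excess 0) required")
  structure(data.frame(osmolarity_excess = osmolarity_excess,
                       volume = volume, modal_r = modal_r),
            iso_osmolarity = iso_osmolarity,
            class = c("OsmoticSeries", "data.frame"))
}

#' Normalize an osmotic series to Boyle-van't Hoff coordinates
#'
#' x = Pi_iso / Pi (reciprocal relative osmotic pressure, proxied by
#' total osmolarity) and y = V / V_iso, plus the crowding track
#' y_r = r_iso / r (reciprocal relative crowding), so the isotonic
#' condition maps to (1, 1) on both tracks.
#'
#' @param series an `OsmoticSeries`.
#' @return data.frame with `x`, `y_volume`, `y_crowding`.
#' @export
normalize_bvh <- function(series) {
  iso_osm <- attr(series, "iso_osmolarity")
  if (is.null(iso_osm)) iso_osm <- 300
  i0 <- which(series$osmolarity_excess == 0)
  if (!length(i0)) stop("isotonic reference missing")
  i0 <- i0[1]
  total <- iso_osm + series$osmolarity_excess
  if (any(total <= 0)) stop("nonpositive total osmolarity")
  data.frame(x = iso_osm / total,
             y_volume = series$volume / series$volume[i0],
             y_crowding = series$modal_r[i0] / series$modal_r)
}

#' Fit the Boyle-van't Hoff line forced through (1, 1)
#'
#' One-parameter least squares of y = 1 + b (x - 1). The x = 0 intercept
#' (1 - b) is the osmotically inactive fraction on the volume track, or
#' the limiting reciprocal crowding on the crowding track.
#'
#' @param x,y normalized coordinates from [normalize_bvh()].
#' @param v_iso,r_iso optional isotonic volume (um^3) / anisotropy used to
#'   convert the intercept to `v_inactive` / `r_limit`.
#' @return A `BvhFit`: list with `slope`, `intercept`
#'   (= `v_inactive_frac`), `v_inactive`, `r_limit`, `rms`.
#' @export
fit_bvh <- function(x, y, v_iso = NA_real_, r_iso = NA_real_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  dx <- x - 1
  if (sum(abs(dx) > 1e-12) < 1)
    stop("degenerate abscissa: need at least one non-isotonic point")
  b <- sum(dx * (y - 1)) / sum(dx^2)
  yhat <- 1 + b * dx
  icpt <- 1 - b
  structure(list(slope = b, intercept = icpt, v_inactive_frac = icpt,
                 v_inactive = icpt * v_iso,
                 r_limit = if (is.finite(r_iso)) r_iso / icpt else NA_real_,
                 rms = sqrt(mean((y - yhat)^2))),
            class = "BvhFit")
}

#' Zero-crowder anisotropy from the concentration-dilution law
#'
#' If (r - alpha) V is conserved between two states,
#' alpha = (r2 V2 - r1 V1) / (V2 - V1).
#'
#' @param r1,v1,r2,v2 anisotropy and volume at two conditions (v1 != v2).
#' @return alpha_r (anisotropy at zero crowder).
#' @export
dilution_alpha <- function(r1, v1, r2, v2) {
  if (v1 == v2) stop("undefined for equal volumes")
  (r2 * v2 - r1 * v1) / (v2 - v1)
}

#' Construct a dilution model
#' @param alpha_r anisotropy at zero crowder.
#' @param r_iso,v_iso isotonic anisotropy and volume.
#' @return A `DilutionModel`.
#' @export
dilution_model <- function(alpha_r, r_iso, v_iso) {
  if (alpha_r >= r_iso) stop("alpha_r must be below the isotonic anisotropy")
  structure(list(alpha_r = alpha_r, r_iso = r_iso, v_iso = v_iso),
            class = "DilutionModel")
}

#' Expected anisotropy under pure concentration-dilution
#'
#' r(V) = (r_iso - alpha_r) (V_iso / V) + alpha_r: halving the volume
#' doubles the crowder term, and r -> alpha_r at infinite dilution.
#'
#' @param model a `DilutionModel`.
#' @param v volume(s) (um^3), > 0.
#' @return expected anisotropy.
#' @export
expected_dilution_curve <- function(model, v) {
  stopifnot(all(v > 0))
  (model$r_iso - model$alpha_r) * (model$v_iso / v) + model$alpha_r
}

#' Deviation of measured anisotropy from the dilution expectation
#'
#' Signed per-condition difference measured r minus expected r(V);
#' positive deviations mean more crowding than volume change alone
#' explains (e.g. excluded-volume effects).
#'
#' @param series an `OsmoticSeries`.
#' @param model a `DilutionModel`.
#' @return list with `per_point` data.frame (volume, modal_r, expected_r,
#'   deviation) and `summary` (mean, max absolute).
#' @export
dilution_deviation <- function(series, model) {
  expd <- expected_dilution_curve(model, series$volume)
  dev <- series$modal_r - expd
  list(per_point = data.frame(volume = series$volume, modal_r = series$modal_r,
                              expected_r = expd, deviation = dev),
       summary = c(mean = mean(dev), max_abs = max(abs(dev))))
}

#' Regulatory volume increase index
#'
#' Percentage volume change between the final time point and the
#' post-shock nadir read at `t_shrink`:
#' 100 (V(t_final) - V(t_shrink)) / V(t_shrink).
#'
#' @param t time points (s or min, consistently).
#' @param volume matching volumes (um^3).
#' @param t_shrink nadir time (default 10 min post-shock).
#' @param t_final final time (default: last point).
#' @return RVI index (percent).
#' @export
rvi_index <- function(t, volume, t_shrink = 10, t_final = max(t)) {
  i1 <- match(t_shrink, t); i2 <- match(t_final, t)
  if (is.na(i1) || is.na(i2))
    stop("required time point missing from the series")
  100 * (volume[i2] - volume[i1]) / volume[i1]
}
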