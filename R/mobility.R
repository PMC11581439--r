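# Translational mobility: FRAP recovery fits (uniform-disk model) and
# single-particle mean squared displacement analysis.

#' Uniform-disk FRAP recovery function
#'
#' f(t) = exp(-2 tau_d / t) [I0(2 tau_d / t) + I1(2 tau_d / t)] for a
#' circular bleach spot of uniform profile; f(0) = 0, f -> 1 as t -> Inf.
#' Computed with exponentially scaled Bessel functions so large arguments
#' do not overflow.
#'
#' @param t time since bleach (s), >= 0.
#' @param tau_d characteristic diffusion time (s).
#' @return recovery fraction in [0, 1].
#' @export
frap_disk_recovery <- function(t, tau_d) {
  out <- numeric(length(t))
  pos <- t > 0
  x <- 2 * tau_d / t[pos]
  out[pos] <- besselI(x, 0, expon.scaled = TRUE) +
    besselI(x, 1, expon.scaled = TRUE)
  out
}

#' Fit a FRAP recovery trace
#'
#' F(t) = F0 + (Finf - F0) f(t; tau_d) with the uniform-disk recovery
#' function; D = w^2 / (4 tau_d) for spot radius w and
#' mobile_fraction = (Finf - F0) / (1 - F0), with intensities normalized
#' to a pre-bleach mean of 1.
#'
#' @param trace data.frame with `t` (s, 0 at bleach) and `intensity`
#'   (normalized) columns, or a `RecoveryTrace`.
#' @param spot_radius bleach spot radius w (micrometers).
#' @return A `FrapFit`: list with `dcoeff` (um^2/s), `mobile_fraction`,
#'   `f0`, `f_inf`, `tau_d`, `residual`, `valid` (FALSE when Finf < F0).
#' @export
fit_frap <- function(trace, spot_radius = 1) {
  t <- trace$t; y <- trace$intensity
  stopifnot(length(t) >= 5, all(diff(t) > 0))
  f0_0 <- y[which.min(t)]
  finf_0 <- mean(y[t >= stats::quantile(t, 0.8)])
  if (finf_0 - f0_0 < 1e-6 || stats::sd(y) < 1e-9) {
    # flat post-bleach trace: nothing recovers
    return(structure(list(dcoeff = NA_real_, mobile_fraction = 0,
                          f0 = f0_0, f_inf = f0_0, tau_d = NA_real_,
                          residual = y - mean(y), valid = TRUE),
                     class = "FrapFit"))
  }
  half <- f0_0 + (finf_0 - f0_0) / 2
  tau0 <- t[t > 0][which.min(abs(y[t > 0] - half))]
  fit <- minpack.lm::nlsLM(
    y ~ f0 + (finf - f0) * frap_disk_recovery(t, tau_d),
    start = list(f0 = f0_0, finf = finf_0, tau_d = max(tau0, min(t[t > 0]))),
    lower = c(-Inf, -Inf, min(t[t > 0]) / 100),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  structure(list(dcoeff = spot_radius^2 / (4 * cf[["tau_d"]]),
                 mobile_fraction = (cf[["finf"]] - cf[["f0"]]) / (1 - cf[["f0"]]),
                 f0 = cf[["f0"]], f_inf = cf[["finf"]], tau_d = cf[["tau_d"]],
                 residual = unname(residuals(fit)),
                 valid = cf[["finf"]] >= cf[["f0"]]),
            class = "FrapFit")
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' MSD(k dt) is averaged over all ordered pairs k frames apart, for lags
#' up to `max_lag_fraction` of the track length.
#'
#' @param traj data.frame with `t` (uniformly spaced, s), `x`, `y`
#'   (micrometers).
#' @param max_lag_fraction largest lag as a fraction of track length.
#' @return An `MsdCurve` data.frame: `lag` (s), `msd` (um^2), `n_pairs`.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  n <- nrow(traj)
  if (n < 2) stop("trajectory needs at least 2 points")
  dt <- diff(traj$t)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("frame interval must be uniform")
  kmax <- max(1L, floor(max_lag_fraction * (n - 1)))
  msd <- numeric(kmax); np <- integer(kmax)
  for (k in seq_len(kmax)) {
    dx <- traj$x[(k + 1):n] - traj$x[1:(n - k)]
    dy <- traj$y[(k + 1):n] - traj$y[1:(n - k)]
    msd[k] <- mean(dx^2 + dy^2)
    np[k] <- n - k
  }
  structure(data.frame(lag = dt[1] * seq_len(kmax), msd = msd, n_pairs = np),
            class = c("MsdCurve", "data.frame"))
}

#' Ensemble MSD: time-average per track, then mean across tracks
#'
#' @param trajs data.frame with `particle_id`, `t`, `x`, `y`, or a list of
#'   single-track data.frames.
#' @inheritParams compute_msd
#' @return An `MsdCurve` averaged across tracks (equal weight per track);
#'   `n_pairs` counts contributing tracks per lag.
#' @export
ensemble_msd <- function(trajs, max_lag_fraction = 0.25) {
  if (is.data.frame(trajs)) trajs <- split(trajs, trajs$particle_id)
  curves <- lapply(trajs, compute_msd, max_lag_fraction = max_lag_fraction)
  lags <- sort(unique(unlist(lapply(curves, `[[`, "lag"))))
  acc <- sapply(lags, function(l) {
    v <- unlist(lapply(curves, function(cv) cv$msd[match(l, cv$lag)]))
    v <- v[!is.na(v)]
    c(mean(v), length(v))
  })
  structure(data.frame(lag = lags, msd = acc[1, ], n_pairs = as.integer(acc[2, ])),
            class = c("MsdCurve", "data.frame"))
}

#' Log-log slope of an MSD curve
#'
#' Least-squares slope of log(MSD) against log(lag) inside `lag_window`;
#' 1 = free diffusion, < 1 subdiffusive/confined, 2 ballistic.
#'
#' @param curve an `MsdCurve`.
#' @param lag_window inclusive lag window (s); default 0.1-1 s.
#' @return slope (dimensionless).
#' @export
msd_loglog_slope <- function(curve, lag_window = c(0.1, 1)) {
  sel <- curve$lag >= lag_window[1] & curve$lag <= lag_window[2]
  bad <- sel & curve$msd <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive MSD value(s) excluded from the log-log fit")
    sel <- sel & curve$msd > 0
  }
  if (sum(sel) < 3) stop("need at least 3 positive lags in the window")
  unname(coef(lm(log(curve$msd[sel]) ~ log(curve$lag[sel])))[2])
}

#' Apparent diffusion coefficient at a given timescale
#'
#' D_app = MSD(lag) / (4 lag), with MSD linearly interpolated between
#' measured lags.
#'
#' @param curve an `MsdCurve`.
#' @param lag timescale (s) within the curve range.
#' @return apparent D (um^2/s).
#' @export
diffusion_at_lag <- function(curve, lag) {
  if (lag < min(curve$lag) || lag > max(curve$lag))
    stop("lag outside the measured range")
  m <- approx(curve$lag, curve$msd, xout = lag)$y
  m / (4 * lag)
}
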