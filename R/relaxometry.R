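#' Single-echo delta-R2* conversion
#'
#' Converts a gradient-echo BOLD series into voxelwise changes of the
#' effective transverse relaxation rate,
#' \deqn{\Delta R_2^*(t) = -\frac{1}{TE}\,\ln\frac{S(t)}{S_0},}
#' where \eqn{S_0} is the temporal mean of the voxel's series. The sign is
#' kept as computed: a signal increase (oxygenation increase, less
#' deoxyhemoglobin) maps to a delta-R2* decrease. Downstream estimators use
#' magnitudes at the fundamental frequency and are insensitive to this sign.
#'
#' @param series An [echo_series()]. Within `mask` (if given) all samples
#'   must be strictly positive.
#' @param mask Optional 3D logical array restricting the conversion; voxels
#'   outside the mask are returned as zero curves.
#' @return A [conc_series()] on the same grid and timing, in 1/s.
#' @seealso [dual_echo_delta_r2star()]
#' @export
single_echo_delta_r2star <- function(series, mask = NULL) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$data)
  m <- as_voxel_matrix(series$data)
  if (is.null(mask)) {
    keep <- rep(TRUE, nrow(m))
  } else {
    if (!identical(dim(mask), d[1:3]))
      stop("mask grid does not match the echo series")
    keep <- as.vector(mask) & TRUE
  }
  if (any(m[keep, ] <= 0)) {
    bad <- which(rowSums(m <= 0) > 0 & keep)[1]
    idx <- arrayInd(bad, d[1:3])
    stop(sprintf("non-positive signal inside the mask at voxel (%d, %d, %d); cannot take log",
                 idx[1], idx[2], idx[3]))
  }
  out <- matrix(0, nrow(m), ncol(m))
  s0 <- rowMeans(m[keep, , drop = FALSE])
  out[keep, ] <- -log(m[keep, , drop = FALSE] / s0) / series$te
  dim(out) <- d
  conc_series(out, tr = series$tr, t0 = series$t0)
}

#' Dual-echo delta-R2* conversion
#'
#' Combines two simultaneously acquired echoes into a delta-R2* estimate
#' that cancels echo-time-independent signal fluctuations:
#' \deqn{\Delta R_2^*(t) = \frac{1}{TE_2 - TE_1}
#'   \left[\ln\frac{S_{TE_1}(t)}{S_{0,TE_1}} -
#'         \ln\frac{S_{TE_2}(t)}{S_{0,TE_2}}\right],}
#' with per-echo baselines \eqn{S_0} taken as temporal means. Signals
#' generated from a common delta-R2*(t) by mono-exponential decay at the two
#' echo times are inverted exactly.
#'
#' @param series1,series2 [echo_series()] objects sharing grid, timing and
#'   time-point count, with `series2$te > series1$te`.
#' @inheritParams single_echo_delta_r2star
#' @return A [conc_series()] in 1/s.
#' @export
dual_echo_delta_r2star <- function(series1, series2, mask = NULL) {
  stopifnot(inherits(series1, "echo_series"), inherits(series2, "echo_series"))
  if (!identical(dim(series1$data), dim(series2$data)))
    stop("echo series grids/time-point counts do not match")
  if (abs(series1$tr - series2$tr) > 1e-9 || abs(series1$t0 - series2$t0) > 1e-9)
    stop("echo series timing does not match")
  if (series2$te <= series1$te)
    stop("te2 must be greater than te1")
  d <- dim(series1$data)
  m1 <- as_voxel_matrix(series1$data)
  m2 <- as_voxel_matrix(series2$data)
  keep <- if (is.null(mask)) rep(TRUE, nrow(m1)) else as.vector(mask) & TRUE
  if (!is.null(mask) && !identical(dim(mask), d[1:3]))
    stop("mask grid does not match the echo series")
  if (any(m1[keep, ] <= 0) || any(m2[keep, ] <= 0))
    stop("non-positive signal inside the mask; cannot take log")
  out <- matrix(0, nrow(m1), ncol(m1))
  l1 <- log(m1[keep, , drop = FALSE] / rowMeans(m1[keep, , drop = FALSE]))
  l2 <- log(m2[keep, , drop = FALSE] / rowMeans(m2[keep, , drop = FALSE]))
  out[keep, ] <- (l1 - l2) / (series2$te - series1$te)
  dim(out) <- d
  conc_series(out, tr = series1$tr, t0 = series1$t0)
}

#' Least-squares sinusoid fit
#'
#' Fits `offset + slope * t + b sin(2 pi f_c t) + c cos(2 pi f_c t)` to a
#' single time series by ordinary least squares. The linear term absorbs
#' scanner drift; for series spanning an integer number of stimulus cycles
#' the joint fit leaves the fundamental unbiased. The fitted sinusoid is
#' reported as `amplitude * cos(2 pi f_c t + phase)` with
#' `amplitude = sqrt(b^2 + c^2)` and `phase = atan2(-b, c)` in
#' \eqn{[-\pi, \pi)}; a pure delayed response has phase decreasing with
#' delay.
#'
#' @param signal Numeric vector, the time series.
#' @param tr Sampling interval in seconds.
#' @param f_c Fundamental frequency in Hz; must be positive, below Nyquist,
#'   and the series must span at least 2 cycles.
#' @param t0 Time of the first sample (seconds).
#' @return A list with `amplitude_pp` (peak-to-peak, signal units),
#'   `amplitude_pct` (peak-to-peak as percent of the fitted offset, `NA` if
#'   the offset is not positive), `phase` (radians), `offset`, `slope`, and
#'   `residual_sd` (sd of residuals after removing offset, trend and
#'   fundamental).
#' @export
fit_sinusoid <- function(signal, tr, f_c, t0 = 0) {
  check_fc(f_c, tr)
  n <- length(signal)
  if (n * tr < 2 / f_c)
    stop("series must span at least two cycles of the fundamental")
  t <- t0 + (seq_len(n) - 1) * tr
  X <- cbind(1, t - mean(t), sin(2 * pi * f_c * t), cos(2 * pi * f_c * t))
  cf <- qr.coef(qr(X), signal)
  res <- signal - X %*% cf
  amp <- sqrt(cf[3]^2 + cf[4]^2)
  list(amplitude_pp = 2 * amp,
       amplitude_pct = if (cf[1] > 0) 200 * amp / cf[1] else NA_real_,
       phase = wrap_pi(atan2(-cf[3], cf[4])),
       offset = unname(cf[1]),
       slope = unname(cf[2]),
       residual_sd = stats::sd(res))
}

#' Temporal signal-to-noise ratio
#'
#' Ratio of the fitted peak-to-peak amplitude of the fundamental sinusoid to
#' the standard deviation of the residual fluctuations after removing
#' offset, linear trend and the fundamental. Invariant to multiplying the
#' signal by a positive constant. A residual variance of (numerically) zero
#' returns `Inf`.
#'
#' @inheritParams fit_sinusoid
#' @return Non-negative scalar (dimensionless), possibly `Inf`.
#' @export
temporal_snr <- function(signal, tr, f_c, t0 = 0) {
  fit <- fit_sinusoid(signal, tr, f_c, t0 = t0)
  if (fit$residual_sd <= .Machine$double.eps^0.5 * max(fit$amplitude_pp, 1e-300))
    return(Inf)
  fit$amplitude_pp / fit$residual_sd
}

# Vectorized sinusoid fit over a voxels-by-time matrix; returns per-voxel
# columns of the regression plus derived quantities. Workhorse behind
# quality_maps() and demodulate_fundamental(). With detrend = FALSE the fit
# reduces to the plain projection onto {1, sin, cos}, which is exactly
# orthogonal to other integer-cycle harmonics.
fit_sinusoid_matrix <- function(m, tr, f_c, t0 = 0, detrend = TRUE) {
  n <- ncol(m)
  t <- t0 + (seq_len(n) - 1) * tr
  X <- cbind(1, t - mean(t), sin(2 * pi * f_c * t), cos(2 * pi * f_c * t))
  if (!detrend) X <- X[, -2, drop = FALSE]
  qx <- qr(X)
  cf <- qr.coef(qx, t(m))            # 3-4 x V
  res <- t(m) - X %*% cf             # T x V
  if (!detrend) cf <- rbind(cf[1, , drop = FALSE], 0, cf[-1, , drop = FALSE])
  rsd <- sqrt(colSums(res^2) / (n - 1))
  amp <- sqrt(cf[3, ]^2 + cf[4, ]^2)
  list(offset = cf[1, ], slope = cf[2, ], b = cf[3, ], c = cf[4, ],
       amplitude = amp, phase = wrap_pi(atan2(-cf[3, ], cf[4, ])),
       residual_sd = rsd)
}

#' Per-voxel sinusoid quality maps
#'
#' Fits the fundamental sinusoid to every voxel of a BOLD echo series
#' (expressed as percent signal change) and returns amplitude, phase and
#' temporal-SNR maps, the raw material for pial-vein suppression and delay
#' mapping.
#'
#' @param series An [echo_series()].
#' @param f_c Fundamental frequency (Hz).
#' @param mask Optional 3D logical array; voxels outside are `NA`.
#' @param crop If `TRUE` (default) the series is first cropped to the
#'   largest integer number of stimulus cycles.
#' @return A list of 3D maps: `amplitude` (peak-to-peak percent of
#'   baseline), `phase` (radians, in \eqn{[-\pi,\pi)}), `tsnr`
#'   (dimensionless).
#' @export
quality_maps <- function(series, f_c, mask = NULL, crop = TRUE) {
  stopifnot(inherits(series, "echo_series"))
  check_fc(f_c, series$tr)
  d <- dim(series$data)
  m <- as_voxel_matrix(series$data)
  if (crop) {
    nk <- n_integer_cycles(ncol(m), series$tr, f_c)
    m <- m[, seq_len(nk), drop = FALSE]
  }
  s0 <- rowMeans(m)
  ok <- s0 > 0
  pct <- matrix(NA_real_, nrow(m), ncol(m))
  pct[ok, ] <- 100 * (m[ok, , drop = FALSE] / s0[ok] - 1)
  keep <- if (is.null(mask)) ok else (as.vector(mask) & ok)
  fit <- fit_sinusoid_matrix(pct[keep, , drop = FALSE], series$tr, f_c,
                             t0 = series$t0)
  amp <- phs <- tsnr <- rep(NA_real_, nrow(m))
  amp[keep] <- 2 * fit$amplitude
  phs[keep] <- fit$phase
  tsnr[keep] <- ifelse(fit$residual_sd <= .Machine$double.eps^0.5,
                       Inf, 2 * fit$amplitude / fit$residual_sd)
  list(amplitude = as_map(amp, d[1:3]),
       phase = as_map(phs, d[1:3]),
       tsnr = as_map(tsnr, d[1:3]))
}

#' Pial-vein suppression mask
#'
#' Flags voxels whose fitted sinusoid amplitude strictly exceeds the given
#' percentile of in-brain amplitudes. Large draining veins carry blood-pool
#' signal an order of magnitude above tissue and would otherwise dominate
#' tissue averages; the returned mask marks voxels to *exclude* from tissue
#' statistics. The percentile is computed by linear interpolation between
#' order statistics (R quantile type 7).
#'
#' @param amplitude 3D amplitude map (e.g. from [quality_maps()]).
#' @param brain_mask 3D logical array of brain voxels.
#' @param percentile Fraction in (0, 1); default 0.98.
#' @return 3D logical array: `TRUE` where the voxel should be excluded.
#' @export
suppress_high_amplitude_voxels <- function(amplitude, brain_mask,
                                           percentile = 0.98) {
  if (percentile <= 0 || percentile >= 1)
    stop("'percentile' must lie strictly between 0 and 1")
  if (!any(brain_mask))
    stop("empty brain mask")
  vals <- amplitude[brain_mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals))
    stop("no finite amplitudes inside the brain mask")
  thr <- stats::quantile(vals, percentile, names = FALSE, type = 7)
  out <- array(FALSE, dim(amplitude))
  out[brain_mask] <- is.finite(amplitude[brain_mask]) &
    amplitude[brain_mask] > thr
  out
}
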