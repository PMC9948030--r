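#' Demodulate the fundamental frequency component
#'
#' Computes, per voxel, the complex least-squares projection of the
#' concentration curve onto the fundamental sinusoid at `f_c`, jointly with
#' an offset and a linear drift term. Over an integer number of cycles this
#' equals the corresponding DFT bin. The complex coefficient `Z` is
#' normalized so that a voxel series `A * sin(2 pi f_c t)` yields
#' `Mod(Z) = A`; the series is represented as `Re(Z * exp(1i * 2 * pi *
#' f_c * t))`, so a delay of `dt` seconds multiplies `Z` by
#' `exp(-1i * 2 * pi * f_c * dt)` (phase decreases with delay).
#'
#' @param conc A [conc_series()].
#' @param f_c Fundamental frequency in Hz.
#' @param mask Optional 3D logical array; voxels outside are `NA`.
#' @param crop Crop to the largest integer number of cycles first (default
#'   `TRUE`).
#' @param detrend Jointly estimate a linear drift term (default `TRUE`).
#'   Detrending immunizes the fundamental against scanner drift, at the
#'   cost of a small (few percent) leakage from harmonics, which are not
#'   exactly orthogonal to the trend; with `detrend = FALSE` the projection
#'   is exactly orthogonal to every other integer-cycle frequency.
#' @return A list of class `spectral_summary` with `f_c`, `coeff` (3D
#'   complex), `magnitude` (3D, units of delta-R2*, 1/s) and `phase` (3D,
#'   radians in \eqn{[-\pi, \pi)}).
#' @export
demodulate_fundamental <- function(conc, f_c, mask = NULL, crop = TRUE,
                                   detrend = TRUE) {
  stopifnot(inherits(conc, "conc_series"))
  check_fc(f_c, conc$tr)
  d <- dim(conc$data)
  m <- as_voxel_matrix(conc$data)
  if (crop) {
    nk <- n_integer_cycles(ncol(m), conc$tr, f_c)
    m <- m[, seq_len(nk), drop = FALSE]
  }
  if (ncol(m) * conc$tr < 1 / f_c - 1e-9)
    stop("fundamental frequency not resolvable by the series length")
  keep <- if (is.null(mask)) rep(TRUE, nrow(m)) else as.vector(mask) & TRUE
  fit <- fit_sinusoid_matrix(m[keep, , drop = FALSE], conc$tr, f_c,
                             t0 = conc$t0, detrend = detrend)
  z <- rep(NA_complex_, nrow(m))
  z[keep] <- complex(real = fit$c, imaginary = -fit$b)
  structure(list(f_c = f_c,
                 coeff = as_map(z, d[1:3]),
                 magnitude = as_map(Mod(z), d[1:3]),
                 phase = as_map(wrap_pi(Arg(z)), d[1:3])),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> f_c = %.4g Hz, grid %s, median magnitude %.4g 1/s\n",
              x$f_c, paste(dim(x$coeff), collapse = " x "),
              stats::median(x$magnitude, na.rm = TRUE)))
  invisible(x)
}

# Demodulate a single curve; returns complex coefficient with the same
# convention as demodulate_fundamental().
demodulate_curve <- function(x, tr, f_c, t0 = 0, crop = TRUE,
                             detrend = TRUE) {
  if (crop) x <- x[seq_len(n_integer_cycles(length(x), tr, f_c))]
  fit <- fit_sinusoid_matrix(matrix(x, nrow = 1), tr, f_c, t0 = t0,
                             detrend = detrend)
  complex(real = fit$c, imaginary = -fit$b)
}

#' Map voxel response delays at the fundamental frequency
#'
#' Converts per-voxel fundamental phases into response delays in seconds.
#' Later responses have larger delays. If `reference_phase` is supplied
#' (e.g. the known stimulus phase of a phantom) delays are the raw lag
#' relative to it, wrapped into `[0, 1/f_c)`. Otherwise the reference is the
#' phase of the brain-mask mean response: voxel lags are first wrapped into
#' the centred interval `(-period/2, period/2]` around that reference and
#' then shifted so the earliest in-mask voxel has delay 0, keeping the whole
#' (physiologically narrow) delay distribution on one branch with the
#' venous tail near the top. Voxels with zero fundamental magnitude are
#' returned as `NA`.
#'
#' @param spec A `spectral_summary` from [demodulate_fundamental()].
#' @param brain_mask 3D logical array (required when `reference_phase` is
#'   `NULL`).
#' @param reference_phase Optional scalar reference phase in radians.
#' @return 3D map of delays in seconds; attribute `reference_phase` records
#'   the phase that was used.
#' @export
phase_delay_map <- function(spec, brain_mask = NULL, reference_phase = NULL) {
  stopifnot(inherits(spec, "spectral_summary"))
  period <- 1 / spec$f_c
  omega <- 2 * pi * spec$f_c
  defined <- is.finite(spec$magnitude) & spec$magnitude > 0
  rezero <- is.null(reference_phase)
  if (rezero) {
    if (is.null(brain_mask))
      stop("'brain_mask' is required when no reference phase is given")
    zm <- spec$coeff[brain_mask & defined]
    if (!length(zm))
      stop("no defined phases inside the brain mask")
    reference_phase <- Arg(mean(zm))
  }
  lag <- (reference_phase - spec$phase) / omega
  delay <- array(NA_real_, dim(spec$phase))
  if (rezero) {
    lag <- wrap_centered(lag, period)
    base <- min(lag[brain_mask & defined])
    delay[defined] <- lag[defined] - base
  } else {
    delay[defined] <- wrap_period(lag[defined], period)
  }
  attr(delay, "reference_phase") <- reference_phase
  delay
}

#' Venous reference delay and phase
#'
#' The venous reference is the stated percentile (default the 98th) of the
#' in-brain voxel delay histogram: draining veins respond latest, so the
#' upper tail of the delay distribution localizes the venous phase without
#' manual vessel selection. Percentiles use linear interpolation between
#' order statistics (R quantile type 7).
#'
#' @param delay_map 3D delay map from [phase_delay_map()] (seconds).
#' @param brain_mask 3D logical array.
#' @param f_c Fundamental frequency (Hz), used to express the result in
#'   radians.
#' @param percentile Fraction in (0, 1), default 0.98.
#' @param min_n Minimum number of defined delays required (default 50).
#' @return List with `delay_s` (seconds) and `phase` (radians relative to
#'   the delay map's reference phase, in \eqn{[-\pi,\pi)}).
#' @export
venous_reference_phase <- function(delay_map, brain_mask, f_c,
                                   percentile = 0.98, min_n = 50) {
  vals <- delay_map[brain_mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals))
    stop("empty delay distribution")
  if (length(vals) < min_n)
    stop(sprintf("only %d defined delays (need >= %d)", length(vals), min_n))
  if (percentile <= 0 || percentile >= 1)
    stop("'percentile' must lie strictly between 0 and 1")
  dly <- stats::quantile(vals, percentile, names = FALSE, type = 7)
  ref <- attr(delay_map, "reference_phase")
  phs <- if (is.null(ref)) NA_real_ else wrap_pi(ref - 2 * pi * f_c * dly)
  list(delay_s = dly, phase = phs)
}

#' Automatic venous output function selection
#'
#' Selects the `n_vof` voxels that act as the blood-pool reference: among
#' voxels whose delay exceeds the stated percentile of in-brain delays
#' (veins respond latest), voxels are ranked by the time integral of the
#' rectified, demeaned concentration curve over integer stimulus cycles
#' (veins have near-100% blood volume and hence maximal response), and the
#' top `n_vof` are kept. Ties are broken by integral value then by
#' lexicographic voxel index, making the selection deterministic and
#' invariant to voxel traversal order and positive rescaling.
#'
#' @param conc A [conc_series()].
#' @param delay_map 3D delay map (seconds) from [phase_delay_map()].
#' @param brain_mask 3D logical array.
#' @param f_c Fundamental frequency (Hz).
#' @param n_vof Number of voxels to select (default 20).
#' @param delay_percentile Delay-histogram percentile a candidate must
#'   exceed (default 0.98).
#' @return A list of class `vof`: `voxel_indices` (`n_vof` x 3 matrix of
#'   grid coordinates), `curve` (mean concentration series over the selected
#'   voxels, full input length), `delay_s`, `phase_venous` (from the delay
#'   histogram), `n_vof`, `f_c`.
#' @export
select_vof <- function(conc, delay_map, brain_mask, f_c, n_vof = 20,
                       delay_percentile = 0.98) {
  stopifnot(inherits(conc, "conc_series"))
  d <- dim(conc$data)
  ven <- venous_reference_phase(delay_map, brain_mask, f_c,
                                percentile = delay_percentile,
                                min_n = n_vof)
  thr <- ven$delay_s
  cand <- which(as.vector(brain_mask) & is.finite(as.vector(delay_map)) &
                  as.vector(delay_map) >= thr)
  if (length(cand) < n_vof)
    stop(sprintf(paste("only %d voxels exceed the delay criterion (need %d);",
                       "consider a lower 'delay_percentile'"),
                 length(cand), n_vof))
  m <- as_voxel_matrix(conc$data)
  nk <- n_integer_cycles(ncol(m), conc$tr, f_c)
  mc <- m[cand, seq_len(nk), drop = FALSE]
  score <- rowSums(abs(mc - rowMeans(mc))) * conc$tr
  ord <- order(-score, cand)
  sel <- cand[ord[seq_len(n_vof)]]
  structure(list(voxel_indices = arrayInd(sel, d[1:3]),
                 voxel_linear = sel,
                 curve = colMeans(m[sel, , drop = FALSE]),
                 delay_s = ven$delay_s,
                 phase_venous = ven$phase,
                 n_vof = n_vof,
                 f_c = f_c),
            class = "vof")
}

#' @export
print.vof <- function(x, ...) {
  cat(sprintf("<vof> %d voxels, venous delay %.2f s (phase %.3f rad), f_c %.4g Hz\n",
              x$n_vof, x$delay_s, x$phase_venous, x$f_c))
  invisible(x)
}
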