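#' Fit the frequency-domain perfusion model to a sinusoidal-CO2 BOLD study
#'
#' The central fitting function. Starting from one or two gradient-echo
#' BOLD series acquired during a sinusoidal end-tidal CO2 challenge it
#' runs, in order: cropping to integer stimulus cycles; delta-R2*
#' conversion (single- or dual-echo); per-voxel sinusoid quality maps and
#' pial-vein suppression; demodulation of the fundamental frequency;
#' delay mapping and automatic venous-output-function selection; the
#' frequency-domain tracer-kinetics estimators for TD, CBF, CBV and MTT;
#' and, when a gas trace is supplied, voxelwise CVR regression with a
#' CBF/CVR ratio map. The fit is deterministic: rerunning on the same
#' inputs reproduces every map bit for bit.
#'
#' Vein suppression is applied to tissue statistics (summaries, global
#' coefficients) only, after VOF selection: the VOF deliberately uses the
#' highest-amplitude voxels that the suppression removes from tissue
#' averages.
#'
#' @param echo1 An [echo_series()], the short echo.
#' @param echo2 Optional second [echo_series()] (longer echo); when given,
#'   the dual-echo delta-R2* conversion is used.
#' @param brain_mask 3D logical array of brain voxels.
#' @param etco2 Optional [gas_trace()]; enables the CVR maps.
#' @param labels Optional 3D integer ROI label array (used by `summary()`).
#' @param period Stimulus period in seconds (default 60); the fundamental
#'   frequency is `1 / period`.
#' @param n_vof Number of voxels in the venous output function (default
#'   20).
#' @param suppress_percentile Amplitude percentile above which voxels are
#'   excluded from tissue statistics (default 0.98).
#' @param delay_percentile Delay percentile defining the venous reference
#'   (default 0.98).
#' @param config A [kinetics_config()].
#' @param keep_data Keep the cropped concentration array in the returned
#'   object so `residuals()` can be computed (default `TRUE`).
#' @return An object of class `sinedsc_fit`; see Details. Main components:
#'   `maps` (3D arrays `cbf`, `cbv`, `td`, `mtt`, `cvr`, `cvr_delay`,
#'   `cbf_cvr_ratio`, `amplitude`, `phase`, `tsnr`, `delay`), `vof`,
#'   `venous` (reference delay/phase), `suppressed` (exclusion mask),
#'   `units`, `counts`, `f_c`, `config`.
#' @examples
#' ph <- generate_phantom(phantom_spec(dim = c(18, 18, 4), n_frames = 120,
#'                                     tsnr = Inf))
#' fit <- sinedsc_fit(ph$echoes[[1]], brain_mask = ph$brain_mask,
#'                    etco2 = ph$gas, labels = ph$labels)
#' fit
#' coef(fit)
#' @export
sinedsc_fit <- function(echo1, echo2 = NULL, brain_mask, etco2 = NULL,
                        labels = NULL, period = 60, n_vof = 20,
                        suppress_percentile = 0.98, delay_percentile = 0.98,
                        config = kinetics_config(), keep_data = TRUE) {
  stopifnot(inherits(echo1, "echo_series"), inherits(config, "kinetics_config"))
  d <- dim(echo1$data)
  if (!identical(dim(brain_mask), d[1:3]))
    stop("'brain_mask' grid does not match the echo series")
  f_c <- 1 / period
  check_fc(f_c, echo1$tr)

  # crop to integer stimulus cycles up front; every later stage sees the
  # cropped window, so baselines and spectra are cycle-consistent
  nk <- n_integer_cycles(d[4], echo1$tr, f_c)
  crop_echo <- function(e)
    echo_series(e$data[, , , seq_len(nk), drop = FALSE], te = e$te,
                tr = e$tr, t0 = e$t0)
  e1 <- crop_echo(echo1)
  conc <- if (is.null(echo2)) {
    single_echo_delta_r2star(e1, mask = brain_mask)
  } else {
    dual_echo_delta_r2star(e1, crop_echo(echo2), mask = brain_mask)
  }

  qm <- quality_maps(e1, f_c, mask = brain_mask, crop = FALSE)
  suppressed <- suppress_high_amplitude_voxels(qm$amplitude, brain_mask,
                                               percentile = suppress_percentile)

  spec <- demodulate_fundamental(conc, f_c, mask = brain_mask, crop = FALSE)
  delay <- phase_delay_map(spec, brain_mask = brain_mask)
  vof <- select_vof(conc, delay, brain_mask, f_c, n_vof = n_vof,
                    delay_percentile = delay_percentile)
  mag_vof <- Mod(demodulate_curve(vof$curve, conc$tr, f_c, t0 = conc$t0,
                                  crop = FALSE))

  td <- wrap_period(vof$delay_s - delay, period)
  td[!is.finite(delay)] <- NA_real_
  cbf <- cbf_frequency_domain(spec$magnitude, mag_vof, td, f_c,
                              cfg = config, tr = conc$tr, period = period)
  cbv <- cbv_map(spec$magnitude, mag_vof, cfg = config)
  mtt <- mtt_map(cbv, cbf)

  cvr <- cvr_delay <- ratio <- NULL
  lag_global <- NA_real_
  if (!is.null(etco2)) {
    cv <- cvr_map(e1, etco2, brain_mask, period = period, cbf = cbf)
    cvr <- cv$cvr
    cvr_delay <- cv$cvr_delay
    ratio <- cv$cbf_cvr_ratio
    lag_global <- cv$lag_global
  }

  structure(list(
    maps = list(cbf = strip_attr(cbf), cbv = cbv, td = td, mtt = mtt,
                cvr = cvr, cvr_delay = cvr_delay, cbf_cvr_ratio = ratio,
                amplitude = qm$amplitude, phase = qm$phase, tsnr = qm$tsnr,
                delay = strip_attr(delay)),
    vof = vof,
    venous = list(delay_s = vof$delay_s, phase = vof$phase_venous),
    suppressed = suppressed,
    brain_mask = brain_mask,
    labels = labels,
    spectral = spec,
    conc = if (keep_data) conc else NULL,
    f_c = f_c,
    period = period,
    tr = echo1$tr,
    n_frames_used = nk,
    dual_echo = !is.null(echo2),
    lag_global = lag_global,
    config = config,
    counts = list(n_brain = sum(brain_mask),
                  n_suppressed = sum(suppressed),
                  n_tau_floored = attr(cbf, "n_floored"),
                  n_tau_capped = attr(cbf, "n_capped")),
    units = c(cbf = "mL/100g/min", cbv = "mL/100g", td = "s", mtt = "s",
              cvr = "%/mmHg", cvr_delay = "s", tsnr = "", amplitude = "%pp",
              delay = "s"),
    call = match.call()),
    class = "sinedsc_fit")
}

strip_attr <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# voxels entering tissue statistics: in brain, defined, not vein-suppressed
tissue_idx <- function(object) {
  object$brain_mask & !object$suppressed
}

#' @export
print.sinedsc_fit <- function(x, ...) {
  cat("Sinusoidal-CO2 perfusion fit\n")
  cat(sprintf("  %s-echo delta-R2*, %d frames used (%.0f s), f_c = %.4g Hz\n",
              if (x$dual_echo) "dual" else "single", x$n_frames_used,
              x$n_frames_used * x$tr, x$f_c))
  cat(sprintf("  brain voxels: %d (%d vein-suppressed); VOF: %d voxels, venous delay %.2f s\n",
              x$counts$n_brain, x$counts$n_suppressed, x$vof$n_vof,
              x$venous$delay_s))
  if (x$counts$n_tau_floored + x$counts$n_tau_capped > 0)
    cat(sprintf("  residue time constants clamped: %d floored, %d capped\n",
                x$counts$n_tau_floored, x$counts$n_tau_capped))
  cf <- coef(x)
  cat("  tissue means:\n")
  for (nm in names(cf))
    cat(sprintf("    %-12s %8.3g %s\n", nm, cf[[nm]], x$units[[nm]]))
  invisible(x)
}

#' Global tissue coefficients of a perfusion fit
#'
#' Mean CBF, CBV, TD, MTT (and CVR when fitted) over defined, in-brain,
#' non-vein-suppressed voxels.
#'
#' @param object A `sinedsc_fit`.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.sinedsc_fit <- function(object, ...) {
  idx <- tissue_idx(object)
  pick <- c("cbf", "cbv", "td", "mtt", "cvr")
  out <- vapply(pick, function(nm) {
    m <- object$maps[[nm]]
    if (is.null(m)) return(NA_real_)
    mean(m[idx], na.rm = TRUE)
  }, numeric(1))
  out[!is.na(out)]
}

#' Summarize a perfusion fit over regions of interest
#'
#' Builds per-ROI tables (mean, sd, n) of each perfusion map using the
#' label volume stored in the fit (or one supplied here), with vein
#' suppression applied.
#'
#' @param object A `sinedsc_fit`.
#' @param labels Optional 3D integer label array overriding the stored one.
#' @param roi_names Optional named character vector of label names.
#' @param ... Unused.
#' @return An object of class `summary.sinedsc_fit`: a list of ROI tables,
#'   one per map, plus the global coefficients.
#' @export
summary.sinedsc_fit <- function(object, labels = NULL, roi_names = NULL, ...) {
  labels <- if (!is.null(labels)) labels else object$labels
  tables <- NULL
  if (!is.null(labels)) {
    excl <- object$suppressed | !object$brain_mask
    nm <- c("cbf", "cbv", "td", "mtt", "cvr", "tsnr")
    nm <- nm[!vapply(object$maps[nm], is.null, logical(1))]
    tables <- lapply(object$maps[nm], roi_summary, labels = labels,
                     exclusion_mask = excl, roi_names = roi_names)
  }
  structure(list(tables = tables, coef = coef(object),
                 counts = object$counts, units = object$units,
                 venous = object$venous),
            class = "summary.sinedsc_fit")
}

#' @export
print.summary.sinedsc_fit <- function(x, ...) {
  cat("Perfusion fit summary\n  global tissue means:\n")
  for (nm in names(x$coef))
    cat(sprintf("    %-12s %8.3g %s\n", nm, x$coef[[nm]], x$units[[nm]]))
  if (!is.null(x$tables)) {
    for (nm in names(x$tables)) {
      cat(sprintf("  %s by ROI (%s):\n", nm, x$units[[nm]]))
      print(x$tables[[nm]], row.names = FALSE)
    }
  }
  invisible(x)
}

#' Fitted fundamental concentration curves
#'
#' Reconstructs, per voxel, the fitted model
#' `offset + drift * t + Re(Z exp(i 2 pi f_c t))` of the concentration
#' series over the cropped frames.
#'
#' @param object A `sinedsc_fit` fitted with `keep_data = TRUE`.
#' @param ... Unused.
#' @return 4D array (x, y, z, t) of fitted delta-R2* values.
#' @export
fitted.sinedsc_fit <- function(object, ...) {
  if (is.null(object$conc))
    stop("fit was run with keep_data = FALSE")
  conc <- object$conc
  d <- dim(conc$data)
  m <- as_voxel_matrix(conc$data)
  bm <- as.vector(object$brain_mask)
  ft <- fit_sinusoid_matrix(m[bm, , drop = FALSE], conc$tr, object$f_c,
                            t0 = conc$t0)
  t <- conc$t0 + (seq_len(d[4]) - 1) * conc$tr
  tc <- t - mean(t)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  out[bm, ] <- ft$offset + outer(ft$slope, tc) +
    outer(ft$b, sin(2 * pi * object$f_c * t)) +
    outer(ft$c, cos(2 * pi * object$f_c * t))
  dim(out) <- d
  out
}

#' Residual concentration fluctuations
#'
#' Concentration minus the fitted offset, drift and fundamental sinusoid;
#' the raw material of the temporal-SNR denominator.
#'
#' @inheritParams fitted.sinedsc_fit
#' @return 4D array of residual delta-R2* values.
#' @export
residuals.sinedsc_fit <- function(object, ...) {
  if (is.null(object$conc))
    stop("fit was run with keep_data = FALSE")
  object$conc$data - fitted(object)
}

#' Plot a perfusion map slice
#'
#' @param x A `sinedsc_fit`.
#' @param map Which map to show (default `"cbf"`).
#' @param slice Axial slice index (default: middle slice).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the matrix that was plotted.
#' @export
plot.sinedsc_fit <- function(x, map = "cbf", slice = NULL, ...) {
  m <- x$maps[[map]]
  if (is.null(m))
    stop(sprintf("map '%s' not available in this fit", map))
  if (is.null(slice)) slice <- ceiling(dim(m)[3] / 2)
  sl <- m[, , slice]
  graphics::image(seq_len(nrow(sl)), seq_len(ncol(sl)), sl,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x", ylab = "y",
                  main = sprintf("%s (%s), slice %d", map, x$units[[map]],
                                 slice), ...)
  invisible(sl)
}
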