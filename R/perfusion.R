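#' Tracer-kinetics configuration
#'
#' Constants and switches for the frequency-domain kinetics estimators.
#'
#' @param kappa Hematocrit correction factor. The deoxygenation contrast is
#'   confined to red cells, so the capillary-to-large-vessel hematocrit
#'   ratio (0.69) enters as `kappa = 1/0.69`.
#' @param rho Brain density in g/mL (default 1.05).
#' @param tau_floor Lower bound on the residue time constant in seconds;
#'   `NA` (default) means half the repetition time is used at fit time.
#' @param tau_cap Upper bound on the residue time constant; `NA` means half
#'   the stimulus period.
#' @param apply_kappa_to_cbf Apply the hematocrit factor to CBF as well as
#'   CBV (default `TRUE`). CBF and CBV are both linear in the tissue-to-VOF
#'   concentration ratio; applying the same factor keeps the central volume
#'   theorem MTT = CBV/CBF internally consistent.
#' @param etco2_reference Reference end-tidal CO2 in mmHg (default 40),
#'   the operating point of the flow model [cbf_time_course()].
#' @return A list of class `kinetics_config`.
#' @export
kinetics_config <- function(kappa = 1 / 0.69, rho = 1.05, tau_floor = NA,
                            tau_cap = NA, apply_kappa_to_cbf = TRUE,
                            etco2_reference = 40) {
  if (kappa <= 0 || rho <= 0)
    stop("'kappa' and 'rho' must be strictly positive")
  structure(list(kappa = kappa, rho = rho, tau_floor = tau_floor,
                 tau_cap = tau_cap, apply_kappa_to_cbf = apply_kappa_to_cbf,
                 etco2_reference = etco2_reference),
            class = "kinetics_config")
}

#' Residue function magnitude spectrum
#'
#' The tissue residue function is modeled as a decaying exponential
#' `R(t) = exp(-t / tau)`; its magnitude spectrum is
#' \deqn{|R(f)| = \frac{1}{\sqrt{1/\tau^2 + (2\pi f)^2}},}
#' which equals `tau` at DC, is strictly decreasing in `f`, and approaches
#' `1 / (2 pi f)` at high frequency.
#'
#' @param tau Time constant(s) in seconds, strictly positive.
#' @param f Frequency (Hz), `>= 0`. Vectorized over both arguments.
#' @return Magnitude in seconds.
#' @export
residue_magnitude <- function(tau, f) {
  if (any(tau <= 0, na.rm = TRUE))
    stop("'tau' must be strictly positive")
  1 / sqrt(1 / tau^2 + (2 * pi * f)^2)
}

#' Tissue-to-vein time delay map
#'
#' Converts the tissue and venous fundamental phases to a time delay
#' \deqn{TD = \frac{\phi_{tissue} - \phi_{venous}}{2\pi f_c},}
#' wrapped into `[0, 1/f_c)`. With the demodulation convention used here
#' (phase decreases with delay) a tissue voxel responding `TD` seconds
#' *before* the venous outflow yields a positive delay of `TD` seconds; the
#' drive reaches exchanging vessels before the collected venous pool.
#'
#' @param phase_tissue 3D map (or vector) of tissue phases in radians.
#' @param phase_venous Scalar venous reference phase in radians.
#' @param f_c Fundamental frequency (Hz).
#' @return Map of delays in seconds in `[0, 1/f_c)`; `NA` phases propagate.
#' @export
time_delay_map <- function(phase_tissue, phase_venous, f_c) {
  if (!is.finite(phase_venous))
    stop("'phase_venous' must be a finite scalar")
  period <- 1 / f_c
  td <- wrap_period((phase_tissue - phase_venous) / (2 * pi * f_c), period)
  td[!is.finite(phase_tissue)] <- NA_real_
  td
}

# Clamp residue time constants to [floor, cap]; returns values + counts.
clamp_tau <- function(tau, tau_floor, tau_cap) {
  n_floored <- sum(tau < tau_floor, na.rm = TRUE)
  n_capped <- sum(tau > tau_cap, na.rm = TRUE)
  tau <- pmin(pmax(tau, tau_floor), tau_cap)
  list(tau = tau, n_floored = n_floored, n_capped = n_capped)
}

#' Frequency-domain cerebral blood flow
#'
#' Single-frequency solution of the tracer-kinetics model
#' `C_tissue(f) = C_blood(f) * CBF * R(f)` at the fundamental `f_c`: per
#' voxel,
#' \deqn{CBF_{raw} = \frac{|C_{tissue}(f_c)|}{|C_{VOF}(f_c)|\,|R(f_c;\tau)|},}
#' with the residue time constant approximated by the measured time delay
#' (`tau = TD`, floored/capped per `cfg`). Magnitudes make the estimate
#' independent of the tissue-to-vein delay, accommodating the anti-causal
#' vein-referenced system. The raw flow (1/s) is scaled to mL/100 g/min by
#' `6000 * kappa / rho` (or `6000 / rho` when `apply_kappa_to_cbf` is
#' `FALSE`).
#'
#' @param mag_tissue 3D map (or vector) of tissue fundamental magnitudes
#'   (1/s).
#' @param mag_vof Scalar VOF fundamental magnitude (1/s), strictly positive.
#' @param td_map Time-delay map in seconds (same shape as `mag_tissue`).
#' @param f_c Fundamental frequency (Hz).
#' @param cfg A [kinetics_config()].
#' @param tr Repetition time in seconds (used for the default tau floor).
#' @param period Stimulus period in seconds (used for the default tau cap);
#'   defaults to `1 / f_c`.
#' @return CBF map in mL/100 g/min, with attributes `n_floored` and
#'   `n_capped` counting clamped time constants.
#' @export
cbf_frequency_domain <- function(mag_tissue, mag_vof, td_map, f_c,
                                 cfg = kinetics_config(), tr,
                                 period = 1 / f_c) {
  if (!is.finite(mag_vof) || mag_vof <= 0)
    stop("VOF fundamental magnitude must be strictly positive")
  tau_floor <- if (is.na(cfg$tau_floor)) tr / 2 else cfg$tau_floor
  tau_cap <- if (is.na(cfg$tau_cap)) period / 2 else cfg$tau_cap
  cl <- clamp_tau(td_map, tau_floor, tau_cap)
  raw <- mag_tissue / (mag_vof * residue_magnitude(cl$tau, f_c))
  scale <- 6000 / cfg$rho * if (cfg$apply_kappa_to_cbf) cfg$kappa else 1
  out <- raw * scale
  attr(out, "n_floored") <- cl$n_floored
  attr(out, "n_capped") <- cl$n_capped
  out
}

#' Cerebral blood volume map
#'
#' For a zero-mean periodic tracer signal the area-under-curve ratio of the
#' classic CBV definition is taken per cycle on the rectified curves; for
#' sinusoids this reduces to the ratio of fundamental magnitudes, which is
#' the default estimator:
#' \deqn{CBV = 100\,\frac{\kappa}{\rho}\,
#'   \frac{|C_{tissue}(f_c)|}{|C_{VOF}(f_c)|}\ \mathrm{mL/100\,g}.}
#'
#' @inheritParams cbf_frequency_domain
#' @return CBV map in mL/100 g.
#' @seealso [cbv_map_auc()] for the rectified area-under-curve variant.
#' @export
cbv_map <- function(mag_tissue, mag_vof, cfg = kinetics_config()) {
  if (!is.finite(mag_vof) || mag_vof <= 0)
    stop("VOF fundamental magnitude must be strictly positive")
  100 * cfg$kappa / cfg$rho * mag_tissue / mag_vof
}

#' Cerebral blood volume via rectified area under the curve
#'
#' Literal integral-ratio form of the CBV definition: the time integral of
#' the rectified, demeaned tissue curve over integer stimulus cycles divided
#' by the same integral of the VOF curve. For noiseless sinusoids (mean of
#' `|sin|` is `2/pi` times the amplitude in both numerator and denominator)
#' this agrees with the magnitude-ratio estimator [cbv_map()].
#'
#' @param conc A [conc_series()].
#' @param vof_curve Numeric vector, the VOF concentration curve on the same
#'   time grid.
#' @param f_c Fundamental frequency (Hz).
#' @param cfg A [kinetics_config()].
#' @param mask Optional 3D logical array.
#' @return CBV map in mL/100 g.
#' @export
cbv_map_auc <- function(conc, vof_curve, f_c, cfg = kinetics_config(),
                        mask = NULL) {
  stopifnot(inherits(conc, "conc_series"))
  d <- dim(conc$data)
  m <- as_voxel_matrix(conc$data)
  nk <- n_integer_cycles(ncol(m), conc$tr, f_c)
  m <- m[, seq_len(nk), drop = FALSE]
  v <- vof_curve[seq_len(nk)]
  auc_v <- sum(abs(v - mean(v))) * conc$tr
  if (auc_v <= 0)
    stop("VOF curve has zero rectified area")
  keep <- if (is.null(mask)) rep(TRUE, nrow(m)) else as.vector(mask) & TRUE
  out <- rep(NA_real_, nrow(m))
  mk <- m[keep, , drop = FALSE]
  out[keep] <- rowSums(abs(mk - rowMeans(mk))) * conc$tr / auc_v
  as_map(100 * cfg$kappa / cfg$rho * out, d[1:3])
}

#' Mean transit time map
#'
#' Central volume theorem: `MTT = CBV / CBF`, converted to seconds
#' (`CBV` in mL/100 g, `CBF` in mL/100 g/min, factor 60).
#'
#' @param cbv CBV map (mL/100 g).
#' @param cbf CBF map (mL/100 g/min).
#' @return MTT map in seconds; voxels with `cbf == 0` are `NA`.
#' @export
mtt_map <- function(cbv, cbf) {
  out <- 60 * cbv / cbf
  out[!is.na(cbf) & cbf == 0] <- NA_real_
  out
}

#' Cerebrovascular reactivity map
#'
#' Voxelwise ordinary least squares of percent BOLD signal change on the
#' end-tidal CO2 trace. The trace is resampled (linear interpolation) onto
#' the frame mid-times; a global lag maximizing the cross-correlation with
#' the brain-mean percent signal is searched over `+/- period/2` on a fine
#' grid (`tr/10`), then each voxel is assigned the lag within the same
#' window that maximizes its own correlation, and the regression slope at
#' that lag is reported in %/mmHg.
#'
#' @param series An [echo_series()] (typically the short echo).
#' @param etco2 A [gas_trace()] covering the acquisition window.
#' @param brain_mask 3D logical array.
#' @param period Stimulus period in seconds (bounds the lag search).
#' @param cbf Optional CBF map; when given, a CBF/CVR ratio map is
#'   computed over voxels with positive CVR.
#' @return List with 3D maps `cvr` (%/mmHg), `cvr_delay` (s; per-voxel lag
#'   of the BOLD response behind the gas trace), `cbf_cvr_ratio` (or `NULL`),
#'   and scalars `lag_global` (s) and `boundary_warning`.
#' @export
cvr_map <- function(series, etco2, brain_mask, period = 60, cbf = NULL) {
  stopifnot(inherits(series, "echo_series"))
  if (!all(c("time_s", "etco2_mmHg") %in% names(etco2)))
    stop("'etco2' must have columns time_s and etco2_mmHg")
  if (stats::var(etco2$etco2_mmHg) <= 0)
    stop("EtCO2 trace has zero variance")
  d <- dim(series$data)
  m <- as_voxel_matrix(series$data)
  bm <- as.vector(brain_mask)
  s0 <- rowMeans(m)
  pct <- 100 * (m[bm, , drop = FALSE] / s0[bm] - 1)
  n <- ncol(m)
  tmid <- series$t0 + (seq_len(n) - 1) * series$tr + series$tr / 2
  co2_at <- function(lag) {
    stats::approx(etco2$time_s, etco2$etco2_mmHg, xout = tmid - lag,
                  rule = 2)$y
  }
  lags <- seq(-period / 2, period / 2, by = series$tr / 10)
  gmean <- colMeans(pct)
  cors <- vapply(lags, function(l) {
    g <- co2_at(l)
    if (stats::sd(g) == 0) return(-Inf)
    stats::cor(gmean, g)
  }, numeric(1))
  lag_global <- lags[which.max(cors)]
  boundary <- which.max(cors) %in% c(1L, length(lags))
  if (boundary)
    warning("global EtCO2 lag search hit the boundary of +/- period/2")
  # per-voxel lag: best correlation over the same grid, then slope there
  pc <- pct - rowMeans(pct)
  pnorm2 <- sqrt(rowSums(pc^2))
  best_r <- rep(-Inf, nrow(pc))
  best_lag <- rep(lag_global, nrow(pc))
  for (l in lags) {
    g <- co2_at(l)
    gc <- g - mean(g)
    gn <- sqrt(sum(gc^2))
    if (gn == 0) next
    r <- as.vector(pc %*% gc) / (pnorm2 * gn)
    upd <- is.finite(r) & r > best_r
    best_r[upd] <- r[upd]
    best_lag[upd] <- l
  }
  slope <- rep(NA_real_, nrow(pc))
  for (l in unique(best_lag)) {
    g <- co2_at(l)
    gc <- g - mean(g)
    ss <- sum(gc^2)
    sel <- best_lag == l
    slope[sel] <- as.vector(pc[sel, , drop = FALSE] %*% gc) / ss
  }
  cvr <- dly <- rep(NA_real_, nrow(m))
  cvr[bm] <- slope
  dly[bm] <- best_lag
  cvr <- as_map(cvr, d[1:3])
  dly <- as_map(dly, d[1:3])
  ratio <- NULL
  if (!is.null(cbf)) {
    ratio <- cbf / cvr
    ratio[!is.finite(ratio) | cvr <= 0] <- NA_real_
  }
  list(cvr = cvr, cvr_delay = dly, cbf_cvr_ratio = ratio,
       lag_global = lag_global, boundary_warning = boundary)
}

#' Sinusoidal flow modulation model
#'
#' The linearized flow response to a capnic stimulus about its operating
#' point:
#' \deqn{CBF(t) = CBF_0\,[1 + CVR\,(EtCO_2(t) - EtCO_{2,ref})],}
#' with `CVR` expressed as a fractional change per mmHg when `cvr` is given
#' in %/mmHg (divided by 100 internally). Within the autoregulatory range a
#' typical grey-matter CVR of 0.2%/mmHg and a 5 mmHg peak-to-peak stimulus
#' oscillate flow by about 1% of baseline, which motivates treating the
#' recovered flow as the baseline value.
#'
#' @param cbf0 Baseline CBF at the reference EtCO2 (any unit).
#' @param cvr Cerebrovascular reactivity in %/mmHg.
#' @param etco2 Numeric vector of EtCO2 values (mmHg), or a [gas_trace()].
#' @param etco2_reference Operating point in mmHg (default 40).
#' @return Numeric vector CBF(t) in the units of `cbf0`.
#' @export
cbf_time_course <- function(cbf0, cvr, etco2, etco2_reference = 40) {
  if (inherits(etco2, "gas_trace") || is.data.frame(etco2))
    etco2 <- etco2$etco2_mmHg
  cbf0 * (1 + cvr / 100 * (etco2 - etco2_reference))
}

#' Time-domain SVD deconvolution comparator
#'
#' Block-circulant (delay-insensitive) discretization of the convolution
#' `C_tissue = C_VOF (x) CBF * R`, solved by truncated singular value
#' decomposition: singular values below `threshold * max` are zeroed, and
#' the raw flow is the maximum of the recovered flow-scaled residue
#' `|CBF * R(t)|`. This is the classic time-domain DSC estimator, retained
#' as an independent cross-check of the frequency-domain route. It needs a
#' spectrally rich input: for a purely sinusoidal drive the circulant system
#' is rank-2 and the truncated solution reconstructs only the fundamental
#' component of the residue.
#'
#' @param conc_tissue Numeric matrix (time x voxels) or vector of tissue
#'   concentration curves.
#' @param vof_curve Numeric vector, the VOF curve on the same time grid.
#' @param tr Sampling interval in seconds.
#' @param threshold Singular-value truncation fraction in (0, 1), default
#'   0.1.
#' @return Numeric vector of raw CBF values (1/s), one per tissue curve.
#' @export
svd_deconvolution <- function(conc_tissue, vof_curve, tr, threshold = 0.1) {
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie strictly within (0, 1)")
  if (is.vector(conc_tissue)) conc_tissue <- matrix(conc_tissue, ncol = 1)
  n <- length(vof_curve)
  if (nrow(conc_tissue) != n)
    stop("tissue curves and VOF curve must share the time grid")
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  A <- matrix(vof_curve[idx], n, n) * tr
  sv <- svd(A)
  keep <- sv$d >= threshold * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  r <- sv$v %*% (dinv * (t(sv$u) %*% conc_tissue))
  apply(abs(r), 2, max)
}
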