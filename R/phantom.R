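# Evaluate code with a locally fixed RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a sinusoidal end-tidal CO2 trace
#'
#' The stimulus the gas blender targets: EtCO2 modulated as
#' `baseline + (peak_to_peak / 2) * sin(2 pi t / period)` (default 35-45
#' mmHg about 40 mmHg with a 60 s period), with EtO2 clamped constant.
#' Optional breath-level Gaussian jitter emulates end-tidal sampling noise.
#'
#' @param duration Trace duration in seconds; must cover at least two
#'   periods.
#' @param period Stimulus period in seconds (default 60).
#' @param baseline Mean EtCO2 in mmHg (default 40).
#' @param peak_to_peak Peak-to-peak EtCO2 excursion in mmHg (default 10);
#'   zero gives a constant trace, negative values are an error.
#' @param dt Sampling interval in seconds (default 1).
#' @param eto2 Constant EtO2 level in mmHg (default 110).
#' @param jitter_sd Breath-level jitter standard deviation in mmHg
#'   (default 0).
#' @param seed RNG seed for the jitter; all randomness flows through it.
#' @return A [gas_trace()].
#' @export
generate_etco2_trace <- function(duration, period = 60, baseline = 40,
                                 peak_to_peak = 10, dt = 1, eto2 = 110,
                                 jitter_sd = 0, seed = NULL) {
  if (peak_to_peak < 0)
    stop("'peak_to_peak' must be non-negative")
  if (duration < 2 * period)
    stop("duration must cover at least two stimulus periods")
  t <- seq(0, duration, by = dt)
  x <- baseline + peak_to_peak / 2 * sin(2 * pi * t / period)
  if (jitter_sd > 0)
    x <- x + with_seed(seed, stats::rnorm(length(t), sd = jitter_sd))
  gas_trace(t, x, eto2 = rep(eto2, length(t)))
}

#' Digital phantom specification
#'
#' Parameters of the forward tracer-kinetics model used to synthesize
#' multi-echo BOLD data with known ground truth. Defaults mirror the
#' acquisition (TR 1.5 s, TE 35/90 ms, 220 dynamics, 60 s period, 35-45
#' mmHg EtCO2) and anchor the compartments at physiological grey/white
#' matter values (CBF 48/25 mL/100 g/min, CBV 3.9/1.7 mL/100 g).
#'
#' At a single stimulus frequency the kinetic model ties the compartment
#' parameters together: the residue magnitude must equal the mean transit
#' time, so the compartment time delay is *derived* as
#' `tau = 1 / sqrt(MTT^-2 - (2 pi f_c)^2)`, and the white-matter CVR
#' follows from the CBV ratio once the grey-matter CVR fixes the BOLD
#' amplitude scale (default 0.14 %/mmHg, i.e. ~1.4% peak-to-peak in grey
#' matter for a 10 mmHg stimulus). Vein voxels carry the blood-pool curve
#' itself, delayed by `vein_delay` so they sit at the top of the delay
#' histogram.
#'
#' @param dim Grid dimensions, length 3 (default `c(32, 32, 8)`).
#' @param n_frames Number of dynamics (default 220).
#' @param tr Repetition time in seconds (default 1.5).
#' @param te Echo times in seconds (default `c(0.035, 0.090)`).
#' @param period Stimulus period in seconds (default 60).
#' @param etco2_baseline,etco2_peak_to_peak Stimulus parameters in mmHg
#'   (defaults 40 and 10).
#' @param cbf,cbv Named compartment vectors (`gm`, `wm`) of ground-truth
#'   CBF (mL/100 g/min) and CBV (mL/100 g).
#' @param cvr_gm Grey-matter CVR in %/mmHg; sets the overall BOLD response
#'   amplitude.
#' @param vein_delay Centre of the venous response delays in seconds
#'   (default 10).
#' @param vein_delay_spread Total spread of vein delays in seconds (default
#'   1): vein voxels are assigned delays on a uniform grid of this width so
#'   the venous tail of the delay histogram has realistic thickness. The
#'   *design* venous reference is the 98th-percentile order statistic of
#'   the resulting in-brain delay distribution, and tissue compartments
#'   lead that reference by their derived time delay, making the
#'   percentile-based venous rule self-consistent by construction.
#' @param tsnr Target temporal SNR: noise sd is calibrated so the mean tSNR
#'   over (vein-suppressed) brain tissue equals this value (default 1.36).
#'   Use `Inf` for a noiseless phantom.
#' @param s0,s0_background Baseline signal inside/outside the brain
#'   (arbitrary units).
#' @param etco2_dt Gas-trace sampling interval in seconds.
#' @param seed RNG seed for the additive noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(32, 32, 8), n_frames = 220, tr = 1.5,
                         te = c(0.035, 0.090), period = 60,
                         etco2_baseline = 40, etco2_peak_to_peak = 10,
                         cbf = c(gm = 48, wm = 25),
                         cbv = c(gm = 3.9, wm = 1.7),
                         cvr_gm = 0.14, vein_delay = 10,
                         vein_delay_spread = 1, tsnr = 1.36,
                         s0 = 1000, s0_background = 50, etco2_dt = 1,
                         seed = 1234L) {
  if (period < 2 * tr)
    stop("stimulus period below the Nyquist limit (period < 2 * TR)")
  if (any(cbf <= 0) || any(cbv <= 0) || cvr_gm <= 0)
    stop("ground-truth CBF, CBV and CVR must be strictly positive")
  if (!all(c("gm", "wm") %in% names(cbf)) || !all(c("gm", "wm") %in% names(cbv)))
    stop("'cbf' and 'cbv' must be named vectors with elements 'gm' and 'wm'")
  if (etco2_peak_to_peak <= 0)
    stop("'etco2_peak_to_peak' must be positive")
  mtt <- 60 * cbv[c("gm", "wm")] / cbf[c("gm", "wm")]
  if (any(mtt >= period / (2 * pi)))
    stop("compartment MTT too long for the stimulus period (residue magnitude cannot reach it)")
  structure(list(dim = dim, n_frames = n_frames, tr = tr, te = te,
                 period = period, etco2_baseline = etco2_baseline,
                 etco2_peak_to_peak = etco2_peak_to_peak,
                 cbf = cbf, cbv = cbv, cvr_gm = cvr_gm,
                 vein_delay = vein_delay,
                 vein_delay_spread = vein_delay_spread, tsnr = tsnr, s0 = s0,
                 s0_background = s0_background, etco2_dt = etco2_dt,
                 seed = seed),
            class = "phantom_spec")
}

# Compartment geometry: an axis-aligned brain box with a cortical
# grey-matter shell around a central white-matter core and a posterior
# venous block. Fractions scale with the grid.
phantom_geometry <- function(dim) {
  lo <- pmax(1L, round(0.10 * dim[1:2]))
  xr <- (lo[1] + 1):(dim[1] - lo[1])
  yr <- (lo[2] + 1):(dim[2] - lo[2])
  zlo <- max(0L, round(0.10 * dim[3]))
  zr <- (zlo + 1):(dim[3] - zlo)
  brain <- array(FALSE, dim)
  brain[xr, yr, zr] <- TRUE
  vein <- array(FALSE, dim)
  vein[round(0.42 * dim[1]):round(0.55 * dim[1]),
       round(0.80 * dim[2]):round(0.92 * dim[2]), zr] <- TRUE
  vein <- vein & brain
  cx <- (1 + dim[1]) / 2
  cy <- (1 + dim[2]) / 2
  r2 <- outer((seq_len(dim[1]) - cx)^2, (seq_len(dim[2]) - cy)^2, "+")
  core <- array(rep(r2 <= (0.26 * dim[1])^2, dim[3]), dim)
  labels <- array(0L, dim)
  labels[brain] <- 1L                 # grey-matter shell
  labels[brain & core] <- 2L          # white-matter core
  labels[vein] <- 3L                  # draining veins
  list(brain = brain, labels = labels)
}

#' Generate a digital phantom
#'
#' Renders multi-echo BOLD volumes from the steady-state forward
#' tracer-kinetics model with known ground truth. Vein voxels carry the
#' blood-pool concentration curve (a delayed sinusoid following the EtCO2
#' drive); tissue voxels carry the steady-state response
#' `CBF_raw * |R(f_c; tau)|` times the blood amplitude, leading the vein by
#' the compartment time delay. Signals are rendered per echo as
#' `S(t) = S0 * exp(-TE * C(t))` and Gaussian noise is added at the sd
#' implied by the tSNR target.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `echoes` (list of [echo_series()], one
#'   per TE), `gas` (the EtCO2 [gas_trace()]), `brain_mask`, `labels`
#'   (0 background, 1 grey matter, 2 white matter, 3 vein), `truth` (list
#'   of 3D maps `cbf`, `cbv`, `td`, `mtt`, `cvr`, plus `vein_delay`,
#'   `blood_amplitude`, `tissue_delay` per compartment), `noise_sd`
#'   (signal units), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  geo <- phantom_geometry(d)
  labels <- geo$labels
  brain <- geo$brain
  n_vein <- sum(labels == 3L)
  n_brain <- sum(brain)
  if (n_vein < 20 || n_vein / n_brain <= 0.021)
    stop("vein compartment too small for the 98th-percentile venous rules; enlarge the grid")

  f_c <- 1 / spec$period
  omega <- 2 * pi * f_c
  kappa <- 1 / 0.69
  rho <- 1.05
  te1 <- spec$te[1]
  amp_co2 <- spec$etco2_peak_to_peak / 2

  mtt <- 60 * spec$cbv[c("gm", "wm")] / spec$cbf[c("gm", "wm")]
  tau <- 1 / sqrt(1 / mtt^2 - omega^2)          # derived compartment TD (s)
  ratio <- spec$cbv[c("gm", "wm")] * rho / (100 * kappa)  # tissue/blood magnitude
  a_gm <- spec$cvr_gm * amp_co2 / (100 * te1)   # GM delta-R2* amplitude (1/s)
  a_blood <- unname(a_gm / ratio["gm"])
  a_t <- a_blood * ratio                        # per-compartment amplitudes
  cvr_c <- 100 * te1 * a_t / amp_co2            # implied CVR, %/mmHg

  # vein delays on a deterministic uniform grid; the design venous
  # reference is the 98th-percentile order statistic of the in-brain delay
  # distribution (all tissue delays lie below the vein block, so only the
  # vein order statistics matter)
  lab <- as.vector(labels)
  vein_delays <- spec$vein_delay +
    spec$vein_delay_spread * (seq(0, 1, length.out = n_vein) - 0.5)
  venous_ref <- stats::quantile(c(rep(0, n_brain - n_vein), vein_delays),
                                0.98, names = FALSE, type = 7)
  d_tissue <- venous_ref - tau
  if (any(d_tissue < 0))
    stop("vein_delay shorter than a compartment time delay; increase it")

  # per-voxel amplitude and response delay
  amp <- delay <- rep(0, length(lab))
  amp[lab == 1L] <- a_t["gm"]; delay[lab == 1L] <- d_tissue["gm"]
  amp[lab == 2L] <- a_t["wm"]; delay[lab == 2L] <- d_tissue["wm"]
  amp[lab == 3L] <- a_blood;   delay[lab == 3L] <- vein_delays

  t <- (seq_len(spec$n_frames) - 1) * spec$tr
  # C(t) = -A sin(omega (t - d)): CO2 up -> oxygenation up -> delta-R2* down
  conc <- -outer(amp * cos(omega * delay), sin(omega * t)) +
    outer(amp * sin(omega * delay), cos(omega * t))

  # noise calibration: mean tissue peak-to-peak percent / target tSNR
  pp_pct <- 200 * te1 * amp
  sd_pct <- if (is.finite(spec$tsnr) && spec$tsnr > 0)
    mean(pp_pct[lab %in% c(1L, 2L)]) / spec$tsnr else 0
  noise_sd <- spec$s0 * sd_pct / 100

  s0vox <- ifelse(lab > 0L, spec$s0, spec$s0_background)
  echoes <- with_seed(spec$seed, lapply(spec$te, function(te) {
    s <- s0vox * exp(-te * conc)
    if (noise_sd > 0)
      s <- s + stats::rnorm(length(s), sd = noise_sd)
    if (any(s <= 0))
      stop("noise level drove the signal non-positive; lower tsnr target or raise s0")
    dim(s) <- c(d, spec$n_frames)
    echo_series(s, te = te, tr = spec$tr)
  }))

  gas <- generate_etco2_trace(duration = spec$n_frames * spec$tr,
                              period = spec$period,
                              baseline = spec$etco2_baseline,
                              peak_to_peak = spec$etco2_peak_to_peak,
                              dt = spec$etco2_dt)

  mk_truth <- function(gm, wm, vein = NA_real_) {
    v <- rep(NA_real_, length(lab))
    v[lab == 1L] <- gm; v[lab == 2L] <- wm; v[lab == 3L] <- vein
    as_map(v, d)
  }
  truth <- list(
    cbf = mk_truth(spec$cbf["gm"], spec$cbf["wm"]),
    cbv = mk_truth(spec$cbv["gm"], spec$cbv["wm"]),
    td = mk_truth(tau["gm"], tau["wm"]),
    mtt = mk_truth(mtt["gm"], mtt["wm"]),
    cvr = mk_truth(cvr_c["gm"], cvr_c["wm"], 100 * te1 * a_blood / amp_co2),
    venous_reference_delay = venous_ref,
    blood_amplitude = a_blood,
    tissue_delay = d_tissue)

  structure(list(echoes = echoes, gas = gas, brain_mask = brain,
                 labels = labels, truth = truth, noise_sd = noise_sd,
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- x$spec$dim
  cat(sprintf("<phantom> %d x %d x %d x %d, %d echoes, noise sd %.3g a.u. (seed %s)\n",
              d[1], d[2], d[3], x$spec$n_frames, length(x$echoes),
              x$noise_sd, format(x$spec$seed)))
  cat(sprintf("  compartments: GM %d, WM %d, vein %d of %d brain voxels\n",
              sum(x$labels == 1L), sum(x$labels == 2L), sum(x$labels == 3L),
              sum(x$brain_mask)))
  invisible(x)
}
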