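#' Construct a single-echo BOLD series
#'
#' An `echo_series` holds a 4D gradient-echo BOLD acquisition for one echo
#' time, together with its timing metadata. Frame `i` (1-based) is taken to
#' have been acquired at `t0 + (i - 1) * tr` seconds.
#'
#' @param data 4D numeric array (x, y, z, t) of signal intensity, arbitrary
#'   units. Must be finite and non-negative, with at least 8 time points.
#' @param te Echo time in seconds (e.g. 0.035).
#' @param tr Repetition time in seconds (e.g. 1.5).
#' @param t0 Acquisition time of the first frame in seconds.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(data, te, tr, t0 = 0) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 8L)
    stop("echo series needs at least 8 time points")
  if (!all(is.finite(data)))
    stop("echo series contains non-finite values")
  if (min(data) < 0)
    stop("echo series contains negative signal intensities")
  if (!is.numeric(te) || length(te) != 1L || te <= 0)
    stop("'te' must be a single positive number (seconds)")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number (seconds)")
  structure(list(data = data, te = te, tr = tr, t0 = t0),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<echo_series> %d x %d x %d grid, %d frames, TE %.1f ms, TR %.3g s\n",
              d[1], d[2], d[3], d[4], 1000 * x$te, x$tr))
  invisible(x)
}

#' Construct a concentration (delta-R2*) series
#'
#' Voxelwise tracer-concentration curves C(t), in units of delta-R2* (1/s).
#' Concentration is taken proportional to delta-R2* with unit coefficients
#' (`r_y_tissue`, `r_y_blood`) by default; estimators downstream only use
#' ratios of tissue to blood concentration, so any common positive scaling
#' cancels.
#'
#' @param data 4D numeric array (x, y, z, t) of delta-R2* in 1/s.
#' @param tr Repetition time in seconds.
#' @param t0 Time of first sample (seconds).
#' @param r_y_tissue,r_y_blood Strictly positive proportionality
#'   coefficients between delta-R2* and concentration (default 1).
#' @return An object of class `conc_series`.
#' @export
conc_series <- function(data, tr, t0 = 0, r_y_tissue = 1, r_y_blood = 1) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, t)")
  if (r_y_tissue <= 0 || r_y_blood <= 0)
    stop("proportionality coefficients must be strictly positive")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number (seconds)")
  structure(list(data = data, tr = tr, t0 = t0,
                 r_y_tissue = r_y_tissue, r_y_blood = r_y_blood),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<conc_series> %d x %d x %d grid, %d frames, TR %.3g s (delta-R2*, 1/s)\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Construct an end-tidal gas trace
#'
#' @param t Strictly increasing sample times in seconds.
#' @param etco2 End-tidal CO2 partial pressure in mmHg (must lie in
#'   (0, 100], the physiological plausibility range).
#' @param eto2 Optional end-tidal O2 partial pressure in mmHg.
#' @return A data frame of class `gas_trace` with columns `time_s`,
#'   `etco2_mmHg` and (optionally) `eto2_mmHg`.
#' @export
gas_trace <- function(t, etco2, eto2 = NULL) {
  if (length(t) != length(etco2))
    stop("'t' and 'etco2' must have equal length")
  if (any(diff(t) <= 0))
    stop("gas trace times must be strictly increasing")
  if (any(etco2 <= 0) || any(etco2 > 100))
    stop("EtCO2 values outside the plausible (0, 100] mmHg range")
  out <- data.frame(time_s = t, etco2_mmHg = etco2)
  if (!is.null(eto2)) {
    if (length(eto2) != length(t))
      stop("'eto2' must match the length of 't'")
    out$eto2_mmHg <- eto2
  }
  class(out) <- c("gas_trace", "data.frame")
  out
}

# --- internal helpers ------------------------------------------------------

# Wrap values into [0, period)
wrap_period <- function(x, period) {
  y <- x %% period
  # guard against period itself appearing through floating point
  y[y >= period] <- 0
  y
}

# Wrap values into (-period/2, period/2]
wrap_centered <- function(x, period) {
  y <- x %% period
  hi <- !is.na(y) & y > period / 2
  y[hi] <- y[hi] - period
  y
}

# Wrap radians into [-pi, pi)
wrap_pi <- function(phi) {
  y <- (phi + pi) %% (2 * pi) - pi
  y[y >= pi] <- -pi
  y
}

# Number of samples spanning the largest integer number of stimulus cycles.
# Requires the samples-per-cycle count to be (numerically) an integer so the
# fundamental is exactly resolved; otherwise falls back to the full series
# with a warning (least-squares projection remains well defined, but strict
# spectral orthogonality is lost).
n_integer_cycles <- function(n_t, tr, f_c, tol = 1e-8) {
  spc <- 1 / (f_c * tr)
  if (abs(spc - round(spc)) > tol * spc) {
    warning("samples per stimulus cycle is not an integer; series not cropped")
    return(n_t)
  }
  spc <- round(spc)
  n_cyc <- floor(n_t / spc)
  if (n_cyc < 1L)
    stop("series shorter than one stimulus cycle")
  n_cyc * spc
}

# Flatten a 4D array to voxels x time
as_voxel_matrix <- function(arr4d) {
  d <- dim(arr4d)
  dim(arr4d) <- c(prod(d[1:3]), d[4])
  arr4d
}

# Restore a voxel vector to a 3D map
as_map <- function(v, dim3) {
  dim(v) <- dim3
  v
}

check_fc <- function(f_c, tr) {
  if (!is.numeric(f_c) || length(f_c) != 1L || f_c <= 0)
    stop("fundamental frequency must be a single positive number (Hz)")
  if (f_c >= 1 / (2 * tr))
    stop(sprintf("fundamental frequency %.4g Hz is at or above Nyquist (%.4g Hz)",
                 f_c, 1 / (2 * tr)))
  invisible(f_c)
}
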