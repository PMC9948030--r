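test_that("residue magnitude spectrum matches the closed form and its limits", {
  # DC limit |R(0)| = tau
  expect_equal(residue_magnitude(6.4, 0), 6.4)
  # closed-form evaluation at the fundamental
  expect_equal(residue_magnitude(6.4, 1 / 60), 5.31642, tolerance = 1e-5)
  # high-frequency asymptote 1 / (2 pi f) within 0.05%
  expect_lt(abs(residue_magnitude(6.4, 1) / (1 / (2 * pi)) - 1), 5e-4)
  # strictly decreasing in f and bounded above by tau
  f <- seq(0, 0.5, by = 0.01)
  r <- residue_magnitude(6.4, f)
  expect_true(all(diff(r) < 0))
  expect_true(all(r <= 6.4))
  expect_error(residue_magnitude(-1, 0.1), "positive")
})

test_that("time-delay wrap identities hold", {
  f_c <- 1 / 60
  expect_equal(time_delay_map(0.7, 0.7, f_c), 0)
  # a full 2 pi phase difference wraps back to zero
  expect_equal(time_delay_map(0.3 + 2 * pi, 0.3, f_c), 0, tolerance = 1e-9)
  # pi/2 rad at 1/60 Hz is an eighth of a cycle: (pi/2) / (2 pi / 60) = 15 s
  expect_equal(time_delay_map(pi / 2, 0, f_c), 15, tolerance = 1e-12)
  # NA phases propagate
  expect_true(is.na(time_delay_map(NA_real_, 0, f_c)))
})

test_that("frequency-domain CBF reproduces the worked scaling example", {
  cfg <- kinetics_config()
  # |C_t| = 0.05, |C_vof| = 1, |R| = 5 s at tau giving that magnitude
  f_c <- 1 / 60
  tau <- 1 / sqrt(1 / 5^2 - (2 * pi * f_c)^2)   # |R(f_c; tau)| == 5 exactly
  cbf <- cbf_frequency_domain(0.05, 1.0, tau, f_c, cfg, tr = 1.5)
  expect_equal(as.numeric(cbf), 0.01 * 6000 * (1 / 0.69) / 1.05,
               tolerance = 1e-9)
  expect_equal(round(as.numeric(cbf), 1), 82.8)

  # kappa/rho cancel out of MTT: MTT = |R(f_c; tau)| by construction
  cbv <- cbv_map(0.05, 1.0, cfg)
  expect_equal(as.numeric(mtt_map(cbv, cbf)), 5, tolerance = 1e-9)

  # tau below the floor is floored and counted
  cbf2 <- cbf_frequency_domain(0.05, 1.0, 0.01, f_c, cfg, tr = 1.5)
  expect_identical(attr(cbf2, "n_floored"), 1L)

  expect_error(cbf_frequency_domain(0.05, 0, 5, f_c, cfg, tr = 1.5),
               "positive")
})

test_that("CBF is invariant to a common rescaling of tissue and VOF spectra", {
  cfg <- kinetics_config()
  mag_t <- c(0.02, 0.1, 0.4)
  a <- cbf_frequency_domain(mag_t, 2, c(4, 5, 6), 1 / 60, cfg, tr = 1.5)
  b <- cbf_frequency_domain(3.7 * mag_t, 3.7 * 2, c(4, 5, 6), 1 / 60, cfg,
                            tr = 1.5)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
})

test_that("CBV estimators agree with the worked example and with each other", {
  cfg <- kinetics_config()
  expect_equal(cbv_map(0.02, 1, cfg), 100 * (1 / 0.69) / 1.05 * 0.02,
               tolerance = 1e-12)
  expect_equal(round(cbv_map(0.02, 1, cfg), 2), 2.76)
  # a pure-blood voxel with kappa = rho = 1 reads 100 mL/100 g
  expect_equal(cbv_map(0.8, 0.8, kinetics_config(kappa = 1, rho = 1)), 100)

  # rectified-AUC variant equals the magnitude ratio on noiseless sinusoids
  tr <- 1.5
  t <- (0:119) * tr
  a <- array(0, c(2, 1, 1, length(t)))
  a[1, 1, 1, ] <- 0.11 * sin(2 * pi * t / 60 - 0.4)
  a[2, 1, 1, ] <- 0.02 * sin(2 * pi * t / 60 + 0.9)
  conc <- conc_series(a, tr = tr)
  vofc <- 0.8 * sin(2 * pi * t / 60)
  v_auc <- cbv_map_auc(conc, vofc, 1 / 60, cfg)
  v_mag <- cbv_map(c(0.11, 0.02), 0.8, cfg)
  expect_equal(as.numeric(v_auc[, 1, 1]), as.numeric(v_mag),
               tolerance = 5e-3)
})

test_that("MTT obeys the central volume theorem bookkeeping", {
  # Table-like grey-matter numbers: 3.9 / 47.9 * 60 s
  expect_equal(round(mtt_map(3.9, 47.9), 2), 4.89)
  expect_equal(mtt_map(0, 50), 0)
  expect_equal(mtt_map(2 * 3.9, 2 * 47.9), mtt_map(3.9, 47.9))
  expect_true(is.na(mtt_map(3.9, 0)))
})

test_that("CVR regression recovers slope and lag from constructed signals", {
  tr <- 1.5
  n <- 160
  t <- (0:(n - 1)) * tr
  gt <- seq(0, n * tr + 10, by = 0.25)
  co2 <- 40 + 2.5 * sin(2 * pi * gt / 60)
  gas <- gas_trace(gt, co2)
  # BOLD% = 0.25 * (EtCO2 - 40) exactly, at the frame mid-times
  pctmid <- 0.25 * (40 + 2.5 * sin(2 * pi * (t + tr / 2) / 60) - 40)
  arr <- array(100, c(3, 2, 1, n))
  for (i in 1:3) for (j in 1:2) arr[i, j, 1, ] <- 100 * (1 + pctmid / 100)
  series <- echo_series(arr, te = 0.035, tr = tr)
  mask <- array(TRUE, c(3, 2, 1))
  cv <- cvr_map(series, gas, mask, period = 60)
  expect_equal(max(abs(cv$cvr - 0.25)), 0, tolerance = 1e-3)
  expect_equal(cv$lag_global, 0, tolerance = tr / 2)

  # EtCO2 effect delayed by 6 s: recovered lag 6 s, slope unchanged within 1%
  pctlag <- 0.25 * 2.5 * sin(2 * pi * ((t + tr / 2) - 6) / 60)
  for (i in 1:3) for (j in 1:2) arr[i, j, 1, ] <- 100 * (1 + pctlag / 100)
  cv2 <- cvr_map(echo_series(arr, te = 0.035, tr = tr), gas, mask,
                 period = 60)
  expect_equal(cv2$lag_global, 6, tolerance = tr / 2)
  expect_lt(max(abs(cv2$cvr / 0.25 - 1)), 0.01)

  expect_error(cvr_map(series, gas_trace(gt, rep(40, length(gt))), mask),
               "variance")
})

test_that("the linearized flow model oscillates by CVR times the stimulus swing", {
  t <- seq(0, 240, by = 0.1)
  gas <- gas_trace(t, 40 + 2.5 * sin(2 * pi * t / 60))
  flow <- cbf_time_course(50, cvr = 0.2, etco2 = gas)
  pp_pct <- 100 * (max(flow) - min(flow)) / 50
  # 0.2 %/mmHg x 5 mmHg peak-to-peak -> ~1% flow oscillation
  expect_equal(pp_pct, 1.0, tolerance = 1e-6)
})

test_that("SVD deconvolution recovers an impulse-driven residue and truncates monotonically", {
  tr <- 1.0
  n <- 64
  t <- (0:(n - 1)) * tr
  tau <- 6.4
  F <- 0.012
  vof <- c(1 / tr, rep(0, n - 1))          # unit-area impulse
  tis <- F * exp(-t / tau)
  rec <- svd_deconvolution(tis, vof, tr, threshold = 0.1)
  expect_lt(abs(rec / F - 1), 0.02)

  # harmonic-rich periodic drive with decaying spectrum: raising the
  # truncation threshold can only lower the recovered maximum
  vof2 <- rowSums(sapply(1:10, function(h) sin(2 * pi * h * t / (n * tr)) / h))
  kern <- F * exp(-t / tau) * tr
  tis2 <- Re(fft(fft(vof2) * fft(kern), inverse = TRUE)) / n
  r_lo <- svd_deconvolution(tis2, vof2, tr, threshold = 0.01)
  r_hi <- svd_deconvolution(tis2, vof2, tr, threshold = 0.5)
  expect_lte(r_hi, r_lo * (1 + 1e-9))

  expect_error(svd_deconvolution(tis, vof, tr, threshold = 1.2), "threshold")
})

test_that("frequency-domain and SVD CBF agree on a broadband noiseless system", {
  # flat-spectrum periodic vein drive pushed through the exponential residue
  # by discrete circular convolution; both estimators see the same system
  set.seed(5)
  dt <- 0.25
  n <- 480                                  # two 60 s cycles
  t <- (0:(n - 1)) * dt
  f_c <- 1 / 60
  # random-phase, equal-magnitude spectrum (real signal)
  # flat spectrum with a DC term (bolus-like positive drive): every
  # frequency the residue lives on, including DC, is observable
  ph <- runif(n / 2 - 1, 0, 2 * pi)
  spec <- c(1, exp(1i * ph), 1, Conj(rev(exp(1i * ph))))
  vof <- Re(fft(spec, inverse = TRUE))
  vof <- vof / sd(vof)
  taus <- c(rep(5.669, 30), rep(4.513, 30)) # GM- and WM-like constants
  Fs <- seq(0.004, 0.008, length.out = 60)
  zv <- sinedsc:::demodulate_curve(vof, dt, f_c, detrend = FALSE)
  fv <- fft(vof)
  tis <- sapply(seq_along(Fs), function(i) {
    kern <- Fs[i] * exp(-t / taus[i]) * dt
    Re(fft(fv * fft(kern), inverse = TRUE)) / n
  })
  svd_cbf <- svd_deconvolution(tis, vof, dt, threshold = 0.1)
  fd_cbf <- vapply(seq_along(Fs), function(i) {
    zt <- sinedsc:::demodulate_curve(tis[, i], dt, f_c, detrend = FALSE)
    Mod(zt) / (Mod(zv) * residue_magnitude(taus[i], f_c))
  }, numeric(1))
  expect_lt(max(abs(fd_cbf / svd_cbf - 1)), 0.05)
  expect_lt(max(abs(svd_cbf / Fs - 1)), 0.01)
})
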