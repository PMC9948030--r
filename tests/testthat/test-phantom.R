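test_that("the EtCO2 generator reproduces the stimulus definition", {
  g <- generate_etco2_trace(duration = 300)
  expect_equal(min(g$etco2_mmHg), 35, tolerance = 1e-9)
  expect_equal(max(g$etco2_mmHg), 45, tolerance = 1e-9)
  # value a quarter period in is the peak; a full period later repeats
  expect_equal(g$etco2_mmHg[g$time_s == 15], 45)
  expect_equal(g$etco2_mmHg[g$time_s == 75], 45)

  # zero swing gives a constant baseline trace
  g0 <- generate_etco2_trace(duration = 300, peak_to_peak = 0)
  expect_true(all(g0$etco2_mmHg == 40))
  expect_error(generate_etco2_trace(duration = 300, peak_to_peak = -1),
               "non-negative")
  expect_error(generate_etco2_trace(duration = 100), "two")

  # jitter is reproducible from the seed and leaves global RNG state alone
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  g1 <- generate_etco2_trace(duration = 300, jitter_sd = 0.5, seed = 7)
  g2 <- generate_etco2_trace(duration = 300, jitter_sd = 0.5, seed = 7)
  expect_identical(g1, g2)
  expect_identical(rnorm(1), before)
})

test_that("phantom construction is deterministic with physiological amplitudes", {
  ph1 <- small_phantom(tsnr = 1.36, seed = 5)
  ph2 <- small_phantom(tsnr = 1.36, seed = 5)
  expect_identical(ph1$echoes[[1]]$data, ph2$echoes[[1]]$data)
  expect_identical(ph1$echoes[[2]]$data, ph2$echoes[[2]]$data)

  # grey-matter BOLD peak-to-peak lies in the design band (~1.2-1.5%)
  ph <- small_phantom()
  qm <- quality_maps(ph$echoes[[1]], 1 / 60, mask = ph$brain_mask)
  gm_pp <- median(qm$amplitude[ph$labels == 1L])
  expect_gt(gm_pp, 1.2)
  expect_lt(gm_pp, 1.5)
  # white matter responds much less, veins much more
  expect_lt(median(qm$amplitude[ph$labels == 2L]), 0.8)
  expect_gt(median(qm$amplitude[ph$labels == 3L]), 10)

  # compartment ground truth is internally consistent with the kinetics:
  # |R(f_c; TD)| equals the mean transit time
  idx <- which(ph$labels == 1L)[1]
  expect_equal(residue_magnitude(ph$truth$td[idx], 1 / 60),
               ph$truth$mtt[idx], tolerance = 1e-9)

  expect_error(phantom_spec(period = 2, tr = 1.5), "Nyquist")
  expect_error(phantom_spec(cbf = c(gm = 10, wm = 5),
                            cbv = c(gm = 3.9, wm = 1.7)), "MTT")
})

test_that("phantom noise calibration lands near the target temporal SNR", {
  ph <- generate_phantom(phantom_spec(tsnr = 1.36, seed = 21))
  qm <- quality_maps(ph$echoes[[1]], 1 / 60, mask = ph$brain_mask)
  tissue <- ph$labels == 1L | ph$labels == 2L
  expect_lt(abs(mean(qm$tsnr[tissue]) / 1.36 - 1), 0.10)
  # grey matter sits well above white matter, as in vivo
  expect_gt(mean(qm$tsnr[ph$labels == 1L]), mean(qm$tsnr[ph$labels == 2L]))
})

test_that("tissue curves equal the anti-causal residue convolution at low frequency-residue product", {
  # In the low omega*tau regime the linear-phase steady-state construction
  # coincides with the true exponential-residue (time-reversed) convolution;
  # verify on an analytic fine grid.
  period <- 60
  f_c <- 1 / period
  omega <- 2 * pi * f_c
  dt <- 0.1
  n <- period / dt * 2
  t <- (0:(n - 1)) * dt
  tau <- 1.52                      # omega * tau ~ 0.16
  Fraw <- 0.01
  a_v <- 5
  d_v <- 10
  vein <- -a_v * sin(omega * (t - d_v))
  # phantom construction: amplitude Fraw |R|, leading the vein by tau
  tissue <- -Fraw * residue_magnitude(tau, f_c) * a_v *
    sin(omega * (t - (d_v - tau)))
  # anti-causal discrete circular convolution with the exponential residue
  kern <- Fraw * exp(-(t + dt / 2) / tau) * dt
  pred <- Re(fft(fft(vein) * Conj(fft(kern)), inverse = TRUE)) / n
  expect_lt(max(abs(pred - tissue)) / max(abs(tissue)), 0.01)

  # at grey-matter-like tau the magnitudes still agree but the phases differ
  # by the documented first-order gap tau - atan(omega tau) / omega
  tau <- 5.669
  tissue_z <- Fraw * residue_magnitude(tau, f_c) * a_v
  kern <- Fraw * exp(-(t + dt / 2) / tau) * dt
  pred <- Re(fft(fft(vein) * Conj(fft(kern)), inverse = TRUE)) / n
  zp <- sinedsc:::demodulate_curve(pred, dt, f_c)
  expect_equal(Mod(zp), tissue_z, tolerance = 5e-3)
  zv <- sinedsc:::demodulate_curve(vein, dt, f_c)
  lead <- ((Arg(zp) - Arg(zv)) / omega) %% period
  expect_equal(lead, atan(omega * tau) / omega, tolerance = 0.05)
})

test_that("writing then reading the phantom reproduces arrays bit-exactly", {
  ph <- small_phantom(tsnr = 1.36, seed = 3)
  dir <- tempfile("phantom")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_phantom(ph, dir)
  e1 <- read_echo_series(paths$echo1, te = 0.035)
  expect_identical(e1$data, ph$echoes[[1]]$data)
  expect_equal(e1$tr, 1.5, tolerance = 1e-6)
  lab <- read_label_volume(paths$labels)
  expect_identical(lab, ph$labels + 0L)
  truth_cbf <- RNifti::readNifti(paths$truth_cbf)
  expect_identical(array(as.numeric(truth_cbf), dim(ph$truth$cbf)),
                   ph$truth$cbf)
  gas <- read_gas_trace(paths$gas)
  expect_equal(gas$etco2_mmHg, ph$gas$etco2_mmHg, tolerance = 1e-12)
})
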