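test_that("ROI curve extraction averages masked pixels per frame", {
  stack <- array(7, dim = c(4, 4, 6))
  mask <- matrix(TRUE, 4, 4)
  times <- (0:5) * 0.1
  cur <- extract_roi_curve(stack, mask, times, td = 0.015, role = "blood")
  expect_equal(cur$values, rep(7, 6))

  # single-pixel mask returns that pixel's series
  stack2 <- array(rnorm(4 * 4 * 6), dim = c(4, 4, 6))
  m1 <- matrix(FALSE, 4, 4); m1[2, 3] <- TRUE
  cur2 <- extract_roi_curve(stack2, m1, times, td = 0.057)
  expect_equal(cur2$values, stack2[2, 3, ])

  expect_error(extract_roi_curve(stack, matrix(FALSE, 4, 4), times, 0.015),
               "empty")
  expect_error(extract_roi_curve(stack, mask, times[-1], 0.015), "frame")
})

test_that("proton-density normalization is a pure scale operation", {
  times <- (0:9) * 0.12
  raw <- signal_series(times, seq(1, 2, length.out = 10) * 50, td = 0.057,
                       normalized = FALSE)
  expect_equal(normalize_by_pd(raw, 1)$values, raw$values)
  expect_equal(normalize_by_pd(raw, 50)$values,
               seq(1, 2, length.out = 10))
  # scaling raw and reference together changes nothing
  raw2 <- signal_series(times, raw$values * 3, td = 0.057,
                        normalized = FALSE)
  expect_equal(normalize_by_pd(raw2, 150)$values,
               normalize_by_pd(raw, 50)$values)
  expect_error(normalize_by_pd(raw, 0), "pd_value")
})

test_that("saturation-recovery inversion recovers T1", {
  expect_equal(signal_to_t1(1 - exp(-1), td = 0.015), 0.015)
  expect_equal(signal_to_t1(1 - exp(-0.015 / 1.55), 0.015), 1.55)
  expect_equal(signal_to_t1(1 - exp(-0.057 / 1.45), 0.057), 1.45)
  # printed-precision endpoints from the fixed pre-contrast T1s
  expect_equal(signal_to_t1(0.009631, 0.015), 1.55, tolerance = 1e-4)
  expect_equal(signal_to_t1(0.038548, 0.057), 1.45, tolerance = 1e-4)
  # strictly decreasing in s
  s <- seq(0.01, 0.9, by = 0.01)
  expect_true(all(diff(signal_to_t1(s, 0.057)) < 0))
  expect_error(signal_to_t1(c(0.5, 1.2), 0.057), "frame\\(s\\) 2")
  expect_error(signal_to_t1(0, 0.057), "outside")
})

test_that("signal to Delta-R1 conversion round-trips the forward model", {
  acq <- acq_params(n_frames = 40)
  times <- frame_times(acq)
  aif <- gamma_variate_aif(aif_params(), times)
  s <- concentration_to_signal(aif, acq, t1_0 = 1.55, role = "blood")
  back <- series_to_delta_r1(s, t1_0 = 1.55)
  expect_equal(back$delta_r1, aif$delta_r1, tolerance = 1e-9)

  # pre-contrast signal maps to zero concentration
  zero <- concentration_to_signal(conc_curve(times, rep(0, 40)), acq, 1.45)
  expect_equal(series_to_delta_r1(zero, 1.45, baseline_correct = FALSE)$delta_r1,
               rep(0, 40), tolerance = 1e-12)

  # T1 drop 1.45 -> 0.5 s corresponds to Delta-R1 = 2 - 1/1.45
  expect_equal(1 / 0.5 - 1 / 1.45, 1.31034, tolerance = 1e-5)
})

test_that("Fermi deconvolution recovers flow on noiseless phantoms and is monotone", {
  acq <- acq_params()
  times <- frame_times(acq)
  aifc <- gamma_variate_aif(aif_params(), times)
  flows <- c(2, 5, 10, 20)
  rec <- vapply(flows, function(mbf) {
    tf <- tissue_curve_from_fermi(aifc, mprkit:::fermi_for_mbf(mbf))
    fermi_deconvolve(aifc, tf)$mbf
  }, numeric(1))
  expect_equal(rec, flows, tolerance = 0.02)
  expect_true(all(diff(rec) > 0))
})

test_that("Fermi deconvolution zero-tissue and scale-invariance limits hold", {
  acq <- acq_params()
  times <- frame_times(acq)
  aifc <- gamma_variate_aif(aif_params(), times)
  zero_tf <- conc_curve(times, rep(0, length(times)))
  expect_equal(fermi_deconvolve(aifc, zero_tf)$mbf, 0)

  tf <- tissue_curve_from_fermi(aifc, mprkit:::fermi_for_mbf(6))
  f1 <- fermi_deconvolve(aifc, tf)
  f2 <- fermi_deconvolve(conc_curve(times, 7.3 * aifc$delta_r1),
                         conc_curve(times, 7.3 * tf$delta_r1))
  expect_equal(f2$mbf, f1$mbf, tolerance = 1e-6)

  expect_error(fermi_deconvolve(conc_curve(c(0, 1, 3), c(0, 1, 0)),
                                conc_curve(c(0, 1, 3), c(0, 1, 0))),
               "15 frames")
  irregular <- c(times[1:30], times[31:50] + 0.05)
  expect_error(fermi_deconvolve(conc_curve(irregular, aifc$delta_r1),
                                conc_curve(irregular, tf$delta_r1)),
               "uniform")
})

test_that("degenerate constant-kernel fit matches the linear-regression oracle", {
  acq <- acq_params()
  times <- frame_times(acq)
  aifc <- gamma_variate_aif(aif_params(), times)
  flat <- fermi_params(amplitude = 0.14, decay = 0, width = 0)
  tf <- tissue_curve_from_fermi(aifc, flat)
  # independent oracle: least-squares slope of tf on the running AIF integral
  xi <- as.numeric(pracma::cumtrapz(times, aifc$delta_r1))
  slope <- coef(lm(tf$delta_r1 ~ 0 + xi))[[1]]
  mbf_oracle <- slope * 60 / 1.05
  fit <- fermi_deconvolve(aifc, tf)
  expect_equal(fit$mbf, mbf_oracle, tolerance = 0.01)
})

test_that("baseline offset on the tissue signal does not move the flow estimate", {
  acq <- acq_params()
  times <- frame_times(acq)
  aifc <- gamma_variate_aif(aif_params(), times)
  tf <- tissue_curve_from_fermi(aifc, mprkit:::fermi_for_mbf(8))
  aif_d <- series_to_delta_r1(
    concentration_to_signal(aifc, acq, 1.55, role = "blood"), 1.55)
  base <- series_to_delta_r1(
    concentration_to_signal(tf, acq, 1.45, role = "tissue"), 1.45)
  # shift the whole tissue concentration by a constant before the signal
  # model; the pre-bolus baseline correction must remove it
  off <- conc_curve(times, tf$delta_r1 + 0.05)
  shifted <- series_to_delta_r1(
    concentration_to_signal(off, acq, 1.45, role = "tissue"), 1.45,
    baseline_frames = seq_len(7))
  m0 <- fermi_deconvolve(aif_d, base)$mbf
  m1 <- fermi_deconvolve(aif_d, shifted)$mbf
  expect_equal(m1, m0, tolerance = 0.01)
})

test_that("MPR is the stress/rest flow ratio with guarded domain", {
  acq <- acq_params()
  times <- frame_times(acq)
  aifc <- gamma_variate_aif(aif_params(), times)
  mk <- function(mbf, cond) fermi_deconvolve(
    aifc, tissue_curve_from_fermi(aifc, mprkit:::fermi_for_mbf(mbf)),
    condition = cond)
  rest <- mk(4, "rest"); stress <- mk(10, "stress")
  expect_equal(compute_mpr(rest, stress)$mpr, 2.5, tolerance = 0.02)
  expect_equal(compute_mpr(rest, rest)$mpr, 1)
  zero_rest <- fermi_deconvolve(aifc, conc_curve(times, rep(0, 50)),
                                condition = "rest")
  expect_error(compute_mpr(zero_rest, stress), "undefined")
})

test_that("bolus arrival detection finds the first supra-threshold frame", {
  acq <- acq_params()
  times <- frame_times(acq)
  aifc <- gamma_variate_aif(aif_params(t0 = 0.96), times)
  s <- concentration_to_signal(aifc, acq, 1.55, role = "blood")
  arr <- detect_bolus_arrival(s$values)
  expect_gt(times[arr], 0.96)
  expect_lte(times[arr - 1], 1.2)
  expect_error(detect_bolus_arrival(rep(1, 50)), "no bolus")
})
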