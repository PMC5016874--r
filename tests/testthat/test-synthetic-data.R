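test_that("gamma-variate AIF matches its closed form and peak normalization", {
  aif <- aif_params(t0 = 1, t_peak = 3, c_peak = 1, alpha = 2)
  cur <- gamma_variate_aif(aif, c(0, 1, 3, 5))
  expect_equal(cur$delta_r1[1], 0)                  # pre-arrival
  expect_equal(cur$delta_r1[2], 0)                  # exactly at t0
  expect_equal(cur$delta_r1[3], 1)                  # peak value at t_peak
  expect_equal(cur$delta_r1[4], 4 * exp(-2), tolerance = 1e-12)
  # peak is the maximum on a fine grid
  fine <- gamma_variate_aif(aif, seq(0, 20, by = 0.01))
  expect_lte(max(fine$delta_r1), 1)
  expect_error(gamma_variate_aif(aif, c(2, 1)), "nondecreasing")
  expect_error(aif_params(t0 = 3, t_peak = 2), "t_peak")
})

test_that("Fermi forward convolution has the impulse, constant-kernel and linearity properties", {
  acq <- acq_params(n_frames = 40)
  times <- default_times(acq)
  dt <- acq$frame_interval
  fer <- fermi_params(amplitude = 0.2, decay = 1.5, width = 1.2)

  # unit-area impulse at frame 0 (trapezoid weight 1/2 at the endpoint)
  imp <- conc_curve(times, c(2 / dt, rep(0, length(times) - 1)))
  out <- tissue_curve_from_fermi(imp, fer)
  expect_equal(out$delta_r1[-1], fermi_impulse(fer, times)[-1],
               tolerance = 1e-12)

  # constant kernel (k = 0): response is (A/2) * running integral of the AIF
  aifc <- gamma_variate_aif(aif_params(), times)
  flat <- fermi_params(amplitude = 0.2, decay = 0, width = 0)
  out2 <- tissue_curve_from_fermi(aifc, flat)
  expect_equal(out2$delta_r1,
               0.1 * as.numeric(pracma::cumtrapz(times, aifc$delta_r1)),
               tolerance = 1e-12)

  # linearity in the input
  out3 <- tissue_curve_from_fermi(conc_curve(times, 3 * aifc$delta_r1), fer)
  base <- tissue_curve_from_fermi(aifc, fer)
  expect_equal(out3$delta_r1, 3 * base$delta_r1, tolerance = 1e-12)

  expect_error(tissue_curve_from_fermi(
    conc_curve(c(0, 0.1, 0.4), c(0, 1, 0)), fer), "uniform")
})

test_that("saturation-recovery forward signal matches hand-computed values", {
  acq <- acq_params()
  zero <- conc_curve(default_times(acq), rep(0, acq$n_frames))
  s_blood <- concentration_to_signal(zero, acq, t1_0 = 1.55, role = "blood")
  expect_equal(s_blood$values, rep(1 - exp(-0.015 / 1.55), acq$n_frames))
  expect_equal(s_blood$values[1], 0.009631, tolerance = 1e-4)
  s_tis <- concentration_to_signal(zero, acq, t1_0 = 1.45, role = "tissue")
  expect_equal(s_tis$values[1], 0.038548, tolerance = 1e-4)
  # full-recovery limit at very long saturation delay
  long_td <- acq_params(td_tf = 1e3)
  s_inf <- concentration_to_signal(zero, long_td, t1_0 = 1.45, role = "tissue")
  expect_equal(s_inf$values, rep(1, acq$n_frames), tolerance = 1e-12)
  expect_error(concentration_to_signal(zero, acq, t1_0 = -1), "t1_0")
  # seeded noise is reproducible
  n1 <- concentration_to_signal(zero, acq, 1.45, noise_sd = 0.01, seed = 4)
  n2 <- concentration_to_signal(zero, acq, 1.45, noise_sd = 0.01, seed = 4)
  expect_identical(n1$values, n2$values)
})

test_that("rendered perfusion phantom reproduces its closed-form curves and is seed-stable", {
  ph <- perfusion_phantom(mbf_rest = 4, mbf_stress = 10, noise_sd = 0,
                          seed = 11)
  acq <- acq_params(n_frames = 30)
  ser <- render_perfusion_series(ph, acq = acq)
  times <- frame_times(acq)
  aif_curve <- extract_roi_curve(ser$rest$aif_stack, ser$blood_mask, times,
                                 acq$td_aif, role = "blood")
  expect_equal(aif_curve$values, ser$truth$curves$rest$s_blood,
               tolerance = 1e-12)
  tf_curve <- extract_roi_curve(ser$rest$tf_stack, ser$myo_mask, times,
                                acq$td_tf, role = "tissue")
  expect_equal(tf_curve$values, ser$truth$curves$rest$s_tissue,
               tolerance = 1e-12)

  # determinism at nonzero noise
  ph2 <- perfusion_phantom(noise_sd = 0.01, seed = 42)
  s1 <- render_perfusion_series(ph2, acq = acq)
  s2 <- render_perfusion_series(ph2, acq = acq)
  expect_identical(s1$rest$tf_stack, s2$rest$tf_stack)

  # MPR of the ground truth is the flow ratio
  ph3 <- perfusion_phantom(mbf_rest = 4, mbf_stress = 20)
  expect_equal(ph3$mpr, 2 * perfusion_phantom(4, 10)$mpr)
  expect_error(perfusion_phantom(mbf_rest = 5, mbf_stress = 4), "mbf_stress")
})

test_that("rasterized LV masks carry correct analytic truth and converge with resolution", {
  g <- render_lv_masks(list(ED = lv_annulus_spec(2, 3, 1)),
                       pixel_spacing = 0.1, slice_thickness = 1)
  tr <- attr(g, "truth")$ED
  expect_equal(tr$myo_volume, pi * 5, tolerance = 1e-12)   # 15.708 mm^3
  expect_equal(tr$cavity_volume, pi * 4, tolerance = 1e-12)

  # zero endocardial radius leaves an empty cavity
  g0 <- render_lv_masks(list(ED = lv_annulus_spec(0, 3, 1)),
                        pixel_spacing = 0.1)
  expect_equal(cavity_volume(g0, "ED"), 0)

  # halving the pixel spacing reduces the rasterization volume error
  err_at <- function(sp) {
    gg <- render_lv_masks(list(ED = lv_annulus_spec(2, 3, 1)),
                          pixel_spacing = sp)
    abs(cavity_volume(gg, "ED") - pi * 4)
  }
  expect_lt(err_at(0.1), err_at(0.2))
  expect_error(render_lv_masks(list(ED = lv_annulus_spec(3, 2, 1))),
               "r_epi")
})

test_that("cylinder displacement fields carry closed-form Ecc ground truth", {
  # identity deformation: zero displacement and zero strain
  id <- cylinder_deformation(2, 3, 2)
  fs0 <- render_displacements(id, spacing = 0.3, n_frames = 2)
  expect_equal(max(abs(fs0$displacements)), 0)
  expect_equal(max(abs(attr(fs0, "truth")$ecc)), 0)

  def <- cylinder_deformation(2, 3, 1.5)
  fs <- render_displacements(def, spacing = 0.25, n_frames = 3)
  tr <- attr(fs, "truth")
  R <- sqrt(rowSums(sweep(fs$positions, 2, def$center)^2))
  delta <- 2^2 - 1.5^2
  # closed form: Ecc = ((r/R)^2 - 1)/2 = -delta / (2 R^2)
  expect_equal(tr$ecc[, 3], -delta / (2 * R^2), tolerance = 1e-12)
  # r/R = 0.9 gives Ecc = -0.095 (direct formula check)
  R9 <- sqrt(delta / (1 - 0.81))
  expect_equal(-delta / (2 * R9^2), 0.5 * (0.81 - 1), tolerance = 1e-12)
  # magnitude decreases monotonically from endo to epi
  ord <- order(R)
  expect_true(all(diff(abs(tr$ecc[ord, 3])) <= 0))
  # deformed positions are consistent with the stated radial map
  r_def <- sqrt(R^2 - delta)
  expect_equal(sqrt(rowSums((fs$positions + fs$displacements[, , 3])^2)),
               r_def, tolerance = 1e-12)
  expect_error(cylinder_deformation(2, 3, 0), "positive")
})

test_that("phase encoding refuses wrapped phases and inverts exactly", {
  def <- cylinder_deformation(2, 3, 1.8)
  fs <- render_displacements(def, spacing = 0.3, n_frames = 2, ke = 0.5)
  phi <- attr(fs, "phase")
  expect_true(all(abs(phi) < pi))
  expect_equal(decode_displacement_phase(phi, 0.5), fs$displacements,
               tolerance = 1e-15)
  expect_error(render_displacements(def, spacing = 0.3, n_frames = 2,
                                    ke = 3), "wrap")
})

test_that("synthetic GTT curves have the configured shape and are seed-stable", {
  flat <- generate_gtt(baseline = 100, peak = 100, noise_sd = 0)
  expect_equal(flat$glucose, rep(100, 5))
  r1 <- generate_gtt(noise_sd = 10, seed = 3)
  r2 <- generate_gtt(noise_sd = 10, seed = 3)
  expect_identical(r1$glucose, r2$glucose)
  shaped <- generate_gtt(baseline = 90, peak = 300, noise_sd = 0)
  expect_gt(shaped$glucose[shaped$times == 10], shaped$glucose[1])
  # heavy noise on a tiny baseline gets clipped at zero, flagged
  clipped <- generate_gtt(baseline = 1, peak = 2, noise_sd = 50, seed = 1)
  expect_true(all(clipped$glucose >= 0))
})

test_that("cohort generator reproduces configured group structure", {
  eff <- default_cohort_effects()
  eff$sd <- 0
  cfg <- cohort_config(n_per_group = 3, effects = eff, seed = 5)
  coh <- generate_cohort(cfg)
  hfd24 <- coh[coh$group == "hfd" & coh$week == 24, ]
  expect_equal(hfd24$mpr, rep(1.5, 3))
  expect_equal(hfd24$lv_mass, rep(118, 3))

  # null configuration: equal means leave no group difference beyond noise
  eff2 <- default_cohort_effects()
  eff2$mean[eff2$metric == "mpr"] <- 2
  eff2$sd[eff2$metric == "mpr"] <- 0.3
  cfg2 <- cohort_config(n_per_group = 50, effects = eff2, seed = 8)
  coh2 <- generate_cohort(cfg2)
  m <- tapply(coh2$mpr, coh2$group, mean)
  se <- 0.3 * sqrt(2 / (50 * 4))
  expect_lt(abs(diff(m)), 4 * se)

  # configured week-24 difference is recovered within 3 SE at n = 8
  cfg3 <- cohort_config(n_per_group = 8, seed = 21)
  coh3 <- generate_cohort(cfg3)
  w24 <- coh3[coh3$week == 24, ]
  mm <- tapply(w24$mpr, w24$group, mean)
  expect_lt(abs((mm[["control"]] - mm[["hfd"]]) - (2.4 - 1.5)),
            3 * 0.4 * sqrt(2 / 8))
  # bit-reproducible
  expect_identical(coh3, generate_cohort(cfg3))
})
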