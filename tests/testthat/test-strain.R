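test_that("deformation gradient is exact on affine fields", {
  pts <- annulus_pts <- render_displacements(
    cylinder_deformation(2, 3, 2), spacing = 0.25, n_frames = 2)$positions
  # zero displacement: F = I everywhere
  dg <- deformation_gradient(pts, matrix(0, nrow(pts), 2))
  expect_false(any(dg$flagged))
  for (i in c(1, 50, nrow(pts)))
    expect_equal(dg$F[i, , ], diag(2), tolerance = 1e-12)

  # affine displacement u = (M - I) X: F = M exactly at every point
  M <- matrix(c(1.1, 0.05, -0.2, 0.9), 2)
  u <- pts %*% t(M) - pts
  dga <- deformation_gradient(pts, u)
  err <- vapply(seq_len(nrow(pts)),
                function(i) max(abs(dga$F[i, , ] - M)), numeric(1))
  expect_lt(max(err), 1e-8)

  # collinear points cannot support a 2-D gradient
  line <- cbind(seq(0, 2, by = 0.1), 0)
  dgl <- deformation_gradient(line, matrix(0, nrow(line), 2), radius = 0.5)
  expect_true(all(dgl$flagged))
})

test_that("circumferential strain extracts the hoop component of E", {
  # identity and rigid rotation carry no strain
  expect_equal(circumferential_strain(diag(2), c(2, 0), c(0, 0)), 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(circumferential_strain(R, c(2, 0), c(0, 0)), 0,
               tolerance = 1e-15)
  # radial map with circumferential stretch r/R = 0.9 at a point on the
  # x-axis: F = diag(dr/dR, r/R), Ecc = (0.81 - 1)/2 = -0.095
  F <- diag(c(1.2, 0.9))
  expect_equal(circumferential_strain(F, c(2, 0), c(0, 0)), -0.095)
  expect_error(circumferential_strain(diag(2), c(1, 1), c(1, 1)), "center")
})

test_that("cylinder phantom Ecc is recovered pointwise within 1%", {
  def <- cylinder_for_mean_ecc(2, 3, -0.14, spacing = 0.2)
  fs <- render_displacements(def, spacing = 0.2, n_frames = 2)
  truth <- attr(fs, "truth")$ecc[, 2]
  prof <- ecc_profile(fs)
  expect_false(any(prof$flagged))
  rel <- abs(prof$pointwise[, 2] - truth) / abs(truth)
  expect_lt(max(rel), 0.01)
})

test_that("Ecc is invariant under rigid motion of the whole field", {
  def <- cylinder_deformation(2, 3, 1.7)
  fs <- render_displacements(def, spacing = 0.25, n_frames = 2)
  pts <- fs$positions
  u_def <- fs$displacements[, , 2]

  # pure rigid motions produce zero strain
  u_rigid <- rigid_field(pts, theta = 0.4, shift = c(1.3, -0.8))
  U <- array(c(rep(0, length(u_rigid)), u_rigid), c(nrow(pts), 2, 2))
  prof <- ecc_profile(strain_frame_set(pts, U, c(0, 0), c(0, 1), fs$depth))
  expect_lt(max(abs(prof$pointwise[, 2]), na.rm = TRUE), 1e-8)

  # rigidly moving a deforming field leaves Ecc unchanged
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  x_def <- (pts + u_def) %*% t(R)
  U2 <- fs$displacements
  U2[, , 2] <- x_def - pts
  # strain is computed against reference geometry, which has not moved
  prof0 <- ecc_profile(fs)
  prof2 <- ecc_profile(strain_frame_set(pts, U2, c(0, 0), fs$times,
                                        fs$depth))
  expect_equal(prof2$pointwise[, 2], prof0$pointwise[, 2],
               tolerance = 1e-8)
})

test_that("peak strain has the expected magnitude ordering across layers", {
  def <- cylinder_for_mean_ecc(2, 3, -0.14)
  fs <- render_displacements(def, spacing = 0.2, n_frames = 4)
  prof <- ecc_profile(fs)
  pk <- peak_global_ecc(prof)
  expect_equal(pk$frame, 4)  # monotone contraction peaks at the last frame
  expect_equal(pk$global, -0.14, tolerance = 0.005)
  expect_gt(abs(pk$subendo), abs(pk$global))
  expect_lt(abs(pk$subepi), abs(pk$global))

  # zero motion: peak is zero
  U0 <- array(0, dim = c(nrow(fs$positions), 2, 2))
  p0 <- ecc_profile(strain_frame_set(fs$positions, U0, c(0, 0), c(0, 1),
                                     fs$depth))
  expect_equal(peak_global_ecc(p0)$global, 0, tolerance = 1e-12)
})

test_that("phase-encoded displacements decode to identical strain", {
  def <- cylinder_deformation(2, 3, 1.8)
  fs <- render_displacements(def, spacing = 0.25, n_frames = 3, ke = 0.5)
  u_dec <- decode_displacement_phase(attr(fs, "phase"), 0.5)
  fs2 <- strain_frame_set(fs$positions, u_dec, fs$center, fs$times,
                         fs$depth)
  g1 <- peak_global_ecc(ecc_profile(fs))$global
  g2 <- peak_global_ecc(ecc_profile(fs2))$global
  expect_equal(g2, g1, tolerance = 1e-6)
})

test_that("CURE spectral arithmetic matches direct DFT results", {
  th <- 2 * pi * (0:7) / 8
  uniform <- matrix(-0.1, 2, 8)
  expect_equal(compute_cure(uniform)$cure, 1)

  first_harmonic <- rbind(cos(th), cos(th))
  expect_equal(compute_cure(first_harmonic, frames = 1:2)$cure, 0)

  # Ecc(theta) = a (1 + cos theta): s0 = a^2 N^2, s1 = (a N / 2)^2 -> 0.8
  mixed <- rbind(0.1 * (1 + cos(th)), 0.1 * (1 + cos(th)))
  expect_equal(compute_cure(mixed, frames = 1:2)$cure, 0.8,
               tolerance = 1e-12)
  # square-root convention: aN / (aN + aN/2) = 2/3
  expect_equal(compute_cure(mixed, frames = 1:2, sqrt_power = TRUE)$cure,
               2 / 3, tolerance = 1e-12)
})

test_that("CURE is bounded and monotone in the dyssynchrony fraction", {
  th <- 2 * pi * (0:23) / 24
  cures <- vapply(seq(0, 3, by = 0.25), function(b) {
    compute_cure(rbind(1 + b * cos(th)), frames = 1)$cure
  }, numeric(1))
  expect_true(all(cures >= 0 & cures <= 1))
  expect_true(all(diff(cures) < 0))

  # random segmental patterns stay inside [0, 1]
  set.seed(2)
  for (i in 1:20) {
    cc <- compute_cure(matrix(rnorm(48), 2, 24), frames = 1:2)$cure
    expect_true(cc >= 0 && cc <= 1)
  }
  expect_error(compute_cure(matrix(0, 2, 24), frames = 1:2), "zero")
  expect_error(compute_cure(matrix(1, 2, 3)), "4 sectors")
})

test_that("CURE defaults to the systolic frames up to peak strain", {
  th <- 2 * pi * (0:7) / 8
  # frames: ramp to peak at frame 3, then relax; post-peak frame is dyssynchronous
  seg <- rbind(rep(-0.05, 8), rep(-0.10, 8), rep(-0.15, 8), 0.05 * cos(th))
  res <- compute_cure(seg)
  expect_equal(res$frames, 1:3)
  expect_equal(res$cure, 1)
})
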