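#' Analytic LV phantom geometries
#'
#' Per-slice endo- and epicardial radii for a stack of short-axis slices,
#' used by [render_lv_masks()]. `lv_annulus_spec()` gives a cylinder
#' (constant radii); `lv_ellipsoid_spec()` tapers the radii towards the apex
#' following a half-ellipsoid profile sampled at slice centers.
#' `incompressible_es_radii()` returns the end-systolic epicardial radius
#' implied by myocardial incompressibility,
#' `r_epi_es^2 = r_epi_ed^2 - r_endo_ed^2 + r_endo_es^2`.
#'
#' @param r_endo,r_epi endocardial and epicardial radii, mm
#'   (`r_epi > r_endo >= 0`).
#' @param n_slices number of short-axis slices.
#' @return A data frame with one row per slice and columns `r_endo`,
#'   `r_epi`.
#' @export
lv_annulus_spec <- function(r_endo, r_epi, n_slices = 1L) {
  check_radii(r_endo, r_epi)
  data.frame(r_endo = rep(r_endo, n_slices), r_epi = rep(r_epi, n_slices))
}

#' @rdname lv_annulus_spec
#' @param length_lv base-to-apex length of the LV, mm; slices are centered
#'   on `n_slices` equal intervals of it.
#' @export
lv_ellipsoid_spec <- function(r_endo, r_epi, length_lv, n_slices = 6L) {
  check_radii(r_endo, r_epi)
  z <- (seq_len(n_slices) - 0.5) / n_slices  # slice centers, 0 = base, 1 = apex
  prof <- sqrt(pmax(1 - z^2, 0))
  data.frame(r_endo = r_endo * prof, r_epi = r_epi * prof)
}

check_radii <- function(r_endo, r_epi) {
  if (any(r_endo < 0) || any(r_epi <= r_endo))
    stop("LV geometry: need r_epi > r_endo >= 0", call. = FALSE)
  invisible(NULL)
}

#' @rdname lv_annulus_spec
#' @param r_endo_ed,r_epi_ed,r_endo_es end-diastolic radii and the
#'   end-systolic endocardial radius, mm.
#' @export
incompressible_es_radii <- function(r_endo_ed, r_epi_ed, r_endo_es) {
  sqrt(r_epi_ed^2 - r_endo_ed^2 + r_endo_es^2)
}

#' Rasterize analytic LV geometry into mask stacks
#'
#' Turns per-phase, per-slice analytic boundary radii into binary endo/epi
#' masks on a pixel grid (a pixel belongs to a mask when its center falls
#' inside the boundary circle) and records the closed-form cavity volume,
#' myocardial volume and wall thickness for oracle comparison.
#'
#' @param phases named list of geometry specs (one per cardiac phase, e.g.
#'   `list(ED = lv_annulus_spec(...), ES = ...)`), each a data frame from
#'   [lv_annulus_spec()] or [lv_ellipsoid_spec()] with equal slice counts.
#' @param pixel_spacing in-plane pixel size, mm (isotropic).
#' @param slice_thickness slice thickness, mm.
#' @param margin_mm image margin beyond the largest epicardial radius, mm.
#' @return An [lv_geometry()] whose `truth` attribute holds analytic
#'   `cavity_volume` (uL), `myo_volume` (mm^3) and `wall_thickness` (mm) per
#'   phase.
#' @export
render_lv_masks <- function(phases, pixel_spacing = 0.1, slice_thickness = 1,
                            margin_mm = 0.5) {
  stopifnot(is.list(phases), length(phases) >= 1L, !is.null(names(phases)))
  for (ph in phases) check_radii(ph$r_endo, ph$r_epi)
  r_max <- max(vapply(phases, function(p) max(p$r_epi), numeric(1)))
  half <- r_max + margin_mm
  n_px <- ceiling(2 * half / pixel_spacing)
  ctr <- (n_px + 1) / 2
  coords <- (seq_len(n_px) - ctr) * pixel_spacing
  rpx <- sqrt(outer(coords^2, coords^2, `+`))

  endo <- list(); epi <- list(); truth <- list()
  for (nm in names(phases)) {
    spec <- phases[[nm]]
    endo[[nm]] <- lapply(seq_len(nrow(spec)),
                         function(s) spec$r_endo[s] > 0 & rpx <= spec$r_endo[s])
    epi[[nm]] <- lapply(seq_len(nrow(spec)),
                        function(s) spec$r_epi[s] > 0 & rpx <= spec$r_epi[s])
    truth[[nm]] <- list(
      cavity_volume = sum(pi * spec$r_endo^2) * slice_thickness,
      myo_volume = sum(pi * (spec$r_epi^2 - spec$r_endo^2)) * slice_thickness,
      wall_thickness = mean(spec$r_epi - spec$r_endo))
  }
  g <- lv_geometry(endo, epi, pixel_spacing = pixel_spacing,
                   slice_thickness = slice_thickness)
  attr(g, "truth") <- truth
  g
}

#' Incompressible cylinder deformation for strain phantoms
#'
#' An area-preserving radial contraction of an annulus: a material point at
#' reference radius `R` moves to `r(R) = sqrt(R^2 - (r_endo_ref^2 -
#' r_endo_def^2))`, so the cross-sectional area between any two material
#' circles is conserved. The circumferential Lagrangian strain of this map
#' has the closed form `Ecc(R) = ((r/R)^2 - 1) / 2`, largest in magnitude at
#' the endocardium and decaying towards the epicardium.
#'
#' @param r_endo_ref,r_epi_ref reference (end-diastolic) endocardial and
#'   epicardial radii, mm.
#' @param r_endo_def deformed endocardial radius, mm (< `r_endo_ref` for
#'   contraction); must keep `r(R)^2 > 0` for all material radii.
#' @param center rotation center, mm (length-2).
#' @return A `cylinder_deformation` object.
#' @export
cylinder_deformation <- function(r_endo_ref, r_epi_ref, r_endo_def,
                                 center = c(0, 0)) {
  check_radii(r_endo_ref, r_epi_ref)
  if (r_endo_def <= 0)
    stop("cylinder_deformation: deformed endocardial radius must be positive ",
         "(the map would otherwise produce negative squared radii)",
         call. = FALSE)
  structure(list(r_endo_ref = r_endo_ref, r_epi_ref = r_epi_ref,
                 r_endo_def = r_endo_def,
                 center = rep_len(as.numeric(center), 2L)),
            class = "cylinder_deformation")
}

# closed-form Ecc of the incompressible cylinder at material radius R,
# for area deficit delta = r_endo_ref^2 - r_endo_def^2
cylinder_ecc <- function(R, delta) -delta / (2 * R^2)

#' Choose a cylinder deformation with a prescribed mean Ecc
#'
#' Because the closed-form Ecc of the incompressible cylinder is linear in
#' the area deficit `delta = r_endo_ref^2 - r_endo_def^2`, the deformed
#' endocardial radius that makes the point-average Ecc over a sampling grid
#' equal a target value has a closed form. Used to build phantoms with a
#' prescribed global peak circumferential strain.
#'
#' @param r_endo_ref,r_epi_ref reference radii, mm.
#' @param target_ecc desired spatial-mean Ecc at full deformation (negative
#'   for contraction).
#' @param spacing grid spacing used for the average, mm.
#' @return A [cylinder_deformation()].
#' @export
cylinder_for_mean_ecc <- function(r_endo_ref, r_epi_ref, target_ecc,
                                  spacing = 0.2) {
  pts <- annulus_grid(r_endo_ref, r_epi_ref, spacing)
  R2 <- rowSums(pts^2)
  delta <- -target_ecc / mean(1 / (2 * R2))
  if (delta >= r_endo_ref^2)
    stop("cylinder_for_mean_ecc: target strain too large for this annulus",
         call. = FALSE)
  cylinder_deformation(r_endo_ref, r_epi_ref, sqrt(r_endo_ref^2 - delta))
}

annulus_grid <- function(r_in, r_out, spacing) {
  g <- seq(-r_out, r_out, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g))
  R <- sqrt(rowSums(pts^2))
  pts[R >= r_in & R <= r_out, , drop = FALSE]
}

#' Render DENSE-style displacement fields from a cylinder deformation
#'
#' Samples material points on a regular grid inside the reference annulus
#' and produces, for each cardiac frame, the in-plane displacement of the
#' incompressible radial map interpolated from the identity (frame 1) to the
#' full deformation (last frame). The closed-form Ecc at every point and
#' frame is recorded as ground truth. Optionally the displacements can be
#' expressed as DENSE phases `phi = 2 pi ke u`, valid only while `|phi| <
#' pi` (no phase wrapping; unwrapping is out of scope).
#'
#' @param def a [cylinder_deformation()].
#' @param spacing material-point spacing, mm.
#' @param n_frames number of frames (frame 1 is the undeformed reference).
#' @param frame_interval frame spacing, seconds.
#' @param ke optional displacement-encoding frequency, cycles/mm; when given
#'   the returned object carries encoded phases and an error is raised if
#'   any phase would wrap.
#' @return A [strain_frame_set()] with a `truth` attribute holding the
#'   closed-form per-point Ecc for every frame (`ecc`, points x frames
#'   matrix) and the per-frame area deficit.
#' @export
render_displacements <- function(def, spacing = 0.2, n_frames = 5,
                                 frame_interval = 0.02, ke = NULL) {
  stopifnot(inherits(def, "cylinder_deformation"))
  X <- sweep(annulus_grid(def$r_endo_ref, def$r_epi_ref, spacing), 2,
             def$center, `+`)
  Xc <- sweep(X, 2, def$center)                # coordinates about the center
  R <- sqrt(rowSums(Xc^2))
  npt <- nrow(X)
  delta_full <- def$r_endo_ref^2 - def$r_endo_def^2
  frac <- if (n_frames == 1L) 1 else (seq_len(n_frames) - 1) / (n_frames - 1)
  # interpolate the endocardial radius, not the deficit, so intermediate
  # frames are themselves valid incompressible maps of the same family
  r_endo_t <- def$r_endo_ref + frac * (def$r_endo_def - def$r_endo_ref)
  delta_t <- def$r_endo_ref^2 - r_endo_t^2

  U <- array(0, dim = c(npt, 2L, n_frames))
  ecc_truth <- matrix(0, npt, n_frames)
  e_r <- Xc / R
  for (k in seq_len(n_frames)) {
    r2 <- R^2 - delta_t[k]
    if (any(r2 <= 0))
      stop("render_displacements: deformation drives squared radius negative",
           call. = FALSE)
    r <- sqrt(r2)
    U[, , k] <- e_r * (r - R)
    ecc_truth[, k] <- cylinder_ecc(R, delta_t[k])
  }
  depth <- (R - def$r_endo_ref) / (def$r_epi_ref - def$r_endo_ref)
  fs <- strain_frame_set(positions = X, displacements = U,
                         center = def$center,
                         times = (seq_len(n_frames) - 1) * frame_interval,
                         depth = depth)
  if (!is.null(ke)) {
    phi <- encode_displacement_phase(U, ke)
    attr(fs, "phase") <- phi
    attr(fs, "ke") <- ke
  }
  attr(fs, "truth") <- list(ecc = ecc_truth, delta = delta_t,
                            deformation = def)
  fs
}

#' DENSE phase/displacement mapping (no wrapping)
#'
#' DENSE encodes tissue displacement `u` (mm) in signal phase
#' `phi = 2 pi ke u` with encoding frequency `ke` (cycles/mm). Only the
#' wrap-free regime `|phi| < pi` is supported: encoding fails loudly if any
#' phase would alias, and decoding is the exact inverse `u = phi / (2 pi
#' ke)`.
#'
#' @param u displacements, mm (any numeric array).
#' @param ke encoding frequency, cycles/mm, positive.
#' @return Phases in radians (`encode`) or displacements in mm (`decode`),
#'   same shape as the input.
#' @export
encode_displacement_phase <- function(u, ke) {
  if (!is.numeric(ke) || ke <= 0)
    stop("ke must be a positive encoding frequency (cycles/mm)", call. = FALSE)
  phi <- 2 * pi * ke * u
  if (any(abs(phi) >= pi))
    stop("encode_displacement_phase: |phase| >= pi would wrap; ",
         "reduce ke or the displacement", call. = FALSE)
  phi
}

#' @rdname encode_displacement_phase
#' @param phi encoded phases, radians.
#' @export
decode_displacement_phase <- function(phi, ke) {
  if (!is.numeric(ke) || ke <= 0)
    stop("ke must be a positive encoding frequency (cycles/mm)", call. = FALSE)
  phi / (2 * pi * ke)
}
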