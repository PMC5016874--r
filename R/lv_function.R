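#' Multi-slice, multi-phase LV mask geometry
#'
#' Container for endo- and epicardial binary masks across short-axis slices
#' and cardiac phases, plus pixel geometry. The endocardial mask must be
#' contained in the epicardial mask for every slice and phase.
#'
#' @param endo,epi named lists (one element per phase, e.g. `"ED"`, `"ES"`),
#'   each a list of logical matrices (one per slice).
#' @param pixel_spacing in-plane pixel size, mm (isotropic).
#' @param slice_thickness slice thickness, mm.
#' @return An `lv_geometry` object.
#' @export
lv_geometry <- function(endo, epi, pixel_spacing, slice_thickness) {
  stopifnot(is.list(endo), is.list(epi))
  if (!identical(names(endo), names(epi)))
    stop("lv_geometry: endo and epi phases differ", call. = FALSE)
  if (pixel_spacing <= 0 || slice_thickness <= 0)
    stop("lv_geometry: pixel geometry must be positive", call. = FALSE)
  for (ph in names(endo)) {
    if (length(endo[[ph]]) != length(epi[[ph]]))
      stop("lv_geometry: slice counts differ in phase ", ph, call. = FALSE)
    for (s in seq_along(endo[[ph]])) {
      en <- endo[[ph]][[s]]; ep <- epi[[ph]][[s]]
      if (any(en & !ep))
        stop("lv_geometry: endocardial mask not contained in epicardial ",
             "mask (phase ", ph, ", slice ", s, ")", call. = FALSE)
    }
  }
  structure(list(endo = endo, epi = epi, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, phases = names(endo)),
            class = "lv_geometry")
}

get_phase <- function(geom, phase) {
  if (!phase %in% geom$phases)
    stop("phase '", phase, "' not present (have: ",
         paste(geom$phases, collapse = ", "), ")", call. = FALSE)
  phase
}

#' LV cavity volume by slice summation
#'
#' Sums endocardial pixel counts over slices: `volume = sum(n_px) * pixel
#' area * slice thickness` in mm^3, reported as uL (1 mm^3 = 1 uL).
#'
#' @param geom an [lv_geometry()].
#' @param phase phase label (e.g. `"ED"`).
#' @return Cavity volume, uL.
#' @export
cavity_volume <- function(geom, phase) {
  stopifnot(inherits(geom, "lv_geometry"))
  phase <- get_phase(geom, phase)
  n <- sum(vapply(geom$endo[[phase]], sum, numeric(1)))
  n * geom$pixel_spacing^2 * geom$slice_thickness
}

#' Ejection fraction
#'
#' `EF = 100 (EDV - ESV) / EDV`, percent.
#'
#' @param edv,esv end-diastolic and end-systolic cavity volumes, uL;
#'   `edv > 0`.
#' @return Ejection fraction, percent.
#' @examples
#' ejection_fraction(43, 17)   # 60.5 %
#' @export
ejection_fraction <- function(edv, esv) {
  if (!(edv > 0)) stop("ejection_fraction: EDV must be positive",
                       call. = FALSE)
  100 * (edv - esv) / edv
}

#' LV mass by slice summation
#'
#' Myocardial volume (epicardial minus endocardial pixel counts, times pixel
#' area and slice thickness) converted to mass with a myocardial density of
#' 1.05 mg/mm^3.
#'
#' @inheritParams cavity_volume
#' @param rho_myo myocardial density, mg/mm^3.
#' @return LV mass, mg.
#' @export
lv_mass <- function(geom, phase, rho_myo = 1.05) {
  stopifnot(inherits(geom, "lv_geometry"))
  phase <- get_phase(geom, phase)
  n_myo <- sum(vapply(seq_along(geom$epi[[phase]]), function(s)
    sum(geom$epi[[phase]][[s]]) - sum(geom$endo[[phase]][[s]]), numeric(1)))
  n_myo * geom$pixel_spacing^2 * geom$slice_thickness * rho_myo
}

#' Sector-based LV wall thickness
#'
#' Divides each slice into angular sectors about the cavity centroid and
#' estimates, per sector, the endo- and epicardial boundary radii from the
#' enclosed sector areas (radius `sqrt(2 A / dtheta)`, exact for circular
#' wedges and robust to rasterization); thickness is their difference.
#' Sectors without myocardium are dropped with a warning; if more than half
#' are dropped the measurement fails.
#'
#' @inheritParams cavity_volume
#' @param n_sectors number of angular sectors (>= 8).
#' @param slices slice indices to measure (default: all).
#' @return Mean wall thickness, mm, with attribute `"sectors"` holding the
#'   per-slice, per-sector thickness matrix.
#' @export
wall_thickness <- function(geom, phase, n_sectors = 24, slices = NULL) {
  stopifnot(inherits(geom, "lv_geometry"))
  phase <- get_phase(geom, phase)
  if (n_sectors < 8) stop("wall_thickness: n_sectors must be >= 8",
                          call. = FALSE)
  if (is.null(slices)) slices <- seq_along(geom$endo[[phase]])
  dtheta <- 2 * pi / n_sectors
  parea <- geom$pixel_spacing^2
  th <- matrix(NA_real_, length(slices), n_sectors)
  for (si in seq_along(slices)) {
    s <- slices[si]
    en <- geom$endo[[phase]][[s]]; ep <- geom$epi[[phase]][[s]]
    if (!any(ep)) next
    idx_ref <- if (any(en)) which(en, arr.ind = TRUE) else
      which(ep, arr.ind = TRUE)
    ctr <- colMeans(idx_ref)
    sector_of <- function(mask) {
      idx <- which(mask, arr.ind = TRUE)
      ang <- atan2(idx[, 2] - ctr[2], idx[, 1] - ctr[1])
      pmin(floor((ang + pi) / dtheta) + 1L, n_sectors)
    }
    a_en <- tabulate(sector_of(en), n_sectors) * parea
    a_ep <- tabulate(sector_of(ep), n_sectors) * parea
    ok <- a_ep > a_en & a_ep > 0
    if (any(!ok))
      warning(sum(!ok), " sector(s) without myocardium dropped (phase ",
              phase, ", slice ", s, ")", call. = FALSE)
    th[si, ok] <- sqrt(2 * a_ep[ok] / dtheta) - sqrt(2 * a_en[ok] / dtheta)
  }
  if (mean(is.na(th)) > 0.5)
    stop("wall_thickness: more than half of all sectors degenerate",
         call. = FALSE)
  structure(mean(th, na.rm = TRUE), sectors = th)
}

#' Identify ED and ES phases by cavity volume
#'
#' Optional helper: end-diastole is the phase of maximum cavity volume,
#' end-systole the minimum.
#'
#' @param geom an [lv_geometry()].
#' @return Named character vector `c(ed = ..., es = ...)`.
#' @export
pick_ed_es <- function(geom) {
  vols <- vapply(geom$phases, function(p) cavity_volume(geom, p), numeric(1))
  c(ed = geom$phases[which.max(vols)], es = geom$phases[which.min(vols)])
}

#' All LV volumetric and geometric indices
#'
#' Computes EDV, ESV, EF, LV mass (at end-diastole) and mean end-diastolic
#' and end-systolic wall thickness from an [lv_geometry()]. ED and ES phases
#' are caller-identified by label.
#'
#' @param geom an [lv_geometry()].
#' @param ed,es phase labels of end-diastole and end-systole.
#' @param rho_myo myocardial density, mg/mm^3.
#' @param n_sectors sectors for [wall_thickness()].
#' @return One-row data frame with columns `edv`, `esv`, `ef`, `mass`,
#'   `edwt`, `eswt` (uL, uL, %, mg, mm, mm).
#' @export
lv_indices <- function(geom, ed = "ED", es = "ES", rho_myo = 1.05,
                       n_sectors = 24) {
  edv <- cavity_volume(geom, ed)
  esv <- cavity_volume(geom, es)
  data.frame(edv = edv, esv = esv,
             ef = ejection_fraction(edv, esv),
             mass = lv_mass(geom, ed, rho_myo = rho_myo),
             edwt = as.numeric(wall_thickness(geom, ed, n_sectors)),
             eswt = as.numeric(wall_thickness(geom, es, n_sectors)))
}
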