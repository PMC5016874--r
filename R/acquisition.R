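#' Acquisition parameters for dual-contrast first-pass imaging
#'
#' Bundles the sequence timing and geometry that govern both the forward
#' (phantom) and inverse (quantification) signal models. Defaults follow a
#' typical 7T mouse dual-contrast first-pass protocol: TE/TR = 1.2/2.1 ms,
#' flip angle 15 degrees, saturation delay 15 ms for the arterial-input (AIF)
#' slice and 57 ms for the tissue-function (TF) slice, 200 x 250 um in-plane
#' resolution, 1 mm slices, and one image per heartbeat at 500 bpm
#' (frame interval 0.12 s).
#'
#' @param tr repetition time, seconds.
#' @param te echo time, seconds.
#' @param flip_angle excitation flip angle, degrees, in (0, 90].
#' @param td_aif saturation delay of the AIF (blood-pool) slice, seconds.
#'   Must be shorter than `td_tf`: the short delay keeps the blood signal in
#'   its linear range during the bolus.
#' @param td_tf saturation delay of the TF (myocardial) slice, seconds.
#' @param frame_interval time between frames (one frame per heartbeat),
#'   seconds.
#' @param n_frames number of frames in the dynamic series.
#' @param pixel_spacing in-plane pixel spacing, mm, length-2 vector
#'   (row, column).
#' @param slice_thickness slice thickness, mm.
#'
#' @return An object of class `acq_params` (a validated list).
#' @examples
#' acq <- acq_params()
#' frame_times(acq)[1:5]
#' @export
acq_params <- function(tr = 0.0021, te = 0.0012, flip_angle = 15,
                       td_aif = 0.015, td_tf = 0.057,
                       frame_interval = 0.12, n_frames = 50,
                       pixel_spacing = c(0.2, 0.25), slice_thickness = 1) {
  p <- list(tr = tr, te = te, flip_angle = flip_angle,
            td_aif = td_aif, td_tf = td_tf,
            frame_interval = frame_interval, n_frames = as.integer(n_frames),
            pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
            slice_thickness = slice_thickness)
  validate_acq_params(p)
  structure(p, class = "acq_params")
}

validate_acq_params <- function(p) {
  scalars <- c("tr", "te", "flip_angle", "td_aif", "td_tf",
               "frame_interval", "n_frames", "slice_thickness")
  for (f in scalars) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("acq_params: field '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (any(!is.finite(p$pixel_spacing)) || any(p$pixel_spacing <= 0))
    stop("acq_params: 'pixel_spacing' must be positive", call. = FALSE)
  if (p$td_aif >= p$td_tf)
    stop("acq_params: td_aif must be shorter than td_tf ",
         "(short-delay slice samples blood, long-delay slice samples tissue)",
         call. = FALSE)
  if (p$flip_angle > 90)
    stop("acq_params: flip_angle must lie in (0, 90] degrees", call. = FALSE)
  invisible(p)
}

#' @rdname acq_params
#' @param acq an `acq_params` object.
#' @return `frame_times()`: numeric vector of frame acquisition times,
#'   seconds, starting at 0.
#' @export
frame_times <- function(acq) {
  (seq_len(acq$n_frames) - 1) * acq$frame_interval
}

#' @export
print.acq_params <- function(x, ...) {
  cat("Acquisition parameters\n")
  cat(sprintf("  TE/TR             : %.3g/%.3g ms\n", x$te * 1e3, x$tr * 1e3))
  cat(sprintf("  flip angle        : %g deg\n", x$flip_angle))
  cat(sprintf("  saturation delays : AIF %g ms, TF %g ms\n",
              x$td_aif * 1e3, x$td_tf * 1e3))
  cat(sprintf("  frames            : %d @ %g s (%.0f bpm)\n",
              x$n_frames, x$frame_interval, 60 / x$frame_interval))
  cat(sprintf("  pixels            : %g x %g mm, slice %g mm\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$slice_thickness))
  invisible(x)
}

acq_sidecar_fields <- c("tr", "te", "flip_angle", "td_aif", "td_tf",
                        "frame_interval", "n_frames", "pixel_spacing",
                        "slice_thickness")

#' Read and write acquisition sidecar files
#'
#' Acquisition parameters travel with image stacks as a JSON sidecar. The
#' reader validates the schema and reports missing or malformed fields by
#' name; the writer emits full double precision so that a write/read round
#' trip is lossless.
#'
#' @param path path to a JSON sidecar file.
#' @return `read_image_sidecar()`: an [acq_params()] object.
#' @export
read_image_sidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(acq_sidecar_fields, names(raw))
  if (length(missing))
    stop("sidecar ", path, " missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(acq_params, raw[acq_sidecar_fields])
}

#' @rdname read_image_sidecar
#' @param acq an `acq_params` object.
#' @export
write_image_sidecar <- function(acq, path) {
  stopifnot(inherits(acq, "acq_params"))
  jsonlite::write_json(unclass(acq)[acq_sidecar_fields], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
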