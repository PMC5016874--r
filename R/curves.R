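#' Signal and concentration time series
#'
#' Two light containers shared by the forward (phantom) and inverse
#' (quantification) models. A `signal_series` holds per-frame ROI-mean signal
#' (dimensionless once proton-density normalized) together with the
#' saturation delay that applies to it; a `conc_curve` holds the
#' concentration proxy Delta-R1 = 1/T1 - 1/T1_0 in 1/s. Contrast-agent
#' relaxivity is never applied: it cancels in the AIF/TF ratio that the
#' Fermi deconvolution uses.
#'
#' @param times frame times, seconds, strictly increasing.
#' @param values per-frame values (signal or Delta-R1).
#' @param td saturation delay applicable to this series, seconds.
#' @param role `"blood"` (AIF) or `"tissue"` (TF).
#' @param normalized logical: has the series been proton-density normalized?
#' @return `signal_series` or `conc_curve` object.
#' @export
signal_series <- function(times, values, td, role = c("tissue", "blood"),
                          normalized = TRUE) {
  role <- match.arg(role)
  check_times(times, strict = TRUE)
  if (length(values) != length(times))
    stop("signal_series: times and values differ in length", call. = FALSE)
  if (!is.numeric(td) || length(td) != 1L || td <= 0)
    stop("signal_series: td must be a single positive number", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 td = td, role = role, normalized = normalized),
            class = "signal_series")
}

#' @rdname signal_series
#' @param delta_r1 change in longitudinal relaxation rate, 1/s.
#' @export
conc_curve <- function(times, delta_r1) {
  check_times(times, strict = FALSE)
  if (length(delta_r1) != length(times))
    stop("conc_curve: times and delta_r1 differ in length", call. = FALSE)
  structure(list(times = as.numeric(times), delta_r1 = as.numeric(delta_r1)),
            class = "conc_curve")
}

check_times <- function(times, strict = FALSE) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop("times must be finite numeric", call. = FALSE)
  d <- diff(times)
  if (strict && any(d <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (!strict && any(d < 0))
    stop("times must be nondecreasing", call. = FALSE)
  invisible(times)
}

# uniform frame spacing, or error; returns dt
uniform_dt <- function(times, tol = 1e-8) {
  d <- diff(times)
  if (length(d) == 0L) stop("need at least two frames", call. = FALSE)
  dt <- mean(d)
  if (any(abs(d - dt) > tol * max(dt, 1)))
    stop("frames are not uniformly sampled", call. = FALSE)
  dt
}

#' @export
print.signal_series <- function(x, ...) {
  cat(sprintf("Signal series (%s, TD = %g ms): %d frames, range [%.4g, %.4g]\n",
              x$role, x$td * 1e3, length(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.conc_curve <- function(x, ...) {
  cat(sprintf("Concentration curve (Delta-R1): %d frames, peak %.4g 1/s\n",
              length(x$times), max(x$delta_r1)))
  invisible(x)
}
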