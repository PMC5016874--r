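#' Fermi impulse-response parameters
#'
#' The tissue impulse response used by constrained (Fermi-function)
#' deconvolution of first-pass curves:
#' \deqn{h(t) = A / (1 + \exp(k (t - d - \tau)))\ \textrm{for}\ t \ge d,
#'       \quad h(t) = 0\ \textrm{for}\ t < d,}
#' with amplitude `A` (1/s), decay rate `k` (1/s), width `tau` (s) and
#' bolus-arrival delay `d` (s). The flow-defining value is the height of the
#' response just after arrival, `h(d+) = A / (1 + exp(-k tau))`; myocardial
#' blood flow is `h(d+) * 60 / rho_tissue` in mL/min/g.
#'
#' @param amplitude `A`, 1/s, nonnegative.
#' @param decay `k`, 1/s, nonnegative (0 gives a constant kernel of height
#'   `A/2`).
#' @param width `tau`, seconds, nonnegative.
#' @param delay `d`, seconds, nonnegative.
#' @return A `fermi_params` object.
#' @examples
#' h <- fermi_params(amplitude = 0.1, decay = 1.5, width = 1.2)
#' fermi_h0(h) * 60 / 1.05   # implied flow in mL/min/g
#' @export
fermi_params <- function(amplitude, decay, width, delay = 0) {
  v <- c(amplitude = amplitude, decay = decay, width = width, delay = delay)
  if (any(!is.finite(v)) || any(v < 0))
    stop("fermi_params: amplitude, decay, width and delay must be finite and >= 0",
         call. = FALSE)
  structure(as.list(v), class = "fermi_params")
}

#' @rdname fermi_params
#' @param fermi a `fermi_params` object.
#' @param t times at which to evaluate the impulse response, seconds.
#' @return `fermi_impulse()`: h(t); `fermi_h0()`: the post-arrival height
#'   h(d+).
#' @export
fermi_impulse <- function(fermi, t) {
  # plogis keeps the logistic tail numerically stable for large k*(t - d - tau)
  h <- fermi$amplitude * plogis(-fermi$decay * (t - fermi$delay - fermi$width))
  h[t < fermi$delay] <- 0
  h
}

#' @rdname fermi_params
#' @export
fermi_h0 <- function(fermi) {
  fermi$amplitude * plogis(fermi$decay * fermi$width)
}

#' @export
print.fermi_params <- function(x, ...) {
  cat(sprintf(
    "Fermi impulse response: A = %.4g 1/s, k = %.4g 1/s, tau = %.4g s, d = %.4g s (h(d+) = %.4g 1/s)\n",
    x$amplitude, x$decay, x$width, x$delay, fermi_h0(x)))
  invisible(x)
}

# Discrete causal convolution on a uniform grid with trapezoidal quadrature:
# out[i] = dt * integral_0^{t_i} a(s) h(t_i - s) ds.
conv_trapz <- function(a, h, dt) {
  n <- length(a)
  stopifnot(length(h) == n)
  out <- numeric(n)
  if (n < 2L) return(out)
  for (i in 2:n) {
    j <- seq_len(i)
    p <- a[j] * h[i - j + 1L]
    out[i] <- dt * (sum(p) - 0.5 * (p[1L] + p[i]))
  }
  out
}

#' Forward tissue curve from an AIF and a Fermi impulse response
#'
#' Computes the discrete causal convolution
#' `c_tis(t) = dt * (aif (*) h_fermi)(t)` with trapezoidal quadrature on the
#' frame grid. This is the forward model inverted by [fermi_deconvolve()];
#' the phantom generator uses it to label tissue curves with known flow.
#'
#' @param aif_curve a [conc_curve()] sampled on a uniform grid.
#' @param fermi a [fermi_params()] object.
#' @return A [conc_curve()] with the tissue Delta-R1 values.
#' @export
tissue_curve_from_fermi <- function(aif_curve, fermi) {
  stopifnot(inherits(aif_curve, "conc_curve"), inherits(fermi, "fermi_params"))
  dt <- uniform_dt(aif_curve$times)
  h <- fermi_impulse(fermi, aif_curve$times - aif_curve$times[1L])
  conc_curve(aif_curve$times, conv_trapz(aif_curve$delta_r1, h, dt))
}
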