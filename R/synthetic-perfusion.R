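#' Gamma-variate arterial input function
#'
#' Parameters of the normalized gamma-variate bolus model used for synthetic
#' arterial input functions (AIFs):
#' \deqn{c(t) = c_{peak} \left(\frac{t - t_0}{t_{peak} - t_0}\right)^{\alpha}
#'       \exp\left(\alpha \left(1 - \frac{t - t_0}{t_{peak} - t_0}\right)\right)}
#' for `t > t0` and 0 before bolus arrival; the curve attains its maximum
#' `c_peak` exactly at `t_peak`. An optional recirculation bump (a scaled,
#' delayed copy of the first pass) is off by default.
#'
#' @param t0 bolus arrival time, seconds.
#' @param t_peak time of peak concentration, seconds; must exceed `t0`.
#' @param c_peak peak Delta-R1, 1/s, positive.
#' @param alpha dimensionless shape parameter, positive.
#' @param recirc_frac fraction of `c_peak` recirculating (0 disables).
#' @param recirc_delay delay of the recirculation bump, seconds.
#' @return An `aif_params` object.
#' @export
aif_params <- function(t0 = 0.96, t_peak = 2.16, c_peak = 6, alpha = 2.5,
                       recirc_frac = 0, recirc_delay = 3) {
  if (t_peak <= t0) stop("aif_params: t_peak must exceed t0", call. = FALSE)
  if (c_peak <= 0 || alpha <= 0)
    stop("aif_params: c_peak and alpha must be positive", call. = FALSE)
  if (recirc_frac < 0 || recirc_frac >= 1 || recirc_delay <= 0)
    stop("aif_params: recirc_frac in [0,1) and recirc_delay > 0", call. = FALSE)
  structure(list(t0 = t0, t_peak = t_peak, c_peak = c_peak, alpha = alpha,
                 recirc_frac = recirc_frac, recirc_delay = recirc_delay),
            class = "aif_params")
}

gamma_variate_value <- function(t, t0, t_peak, c_peak, alpha) {
  x <- (t - t0) / (t_peak - t0)
  v <- ifelse(x > 0, c_peak * x^alpha * exp(alpha * (1 - x)), 0)
  v
}

#' Evaluate a gamma-variate AIF on a time grid
#'
#' @param aif an [aif_params()] object.
#' @param times sampling times, seconds, nondecreasing.
#' @return A [conc_curve()] with the AIF Delta-R1 values.
#' @examples
#' aif <- aif_params(t0 = 1, t_peak = 3, c_peak = 1, alpha = 2)
#' gamma_variate_aif(aif, c(1, 3, 5))$delta_r1   # 0, 1, 4 exp(-2)
#' @export
gamma_variate_aif <- function(aif, times) {
  stopifnot(inherits(aif, "aif_params"))
  check_times(times, strict = FALSE)
  v <- gamma_variate_value(times, aif$t0, aif$t_peak, aif$c_peak, aif$alpha)
  if (aif$recirc_frac > 0)
    v <- v + aif$recirc_frac *
      gamma_variate_value(times, aif$t0 + aif$recirc_delay,
                          aif$t_peak + aif$recirc_delay,
                          aif$c_peak, aif$alpha)
  conc_curve(times, v)
}

#' Saturation-recovery signal from a concentration curve
#'
#' Forward signal model of the dual-contrast sequence. Concentration acts on
#' the longitudinal relaxation rate, `1/T1(t) = 1/T1_0 + Delta-R1(t)`, and
#' the (proton-density normalized) saturation-recovery signal is
#' `s(t) = 1 - exp(-TD / T1(t))` with TD the saturation delay of the slice
#' (`td_aif` for blood, `td_tf` for tissue). Optional zero-mean Gaussian
#' noise is added on the normalized signal.
#'
#' @param curve a [conc_curve()] with nonnegative Delta-R1 values.
#' @param acq an [acq_params()] object supplying the saturation delays.
#' @param t1_0 pre-contrast T1, seconds (1.55 s blood, 1.45 s myocardium by
#'   convention).
#' @param role `"blood"` (uses `td_aif`) or `"tissue"` (uses `td_tf`).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   normalized signal (0 for noiseless).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (and left advanced).
#' @return A [signal_series()].
#' @export
concentration_to_signal <- function(curve, acq, t1_0,
                                    role = c("tissue", "blood"),
                                    noise_sd = 0, seed = NULL) {
  stopifnot(inherits(curve, "conc_curve"), inherits(acq, "acq_params"))
  role <- match.arg(role)
  if (!is.numeric(t1_0) || t1_0 <= 0)
    stop("concentration_to_signal: t1_0 must be positive", call. = FALSE)
  if (any(curve$delta_r1 < 0))
    stop("concentration_to_signal: Delta-R1 values must be >= 0", call. = FALSE)
  td <- if (role == "blood") acq$td_aif else acq$td_tf
  s <- sr_signal(curve$delta_r1, t1_0, td)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + rnorm(length(s), sd = noise_sd)
  }
  signal_series(curve$times, s, td = td, role = role)
}

sr_signal <- function(delta_r1, t1_0, td) {
  t1 <- 1 / (1 / t1_0 + delta_r1)
  1 - exp(-td / t1)
}

#' Phantom ground truth for rest/stress perfusion
#'
#' Describes a digital perfusion phantom: true rest and stress myocardial
#' blood flow, pre-contrast T1s, per-pixel noise level on the normalized
#' signal, and the seed that makes rendering reproducible. Defaults mimic a
#' healthy mouse: rest flow 4 mL/min/g, stress flow 10 mL/min/g, i.e. a
#' myocardial perfusion reserve (MPR) of 2.5.
#'
#' @param mbf_rest,mbf_stress true myocardial blood flow at rest and stress,
#'   mL/min/g; `mbf_stress >= mbf_rest > 0`.
#' @param t1_blood0,t1_myo0 pre-contrast T1 of blood and myocardium, seconds.
#' @param noise_sd per-pixel Gaussian noise SD on the normalized signal.
#' @param seed integer seed used by [render_perfusion_series()].
#' @return A `perfusion_phantom` object; `$mpr` holds the implied reserve.
#' @export
perfusion_phantom <- function(mbf_rest = 4, mbf_stress = 10,
                              t1_blood0 = 1.55, t1_myo0 = 1.45,
                              noise_sd = 0, seed = 1L) {
  if (!(mbf_rest > 0) || mbf_stress < mbf_rest)
    stop("perfusion_phantom: need mbf_stress >= mbf_rest > 0", call. = FALSE)
  if (t1_blood0 <= 0 || t1_myo0 <= 0)
    stop("perfusion_phantom: T1 values must be positive", call. = FALSE)
  if (noise_sd < 0)
    stop("perfusion_phantom: noise_sd must be >= 0", call. = FALSE)
  structure(list(mbf_rest = mbf_rest, mbf_stress = mbf_stress,
                 t1_blood0 = t1_blood0, t1_myo0 = t1_myo0,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 mpr = mbf_stress / mbf_rest),
            class = "perfusion_phantom")
}

# Fermi parameters whose post-arrival height encodes the requested flow.
fermi_for_mbf <- function(mbf, decay = 1.5, width = 1.2, delay = 0,
                          rho_tissue = 1.05) {
  h0 <- mbf * rho_tissue / 60
  fermi_params(amplitude = h0 / plogis(decay * width),
               decay = decay, width = width, delay = delay)
}

#' Render a dual-contrast first-pass phantom image series
#'
#' Rasterizes the forward signal model into two small dynamic image stacks:
#' an AIF slice whose blood-pool disc follows the blood signal curve and a TF
#' slice whose myocardial annulus follows the tissue curve, each for rest and
#' stress. Matching 0/1 ROI masks, the acquisition sidecar, the gamma-variate
#' AIF and the closed-form ground-truth curves are carried alongside so that
#' every downstream stage can be checked against known truth. Rendering is
#' deterministic given the phantom seed.
#'
#' @param phantom a [perfusion_phantom()].
#' @param acq an [acq_params()].
#' @param aif an [aif_params()] describing the bolus (same shape at rest and
#'   stress; only the tissue response changes with flow).
#' @param fermi_shape decay (1/s) and width (s) of the true Fermi response;
#'   the amplitude is set from the phantom flows.
#' @param pd_value proton-density reference intensity: rendered pixel values
#'   are `pd_value * (signal + noise)` and must be divided back out with
#'   [normalize_by_pd()].
#' @param n_pixels image matrix size (square).
#' @return A `perfusion_series` object: for each condition (`rest`,
#'   `stress`) an `aif_stack` and `tf_stack` (x, y, frame arrays), plus
#'   `blood_mask`, `myo_mask`, `acq`, `pd_value`, and a `truth` record with
#'   the generating curves, Fermi parameters and flows.
#' @export
render_perfusion_series <- function(phantom, acq = acq_params(),
                                    aif = aif_params(),
                                    fermi_shape = list(decay = 1.5, width = 1.2),
                                    pd_value = 1, n_pixels = 64) {
  stopifnot(inherits(phantom, "perfusion_phantom"))
  set.seed(phantom$seed)
  times <- frame_times(acq)
  aif_curve <- gamma_variate_aif(aif, times)

  # disc blood pool in the AIF slice, annulus myocardium in the TF slice
  ctr <- (n_pixels + 1) / 2
  xy <- expand.grid(x = seq_len(n_pixels), y = seq_len(n_pixels))
  rpx <- sqrt((xy$x - ctr)^2 + (xy$y - ctr)^2)
  blood_mask <- matrix(rpx <= n_pixels / 6, n_pixels, n_pixels)
  myo_mask <- matrix(rpx > n_pixels / 6 & rpx <= n_pixels / 4,
                     n_pixels, n_pixels)

  render_one <- function(mbf) {
    fer <- fermi_for_mbf(mbf, decay = fermi_shape$decay,
                         width = fermi_shape$width)
    tf_curve <- tissue_curve_from_fermi(aif_curve, fer)
    s_blood <- sr_signal(aif_curve$delta_r1, phantom$t1_blood0, acq$td_aif)
    s_tis <- sr_signal(tf_curve$delta_r1, phantom$t1_myo0, acq$td_tf)
    nfr <- length(times)
    mk_stack <- function(sig, mask) {
      stack <- array(0, dim = c(n_pixels, n_pixels, nfr))
      for (k in seq_len(nfr)) stack[, , k][mask] <- sig[k]
      if (phantom$noise_sd > 0)
        stack <- stack + array(rnorm(length(stack), sd = phantom$noise_sd),
                               dim = dim(stack))
      pd_value * stack
    }
    list(aif_stack = mk_stack(s_blood, blood_mask),
         tf_stack = mk_stack(s_tis, myo_mask),
         fermi = fer, aif_curve = aif_curve, tf_curve = tf_curve,
         s_blood = s_blood, s_tissue = s_tis)
  }

  rest <- render_one(phantom$mbf_rest)
  stress <- render_one(phantom$mbf_stress)
  structure(list(
    rest = rest[c("aif_stack", "tf_stack")],
    stress = stress[c("aif_stack", "tf_stack")],
    blood_mask = blood_mask, myo_mask = myo_mask,
    acq = acq, pd_value = pd_value,
    truth = list(phantom = phantom, aif = aif,
                 fermi_rest = rest$fermi, fermi_stress = stress$fermi,
                 curves = list(rest = list(aif = rest$aif_curve,
                                           tf = rest$tf_curve,
                                           s_blood = rest$s_blood,
                                           s_tissue = rest$s_tissue),
                               stress = list(aif = stress$aif_curve,
                                             tf = stress$tf_curve,
                                             s_blood = stress$s_blood,
                                             s_tissue = stress$s_tissue)))),
    class = "perfusion_series")
}
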