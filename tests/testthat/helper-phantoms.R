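# Shared fixtures: everything is generated in code at test time.

default_times <- function(acq = acq_params()) frame_times(acq)

# run the full image-level perfusion pipeline on a rendered phantom and
# return the MPR result
analyze_rendered_mpr <- function(ser, t1_blood0 = 1.55, t1_myo0 = 1.45) {
  acq <- ser$acq
  times <- frame_times(acq)
  one <- function(cond) {
    aif_raw <- extract_roi_curve(ser[[cond]]$aif_stack, ser$blood_mask,
                                 times, acq$td_aif, role = "blood")
    tf_raw <- extract_roi_curve(ser[[cond]]$tf_stack, ser$myo_mask,
                                times, acq$td_tf, role = "tissue")
    aif_n <- normalize_by_pd(aif_raw, ser$pd_value)
    base <- seq_len(detect_bolus_arrival(aif_n$values) - 1L)
    aif <- series_to_delta_r1(aif_n, t1_blood0, baseline_frames = base)
    tf <- series_to_delta_r1(normalize_by_pd(tf_raw, ser$pd_value), t1_myo0,
                             baseline_frames = base)
    fermi_deconvolve(aif, tf, condition = cond)
  }
  compute_mpr(one("rest"), one("stress"))
}

# rigid-motion displacement field on a point set
rigid_field <- function(points, theta = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  sweep(points %*% t(R), 2, shift, `+`) - points
}
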