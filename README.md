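# mprkit

Quantitative analysis of preclinical (mouse) cardiac MRI studies in R:
first-pass **perfusion** by Fermi-function deconvolution with rest/stress
**myocardial perfusion reserve (MPR)**, cine **LV volumetry** (EDV, ESV,
EF, mass, wall thickness), DENSE-style **circumferential strain** with the
**CURE** synchrony index, and **glucose-tolerance** summaries — plus a
synthetic phantom generator that labels every input with ground truth so
each stage can be validated by closed-form oracles and parameter recovery.

The package targets the analysis chain of longitudinal diet-intervention
studies (high-fat diet vs. control, imaged repeatedly over weeks), where
reduced stress perfusion and MPR, progressive LV hypertrophy and glucose
intolerance are the quantities of interest.

## The models in brief

**Perfusion.** ROI signal curves from a dual-contrast saturation-recovery
sequence (saturation delay 15 ms for the blood pool, 57 ms for myocardium)
are proton-density normalized, converted to T1 via
`T1 = -TD / log(1 - s)`, and expressed as `ΔR1 = 1/T1 - 1/T1₀` with
pre-contrast T1 fixed at 1.55 s (blood) and 1.45 s (myocardium). The
tissue curve is deconvolved against the arterial input under a Fermi
impulse-response model

```
h(t) = A / (1 + exp(k (t − d − τ))),   MBF = h(d⁺) · 60 / ρ   (ρ = 1.05 g/mL)
```

fit by bounded multi-start Levenberg–Marquardt; MPR = stress MBF / rest
MBF.

**Volumetry.** Slice-summation volumes from endo-/epicardial masks;
`EF = 100 (EDV − ESV)/EDV`; mass = myocardial volume × 1.05 mg/mm³; wall
thickness from 24 angular sectors about the cavity centroid.

**Strain.** Per-point deformation gradients `F` by Gaussian-weighted local
polynomial least squares on displacement fields; `E = (FᵀF − I)/2`;
`Ecc = cᵀEc` along the circumferential direction, reported globally, per
sector, and for subendo/subepi layers; CURE = mean over systolic frames of
`s0/(s0+s1)` from the spatial Fourier spectrum of segmental Ecc (1 =
synchronous, 0 = pure first-harmonic dyssynchrony).

**GTT.** Fasting glucose (t = 0) and trapezoidal AUC of the glucose–time
curve.

## Worked example

Render a noisy perfusion phantom with true rest flow 4 and stress flow
10 mL/min/g (true MPR 2.5) and push it through the full image-level
pipeline:

```r
library(mprkit)

ph  <- perfusion_phantom(mbf_rest = 4, mbf_stress = 10,
                         noise_sd = 0.002, seed = 42)
ser <- render_perfusion_series(ph)
acq <- ser$acq; times <- frame_times(acq)

quantify <- function(cond) {
  aif_raw <- extract_roi_curve(ser[[cond]]$aif_stack, ser$blood_mask,
                               times, acq$td_aif, role = "blood")
  tf_raw  <- extract_roi_curve(ser[[cond]]$tf_stack, ser$myo_mask,
                               times, acq$td_tf, role = "tissue")
  aif_n <- normalize_by_pd(aif_raw, ser$pd_value)
  base  <- seq_len(detect_bolus_arrival(aif_n$values) - 1)
  fermi_deconvolve(
    series_to_delta_r1(aif_n, 1.55, baseline_frames = base),
    series_to_delta_r1(normalize_by_pd(tf_raw, ser$pd_value), 1.45,
                       baseline_frames = base),
    condition = cond)
}
rest <- quantify("rest"); stress <- quantify("stress")
compute_mpr(rest, stress)
#> MPR = 2.490 (rest 4.011, stress 9.989 mL/min/g)
```

Both flows are recovered to ~0.3% and the reserve to 0.4% — the residual
is the phantom's pixel noise. Strain and GTT work the same way:

```r
def  <- cylinder_for_mean_ecc(2, 3, -0.14)       # prescribed peak Ecc
prof <- ecc_profile(render_displacements(def, spacing = 0.2, n_frames = 4))
peak_global_ecc(prof)$global                     #> -0.1399611
compute_cure(prof)$cure                          #> 0.9999835 (synchronous)

rec <- gtt_record(c(0, 10, 30, 60, 90), c(100, 200, 150, 120, 110))
auc_trapezoid(rec)                               #> 12500 mg/dL·min
```

A whole two-arm longitudinal study can be simulated to disk and analyzed
in one call each:

```r
cfg <- cohort_config(n_per_group = 4, seed = 11)
simulate_study("study_dir", cfg)     # NIfTI + JSON + CSV per subject/week
res <- run_study("study_dir")        # long-format table + mean ± SD summary
write_study_results(res, "study_out")
```

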