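#' Simulate a complete two-arm longitudinal study on disk
#'
#' Draws a synthetic cohort ([generate_cohort()]) and, for every subject and
#' study week, renders the raw inputs of every pipeline stage into a study
#' directory: dual-contrast first-pass image stacks and ROI masks for rest
#' and stress (NIfTI + JSON sidecar), multi-slice ED/ES LV masks (NIfTI +
#' JSON geometry), a DENSE-style displacement point table (CSV + JSON), and
#' a glucose-tolerance table (CSV). Per-subject perfusion uses a fixed rest
#' flow with the drawn MPR setting the stress flow; LV geometry is solved
#' from the drawn mass and ejection fraction at a fixed end-diastolic
#' volume; the strain phantom is matched to the drawn peak Ecc. The whole
#' simulation is deterministic given the seed.
#'
#' @param dir output directory (created if needed).
#' @param config a [cohort_config()].
#' @param seed integer seed (default: the config seed).
#' @param acq an [acq_params()] used for all perfusion series.
#' @param mbf_rest fixed true rest flow, mL/min/g.
#' @param noise_sd per-pixel noise SD on the normalized first-pass signal.
#' @param strain_effects,gtt_effects per-group/week data frames of strain
#'   and GTT generator means (see defaults in the source); `NULL` keeps the
#'   built-in profiles.
#' @return The study manifest (data frame: `subject`, `group`, `week`,
#'   `body_weight`, `path`), invisibly also written to `manifest.csv`;
#'   the drawn cohort table is written to `truth.csv`.
#' @export
simulate_study <- function(dir, config = cohort_config(n_per_group = 4L),
                           seed = config$seed, acq = acq_params(),
                           mbf_rest = 4, noise_sd = 0.002,
                           strain_effects = NULL, gtt_effects = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  if (is.null(strain_effects)) strain_effects <- default_strain_effects()
  if (is.null(gtt_effects)) gtt_effects <- default_gtt_effects()

  # draw all stochastic per-subject generator parameters from one stream,
  # then render with per-dataset derived seeds
  n <- nrow(cohort)
  eff_row <- function(tab, g, w) {
    e <- tab[tab$group == g & tab$week == w, ]
    if (!nrow(e)) e <- tab[tab$group == g, ][1, ]
    e
  }
  ecc_target <- numeric(n); gtt_par <- vector("list", n)
  for (i in seq_len(n)) {
    se <- eff_row(strain_effects, cohort$group[i], cohort$week[i])
    ecc_target[i] <- min(-0.02, rnorm(1, se$ecc_mean, se$ecc_sd))
    ge <- eff_row(gtt_effects, cohort$group[i], cohort$week[i])
    b <- max(40, rnorm(1, ge$baseline, 8))
    gtt_par[[i]] <- list(baseline = b,
                         peak = max(b + 20, rnorm(1, ge$peak, 25)),
                         decay = ge$decay)
  }

  paths <- character(n)
  for (i in seq_len(n)) {
    sw_dir <- file.path(dir, cohort$subject[i],
                        sprintf("wk%02d", as.integer(cohort$week[i])))
    dir.create(sw_dir, recursive = TRUE, showWarnings = FALSE)
    sw_seed <- (config$seed %% 100000L) * 10000L + i
    # the phantom family requires stress >= rest flow; draws below an MPR
    # of 1 (possible in the impaired arm's tail) are truncated there
    write_subject_perfusion(sw_dir, mpr = max(1, cohort$mpr[i]),
                            mbf_rest = mbf_rest, acq = acq,
                            noise_sd = noise_sd, seed = sw_seed)
    write_subject_lv(sw_dir, mass = max(20, cohort$lv_mass[i]),
                     ef = min(95, max(5, cohort$ef[i])))
    write_subject_strain(sw_dir, ecc_target[i])
    write_subject_gtt(sw_dir, gtt_par[[i]], seed = sw_seed + 5000L,
                      subject = cohort$subject[i], group = cohort$group[i],
                      week = cohort$week[i])
    paths[i] <- sw_dir
  }
  manifest <- data.frame(subject = cohort$subject, group = cohort$group,
                         week = cohort$week,
                         body_weight = cohort$body_weight, path = paths,
                         stringsAsFactors = FALSE)
  write_results(cohort, file.path(dir, "truth.csv"))
  write_results(manifest, file.path(dir, "manifest.csv"))
  jsonlite::write_json(list(seed = config$seed,
                            n_per_group = config$n_per_group,
                            timepoints = config$timepoints),
                       file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' @rdname simulate_study
#' @export
default_strain_effects <- function() {
  wk <- c(6, 12, 18, 24)
  rbind(
    data.frame(group = "control", week = wk,
               ecc_mean = c(-0.14, -0.13, -0.12, -0.12), ecc_sd = 0.02),
    data.frame(group = "hfd", week = wk,
               ecc_mean = c(-0.13, -0.12, -0.11, -0.14), ecc_sd = 0.02))
}

#' @rdname simulate_study
#' @export
default_gtt_effects <- function() {
  wk <- c(6, 12, 18, 24)
  rbind(
    data.frame(group = "control", week = wk, baseline = 90, peak = 280,
               decay = 30),
    data.frame(group = "hfd", week = wk, baseline = c(105, 135, 140, 125),
               peak = c(330, 430, 410, 380), decay = c(40, 70, 60, 55)))
}

write_subject_perfusion <- function(sw_dir, mpr, mbf_rest, acq, noise_sd,
                                    seed) {
  ph <- perfusion_phantom(mbf_rest = mbf_rest, mbf_stress = mbf_rest * mpr,
                          noise_sd = noise_sd, seed = seed)
  ser <- render_perfusion_series(ph, acq = acq)
  sp <- acq$pixel_spacing
  for (cond in c("rest", "stress")) {
    write_stack_nifti(ser[[cond]]$aif_stack,
                      file.path(sw_dir, paste0(cond, "_aif.nii")), sp)
    write_stack_nifti(ser[[cond]]$tf_stack,
                      file.path(sw_dir, paste0(cond, "_tf.nii")), sp)
  }
  write_stack_nifti(ser$blood_mask + 0, file.path(sw_dir, "blood_mask.nii"),
                    sp)
  write_stack_nifti(ser$myo_mask + 0, file.path(sw_dir, "myo_mask.nii"), sp)
  side <- c(unclass(acq)[acq_sidecar_fields], list(pd_value = ser$pd_value))
  jsonlite::write_json(side, file.path(sw_dir, "perfusion.json"),
                       auto_unbox = TRUE, digits = NA)
}

write_subject_lv <- function(sw_dir, mass, ef, edv = 43, n_slices = 6L,
                             slice_thickness = 1, pixel_spacing = 0.12) {
  r_endo_ed <- sqrt(edv / (n_slices * pi * slice_thickness))
  v_myo <- mass / 1.05
  r_epi_ed <- sqrt(r_endo_ed^2 + v_myo / (n_slices * pi * slice_thickness))
  r_endo_es <- r_endo_ed * sqrt(1 - ef / 100)
  r_epi_es <- incompressible_es_radii(r_endo_ed, r_epi_ed, r_endo_es)
  geom <- render_lv_masks(
    list(ED = lv_annulus_spec(r_endo_ed, r_epi_ed, n_slices),
         ES = lv_annulus_spec(r_endo_es, r_epi_es, n_slices)),
    pixel_spacing = pixel_spacing, slice_thickness = slice_thickness)
  for (ph in geom$phases) {
    for (s in seq_along(geom$endo[[ph]])) {
      write_stack_nifti(geom$endo[[ph]][[s]] + 0,
        file.path(sw_dir, sprintf("lv_endo_%s_s%d.nii", ph, s)),
        pixel_spacing)
      write_stack_nifti(geom$epi[[ph]][[s]] + 0,
        file.path(sw_dir, sprintf("lv_epi_%s_s%d.nii", ph, s)),
        pixel_spacing)
    }
  }
  jsonlite::write_json(list(phases = geom$phases, n_slices = n_slices,
                            pixel_spacing = pixel_spacing,
                            slice_thickness = slice_thickness),
                       file.path(sw_dir, "lv.json"), auto_unbox = TRUE,
                       digits = NA)
}

write_subject_strain <- function(sw_dir, ecc_target, r_endo = 2, r_epi = 3,
                                 spacing = 0.25, n_frames = 4L) {
  def <- cylinder_for_mean_ecc(r_endo, r_epi, ecc_target, spacing = spacing)
  fs <- render_displacements(def, spacing = spacing, n_frames = n_frames)
  rows <- do.call(rbind, lapply(seq_len(n_frames), function(k)
    data.frame(frame = k, x = fs$positions[, 1], y = fs$positions[, 2],
               depth = fs$depth, ux = fs$displacements[, 1, k],
               uy = fs$displacements[, 2, k])))
  write_results(rows, file.path(sw_dir, "strain.csv"))
  jsonlite::write_json(list(center = fs$center, times = fs$times),
                       file.path(sw_dir, "strain.json"), digits = NA)
}

write_subject_gtt <- function(sw_dir, par, seed, subject, group, week) {
  rec <- generate_gtt(baseline = par$baseline, peak = par$peak,
                      decay = par$decay, noise_sd = 5, seed = seed,
                      subject = subject, group = group, week = week)
  write_results(data.frame(subject = subject, group = group, week = week,
                           time_min = rec$times,
                           glucose_mg_dl = rec$glucose),
                file.path(sw_dir, "gtt.csv"))
}

#' Read a study manifest
#'
#' @param dir study directory containing `manifest.csv` (as written by
#'   [simulate_study()]).
#' @return The manifest data frame.
#' @export
read_study_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", dir, call. = FALSE)
  read_results(path)
}

#' Run the full analysis pipeline over a study
#'
#' Executes every analysis stage for each subject and study week referenced
#' by a manifest: first-pass perfusion quantification at rest and stress
#' (ROI extraction, proton-density normalization, T1 conversion, Delta-R1,
#' Fermi deconvolution) combined into MPR; LV volumetry (EDV, ESV, EF,
#' mass, ED/ES wall thickness); circumferential strain (global and layer
#' peak Ecc, CURE); and GTT summaries (fasting glucose, trapezoidal AUC).
#' A missing modality leaves its cells missing; an unparseable or failing
#' modality is logged and skipped, never crashes the run.
#'
#' @param manifest a manifest data frame ([read_study_manifest()]) or a
#'   study directory.
#' @param t1_blood0,t1_myo0 pre-contrast T1s, seconds.
#' @param rho_tissue myocardial density, g/mL.
#' @param n_sectors angular sectors for strain profiles.
#' @return A `study_result`: list with `subjects` (long-format data frame:
#'   `subject`, `group`, `week`, `metric`, `value`), `summary` (per group x
#'   week x metric: `mean`, `sd`, `n`; SD is missing when n = 1), and `log`
#'   (per-modality provenance/status records).
#' @export
run_study <- function(manifest, t1_blood0 = 1.55, t1_myo0 = 1.45,
                      rho_tissue = 1.05, n_sectors = 24) {
  if (is.character(manifest)) manifest <- read_study_manifest(manifest)
  rows <- list(); logs <- list()
  add <- function(subj, grp, wk, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subj, group = grp, week = wk, metric = metric,
      value = as.numeric(value), stringsAsFactors = FALSE)
  }
  note <- function(subj, wk, modality, status, msg = "") {
    logs[[length(logs) + 1L]] <<- data.frame(
      subject = subj, week = wk, modality = modality, status = status,
      message = msg, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(manifest))) {
    subj <- manifest$subject[i]; grp <- manifest$group[i]
    wk <- manifest$week[i]; sw <- manifest$path[i]
    add(subj, grp, wk, "body_weight", manifest$body_weight[i])

    perf <- tryCatch(
      analyze_subject_perfusion(sw, t1_blood0, t1_myo0, rho_tissue),
      error = function(e) e)
    if (inherits(perf, "error")) {
      note(subj, wk, "perfusion", "skipped", conditionMessage(perf))
      perf <- list(mbf_rest = NA, mbf_stress = NA, mpr = NA)
    } else note(subj, wk, "perfusion", "ok")
    add(subj, grp, wk, "mbf_rest", perf$mbf_rest)
    add(subj, grp, wk, "mbf_stress", perf$mbf_stress)
    add(subj, grp, wk, "mpr", perf$mpr)

    lv <- tryCatch(analyze_subject_lv(sw, n_sectors), error = function(e) e)
    if (inherits(lv, "error")) {
      note(subj, wk, "lv_function", "skipped", conditionMessage(lv))
      lv <- data.frame(edv = NA, esv = NA, ef = NA, mass = NA, edwt = NA,
                       eswt = NA)
    } else note(subj, wk, "lv_function", "ok")
    lv_names <- c(edv = "edv", esv = "esv", ef = "ef", mass = "lv_mass",
                  edwt = "edwt", eswt = "eswt")
    for (m in names(lv)) add(subj, grp, wk, lv_names[[m]], lv[[m]][1])

    st <- tryCatch(analyze_subject_strain(sw, n_sectors),
                   error = function(e) e)
    if (inherits(st, "error")) {
      note(subj, wk, "strain", "skipped", conditionMessage(st))
      st <- list(ecc_global = NA, ecc_subendo = NA, ecc_subepi = NA,
                 cure = NA)
    } else note(subj, wk, "strain", "ok")
    for (m in names(st)) add(subj, grp, wk, m, st[[m]])

    gt <- tryCatch(analyze_subject_gtt(sw), error = function(e) e)
    if (inherits(gt, "error")) {
      note(subj, wk, "gtt", "skipped", conditionMessage(gt))
      gt <- list(fasting_glucose = NA, gtt_auc = NA)
    } else note(subj, wk, "gtt", "ok")
    for (m in names(gt)) add(subj, grp, wk, m, gt[[m]])
  }
  subjects <- do.call(rbind, rows)
  structure(list(subjects = subjects,
                 summary = summarize_study(subjects),
                 log = do.call(rbind, logs)),
            class = "study_result")
}

analyze_subject_perfusion <- function(sw, t1_blood0, t1_myo0, rho_tissue) {
  side_path <- file.path(sw, "perfusion.json")
  if (!file.exists(side_path)) stop("no perfusion data")
  acq <- read_image_sidecar(side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pd <- if (!is.null(side$pd_value)) side$pd_value else 1
  blood_mask <- read_mask_nifti(file.path(sw, "blood_mask.nii"))
  myo_mask <- read_mask_nifti(file.path(sw, "myo_mask.nii"))
  times <- frame_times(acq)
  one <- function(cond) {
    aif_raw <- extract_roi_curve(
      read_stack_nifti(file.path(sw, paste0(cond, "_aif.nii"))),
      blood_mask, times, td = acq$td_aif, role = "blood")
    tf_raw <- extract_roi_curve(
      read_stack_nifti(file.path(sw, paste0(cond, "_tf.nii"))),
      myo_mask, times, td = acq$td_tf, role = "tissue")
    # bolus arrival is detected on the sharp blood curve and the same
    # pre-bolus baseline window is applied to the slow-rising tissue curve
    aif_n <- normalize_by_pd(aif_raw, pd)
    base <- seq_len(detect_bolus_arrival(aif_n$values) - 1L)
    aif <- series_to_delta_r1(aif_n, t1_blood0, baseline_frames = base)
    tf <- series_to_delta_r1(normalize_by_pd(tf_raw, pd), t1_myo0,
                             baseline_frames = base)
    fermi_deconvolve(aif, tf, rho_tissue = rho_tissue, condition = cond)
  }
  rest <- one("rest"); stress <- one("stress")
  mpr <- compute_mpr(rest, stress)
  list(mbf_rest = rest$mbf, mbf_stress = stress$mbf, mpr = mpr$mpr)
}

analyze_subject_lv <- function(sw, n_sectors) {
  meta_path <- file.path(sw, "lv.json")
  if (!file.exists(meta_path)) stop("no LV data")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  endo <- list(); epi <- list()
  for (ph in meta$phases) {
    endo[[ph]] <- lapply(seq_len(meta$n_slices), function(s)
      read_mask_nifti(file.path(sw, sprintf("lv_endo_%s_s%d.nii", ph, s))))
    epi[[ph]] <- lapply(seq_len(meta$n_slices), function(s)
      read_mask_nifti(file.path(sw, sprintf("lv_epi_%s_s%d.nii", ph, s))))
  }
  geom <- lv_geometry(endo, epi, pixel_spacing = meta$pixel_spacing,
                      slice_thickness = meta$slice_thickness)
  lv_indices(geom, n_sectors = n_sectors)
}

analyze_subject_strain <- function(sw, n_sectors) {
  csv_path <- file.path(sw, "strain.csv")
  if (!file.exists(csv_path)) stop("no strain data")
  tab <- read_results(csv_path)
  meta <- jsonlite::read_json(file.path(sw, "strain.json"),
                              simplifyVector = TRUE)
  frames <- sort(unique(tab$frame))
  f1 <- tab[tab$frame == frames[1], ]
  U <- array(0, dim = c(nrow(f1), 2L, length(frames)))
  for (k in seq_along(frames)) {
    fk <- tab[tab$frame == frames[k], ]
    U[, 1, k] <- fk$ux; U[, 2, k] <- fk$uy
  }
  fs <- strain_frame_set(positions = cbind(f1$x, f1$y), displacements = U,
                         center = meta$center, times = meta$times,
                         depth = f1$depth)
  prof <- ecc_profile(fs, n_sectors = n_sectors)
  pk <- peak_global_ecc(prof)
  cure <- compute_cure(prof)
  list(ecc_global = pk$global, ecc_subendo = pk$subendo,
       ecc_subepi = pk$subepi, cure = cure$cure)
}

analyze_subject_gtt <- function(sw) {
  csv_path <- file.path(sw, "gtt.csv")
  if (!file.exists(csv_path)) stop("no GTT data")
  tab <- read_results(csv_path)
  rec <- gtt_record(tab$time_min, tab$glucose_mg_dl)
  list(fasting_glucose = fasting_glucose(rec), gtt_auc = auc_trapezoid(rec))
}

#' Group mean/SD/n summary of a long-format subject table
#'
#' @param subjects long-format data frame (`subject`, `group`, `week`,
#'   `metric`, `value`).
#' @return Data frame per group x week x metric with `mean`, `sd` (missing
#'   when n = 1) and `n` (count of non-missing subjects).
#' @export
summarize_study <- function(subjects) {
  key <- interaction(subjects$group, subjects$week, subjects$metric,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(subjects, key), function(d) {
    v <- d$value[!is.na(d$value)]
    data.frame(group = d$group[1], week = d$week[1], metric = d$metric[1],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$metric, out$week, out$group), ]
  rownames(out) <- NULL
  out
}

#' Write study results deterministically
#'
#' Writes `subjects.csv`, `summary.csv` and `log.csv` with [write_results()]
#' so that identical inputs yield byte-identical files.
#'
#' @param res a `study_result` from [run_study()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_study_results <- function(res, dir) {
  stopifnot(inherits(res, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results(res$subjects, file.path(dir, "subjects.csv"))
  write_results(res$summary, file.path(dir, "summary.csv"))
  write_results(res$log, file.path(dir, "log.csv"))
  invisible(dir)
}
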