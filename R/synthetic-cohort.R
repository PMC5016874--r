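#' Generate a synthetic glucose tolerance curve
#'
#' Produces glucose samples from a tolerance-shaped profile: a linear rise
#' from the fasting baseline to the peak at `t_peak`, followed by an
#' exponential return towards baseline with time constant `decay`. Optional
#' seeded Gaussian noise is added; any sample driven negative is clipped to
#' 0 and the record is flagged via the `"clipped"` attribute.
#'
#' @param baseline fasting glucose, mg/dL.
#' @param peak peak glucose, mg/dL (`>= baseline` for a tolerance-shaped
#'   curve; equality gives a flat profile).
#' @param t_peak time of peak, minutes.
#' @param decay exponential return time constant, minutes.
#' @param sample_times sampling times, minutes, nondecreasing (default
#'   protocol 0, 10, 30, 60, 90).
#' @param noise_sd Gaussian noise SD, mg/dL.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param subject,group,week labels carried into the record.
#' @return A [gtt_record()]; attribute `"clipped"` is `TRUE` if any sample
#'   was clipped at 0.
#' @export
generate_gtt <- function(baseline = 100, peak = 300, t_peak = 10, decay = 40,
                         sample_times = c(0, 10, 30, 60, 90),
                         noise_sd = 0, seed = NULL,
                         subject = NA, group = NA, week = NA) {
  check_times(sample_times, strict = FALSE)
  if (baseline < 0 || peak < baseline || t_peak <= 0 || decay <= 0)
    stop("generate_gtt: need peak >= baseline >= 0, t_peak > 0, decay > 0",
         call. = FALSE)
  amp <- peak - baseline
  g <- ifelse(sample_times <= t_peak,
              baseline + amp * sample_times / t_peak,
              baseline + amp * exp(-(sample_times - t_peak) / decay))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    g <- g + rnorm(length(g), sd = noise_sd)
  }
  clipped <- any(g < 0)
  rec <- gtt_record(sample_times, pmax(g, 0),
                    subject = subject, group = group, week = week)
  attr(rec, "clipped") <- clipped
  rec
}

#' Configuration of a synthetic two-arm longitudinal cohort
#'
#' Defines group sizes, study weeks and the per-group, per-week effect
#' profile (mean and SD) of each simulated metric. The default profile
#' mimics a high-fat-diet (HFD) versus low-fat control mouse study:
#' myocardial perfusion reserve preserved early but reduced in the HFD arm
#' at 18 and 24 weeks, LV mass progressively increasing under HFD, ejection
#' fraction similar between arms, and body weight elevated under HFD
#' throughout.
#'
#' @param n_per_group animals per arm (>= 2).
#' @param timepoints study weeks post-diet.
#' @param effects data frame with columns `group`, `week`, `metric`,
#'   `mean`, `sd` (SDs nonnegative); see [default_cohort_effects()].
#' @param seed integer seed for [generate_cohort()].
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_per_group = 8L, timepoints = c(6, 12, 18, 24),
                          effects = default_cohort_effects(timepoints),
                          seed = 1L) {
  if (n_per_group < 2L) stop("cohort_config: n_per_group must be >= 2",
                             call. = FALSE)
  need <- c("group", "week", "metric", "mean", "sd")
  if (!all(need %in% names(effects)))
    stop("cohort_config: effects must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(effects$sd < 0))
    stop("cohort_config: SDs must be nonnegative", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group),
                 timepoints = timepoints, effects = effects,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_cohort_effects <- function(timepoints = c(6, 12, 18, 24)) {
  wk <- c(6, 12, 18, 24)
  tab <- rbind(
    data.frame(group = "control", week = wk, metric = "mpr",
               mean = c(2.6, 2.5, 2.5, 2.4), sd = 0.4),
    data.frame(group = "hfd", week = wk, metric = "mpr",
               mean = c(2.5, 2.3, 1.7, 1.5), sd = 0.4),
    data.frame(group = "control", week = wk, metric = "lv_mass",
               mean = c(78, 82, 84, 90), sd = 8),
    data.frame(group = "hfd", week = wk, metric = "lv_mass",
               mean = c(84, 92, 105, 118), sd = 10),
    data.frame(group = "control", week = wk, metric = "ef",
               mean = c(61, 64, 64, 67), sd = 8),
    data.frame(group = "hfd", week = wk, metric = "ef",
               mean = c(66, 65, 69, 74), sd = 8),
    data.frame(group = "control", week = wk, metric = "body_weight",
               mean = c(26, 29, 31, 33), sd = 2),
    data.frame(group = "hfd", week = wk, metric = "body_weight",
               mean = c(35, 41, 46, 49), sd = 3))
  tab[tab$week %in% timepoints, , drop = FALSE]
}

#' Draw a synthetic per-subject longitudinal measurement table
#'
#' Draws independent Gaussian subject-level values around the configured
#' group means for every metric and study week, producing one row per
#' subject and week with columns for each metric. Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @return Data frame with columns `subject`, `group`, `week` and one
#'   column per configured metric.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  eff <- config$effects
  metrics <- unique(eff$metric)
  groups <- unique(eff$group)
  rows <- list()
  for (g in groups) {
    for (i in seq_len(config$n_per_group)) {
      subj <- sprintf("%s%02d", substr(g, 1, 1), i)
      for (w in config$timepoints) {
        row <- list(subject = subj, group = g, week = w)
        for (m in metrics) {
          e <- eff[eff$group == g & eff$week == w & eff$metric == m, ]
          row[[m]] <- if (nrow(e)) rnorm(1, e$mean[1], e$sd[1]) else NA_real_
        }
        rows[[length(rows) + 1L]] <- as.data.frame(row)
      }
    }
  }
  do.call(rbind, rows)
}
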