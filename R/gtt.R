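#' Glucose tolerance test record
#'
#' Sample times (minutes post-injection; 0 is the fasting draw taken before
#' the glucose bolus) and blood glucose values (mg/dL) for one animal at one
#' study week.
#'
#' @param times sample times, minutes, nondecreasing and nonnegative
#'   (default protocol: 0, 10, 30, 60, 90).
#' @param glucose blood glucose, mg/dL, nonnegative.
#' @param subject,group,week optional labels.
#' @return A `gtt_record` object.
#' @export
gtt_record <- function(times, glucose, subject = NA, group = NA, week = NA) {
  check_times(times, strict = FALSE)
  if (any(times < 0)) stop("gtt_record: times must be >= 0", call. = FALSE)
  if (length(glucose) != length(times))
    stop("gtt_record: times and glucose differ in length", call. = FALSE)
  if (any(glucose < 0))
    stop("gtt_record: glucose must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times), glucose = as.numeric(glucose),
                 subject = subject, group = group, week = week),
            class = "gtt_record")
}

#' Trapezoidal area under the glucose curve
#'
#' Total AUC by the trapezoidal rule,
#' `sum( (g_i + g_{i+1}) (t_{i+1} - t_i) / 2 )`, in mg/dL x min. With
#' `incremental = TRUE` the fasting (t = 0) value is subtracted from every
#' sample first (incremental AUC).
#'
#' @param record a [gtt_record()] with at least 2 samples.
#' @param incremental subtract the fasting value before integrating.
#' @return AUC, mg/dL x min.
#' @examples
#' r <- gtt_record(c(0, 10, 30, 60, 90), c(100, 200, 150, 120, 110))
#' auc_trapezoid(r)   # 12500
#' @export
auc_trapezoid <- function(record, incremental = FALSE) {
  stopifnot(inherits(record, "gtt_record"))
  if (length(record$times) < 2L)
    stop("auc_trapezoid: need at least 2 samples", call. = FALSE)
  g <- record$glucose
  if (incremental) g <- g - fasting_glucose(record)
  sum(0.5 * (g[-1] + g[-length(g)]) * diff(record$times))
}

#' Fasting glucose
#'
#' The blood glucose drawn at t = 0, before glucose injection.
#'
#' @param record a [gtt_record()].
#' @return Fasting glucose, mg/dL.
#' @export
fasting_glucose <- function(record) {
  stopifnot(inherits(record, "gtt_record"))
  i <- which(record$times == 0)
  if (!length(i))
    stop("fasting_glucose: no baseline (t = 0) sample present", call. = FALSE)
  record$glucose[i[1L]]
}
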