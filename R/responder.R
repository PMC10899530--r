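# MEKi-floor normalization and per-cell responder analysis.

#' Analysis windows for responder calling
#'
#' @param pre_window Minutes before treatment used for pairing and as the
#'   amplitude/AUC baseline (default 60).
#' @param post_window Minutes after treatment used for pairing (default 60).
#' @param amplitude_window Minutes after treatment searched for the maximum
#'   response amplitude (default 60).
#' @param auc_window Minutes after treatment integrated for the AUC
#'   duration surrogate (default 720, i.e. 12 h).
#' @param alpha Per-cell significance level of the paired t-test
#'   (default 0.005).
#' @param direction_policy `"increase_only"` (default): a cell is a
#'   responder only when significant with `mean(post) > mean(pre)`;
#'   `"any"`: significance in either direction qualifies.
#' @return A list of class `ktrq_windows`.
#' @export
analysis_windows <- function(pre_window = 60, post_window = 60,
                             amplitude_window = 60, auc_window = 720,
                             alpha = 0.005,
                             direction_policy = c("increase_only", "any")) {
  assert_scalar_num(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  assert_scalar_num(pre_window, "pre_window", positive = TRUE)
  assert_scalar_num(post_window, "post_window", positive = TRUE)
  assert_scalar_num(amplitude_window, "amplitude_window", positive = TRUE)
  assert_scalar_num(auc_window, "auc_window", positive = TRUE)
  structure(
    list(pre_window = pre_window, post_window = post_window,
         amplitude_window = amplitude_window, auc_window = auc_window,
         alpha = alpha, direction_policy = match.arg(direction_policy)),
    class = "ktrq_windows"
  )
}

#' Normalize activity traces to the MEK-inhibited floor
#'
#' Scales (or shifts) each cell's trace by its own mean activity over the
#' MEKi floor window, so traces from different cells and replicates share a
#' common reference. After `mode = "divide"` (default) the floor-window
#' mean is exactly 1; after `mode = "subtract"` it is exactly 0. Cells with
#' a non-positive floor mean (divide mode) or no valid floor frames are
#' dropped with a warning giving the count.
#'
#' @param traces Trace tibble (`cell_id`, `time_min`, `activity`, `valid`).
#' @param schedule An [acquisition_schedule()].
#' @param mode `"divide"` or `"subtract"`.
#' @param floor_window Minutes at the end of acquisition used as the floor
#'   (default: final 40% of the schedule's MEKi window, skipping the
#'   relaxation transient right after inhibitor addition).
#' @return Trace tibble of the same shape with normalized `activity`.
#' @export
normalize_traces <- function(traces, schedule, mode = c("divide", "subtract"),
                             floor_window = NULL) {
  mode <- match.arg(mode)
  require_columns(traces, c("cell_id", "time_min", "activity", "valid"), "`traces`")
  ff <- floor_frames(schedule, floor_window)
  if (!length(ff)) stop("schedule has no MEKi floor frames", call. = FALSE)
  t_start <- schedule$times[min(ff)]

  in_floor <- traces$time_min >= t_start - schedule$frame_interval * 1e-9
  m_by_cell <- tapply(
    ifelse(in_floor & traces$valid, traces$activity, NA_real_),
    traces$cell_id, mean, na.rm = TRUE
  )
  m <- m_by_cell[as.character(traces$cell_id)]
  bad_cells <- names(m_by_cell)[!is.finite(m_by_cell) |
                                  (mode == "divide" & m_by_cell <= 0)]
  if (length(bad_cells)) {
    warning(sprintf("dropped %d cell(s) with unusable MEKi floor", length(bad_cells)),
            call. = FALSE)
    keep <- !traces$cell_id %in% as.integer(bad_cells) &
      !traces$cell_id %in% bad_cells
    traces <- traces[keep, , drop = FALSE]
    m <- m[keep]
  }
  traces$activity <- if (mode == "divide") traces$activity / as.numeric(m)
                     else traces$activity - as.numeric(m)
  traces
}

# Single-cell paired pre/post t-test. Returns list(p, statistic, direction,
# n_pairs, indeterminate).
responder_test_one <- function(time_min, activity, valid, schedule, windows) {
  tx <- schedule$treatment_time
  eps <- schedule$frame_interval * 1e-9
  ok <- valid & is.finite(activity)
  pre_idx <- which(ok & time_min <= tx + eps & time_min > tx - windows$pre_window + eps)
  post_idx <- which(ok & time_min > tx + eps & time_min <= tx + windows$post_window + eps)
  k <- min(length(pre_idx), length(post_idx))
  if (k < 3) {
    return(list(p = NA_real_, statistic = NA_real_, direction = "none",
                n_pairs = k, indeterminate = TRUE))
  }
  pre <- activity[pre_idx[(length(pre_idx) - k + 1):length(pre_idx)]]
  post <- activity[post_idx[seq_len(k)]]
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(list(p = 1, statistic = NA_real_, direction = "none",
                n_pairs = k, indeterminate = FALSE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE, alternative = "two.sided")
  dir <- if (mean(post) > mean(pre)) "increase"
         else if (mean(post) < mean(pre)) "decrease" else "none"
  list(p = unname(tt$p.value), statistic = unname(tt$statistic),
       direction = dir, n_pairs = k, indeterminate = FALSE)
}

amplitude_internal <- function(time_min, activity, valid, schedule, windows) {
  tx <- schedule$treatment_time
  eps <- schedule$frame_interval * 1e-9
  ok <- valid & is.finite(activity)
  b0 <- mean(activity[ok & time_min <= tx + eps &
                        time_min > tx - windows$pre_window + eps])
  win <- ok & time_min >= tx - eps & time_min <= tx + windows$amplitude_window + eps
  if (!any(win) || !is.finite(b0)) return(NA_real_)
  max(activity[win]) - b0
}

#' Maximum response amplitude within the amplitude window
#'
#' The maximum of `activity - b0` over
#' `[treatment, treatment + amplitude_window]`, where `b0` is the mean
#' activity over the pre-treatment window. Returns `NA` when the window
#' holds no valid frames.
#'
#' @param trace Single-cell trace tibble (`time_min`, `activity`, `valid`).
#' @param schedule An [acquisition_schedule()].
#' @param windows An [analysis_windows()] object.
#' @return Scalar amplitude (same units as the normalized activity).
#' @export
max_amplitude <- function(trace, schedule, windows = analysis_windows()) {
  require_columns(trace, c("time_min", "activity", "valid"), "`trace`")
  amplitude_internal(trace$time_min, trace$activity, trace$valid,
                     schedule, windows)
}

#' Area under the response curve as a duration surrogate
#'
#' Trapezoidal integral of `activity - b0` over
#' `[treatment, treatment + auc_window]` (12 h by default), in
#' activity-hours. Invalid frames are linearly interpolated from
#' neighboring valid frames; the integral is not clipped at zero. When
#' more than 25% of the window's frames are invalid the value carries
#' attribute `low_confidence = TRUE`.
#'
#' @inheritParams max_amplitude
#' @return Scalar AUC (activity x hours) with a `low_confidence` attribute.
#' @export
auc_12h <- function(trace, schedule, windows = analysis_windows()) {
  require_columns(trace, c("time_min", "activity", "valid"), "`trace`")
  res <- auc_internal(trace$time_min, trace$activity, trace$valid, schedule, windows)
  structure(res$value, low_confidence = res$low_confidence)
}

auc_internal <- function(time_min, activity, valid, schedule, windows) {
  tx <- schedule$treatment_time
  eps <- schedule$frame_interval * 1e-9
  ok <- valid & is.finite(activity)
  b0 <- mean(activity[ok & time_min <= tx + eps &
                        time_min > tx - windows$pre_window + eps])
  in_win <- time_min >= tx - eps & time_min <= tx + windows$auc_window + eps
  tw <- time_min[in_win]
  if (length(tw) < 2 || !is.finite(b0)) {
    return(list(value = NA_real_, low_confidence = TRUE))
  }
  aw <- activity[in_win]
  vw <- ok[in_win]
  frac_invalid <- mean(!vw)
  if (!any(vw)) return(list(value = NA_real_, low_confidence = TRUE))
  if (any(!vw)) {
    aw <- stats::approx(tw[vw], aw[vw], xout = tw, rule = 2)$y
  }
  list(value = trapz(tw / 60, aw - b0), low_confidence = frac_invalid > 0.25)
}

#' Call responders cell-by-cell with a paired pre/post t-test
#'
#' For each cell, the `k` valid frames ending at treatment time are paired
#' in order with the `k` valid frames starting right after it
#' (`k` = the smaller of the two window frame counts), and a two-sided
#' paired t-test is applied to the differences. A cell is a responder when
#' `p < alpha` and, under the default `increase_only` policy, the
#' post-treatment mean exceeds the pre-treatment mean. Zero-variance
#' differences give `p = 1` (non-responder); cells with fewer than 3 valid
#' frame pairs are flagged indeterminate. Amplitude and AUC are reported
#' only for responders, which are the cells analyzed further.
#'
#' @param traces Trace tibble, normally after [normalize_traces()].
#' @param schedule An [acquisition_schedule()].
#' @param windows An [analysis_windows()] object.
#' @return A tibble with one row per cell: `cell_id`, `n_pairs`,
#'   `statistic`, `p_value`, `direction`, `is_responder`, `indeterminate`,
#'   `amplitude`, `auc`, `auc_low_confidence`, plus pass-through
#'   `condition` and `dose_ng_ml`.
#' @export
call_responders <- function(traces, schedule, windows = analysis_windows()) {
  require_columns(traces, c("cell_id", "time_min", "activity", "valid"), "`traces`")
  split_idx <- split(seq_len(nrow(traces)), traces$cell_id)
  n <- length(split_idx)
  ids <- vector(mode = typeof(traces$cell_id), length = n)
  n_pairs <- integer(n); statistic <- numeric(n); p_value <- numeric(n)
  direction <- character(n); is_resp <- logical(n); indet <- logical(n)
  amp <- rep(NA_real_, n); auc <- rep(NA_real_, n); auc_lc <- rep(NA, n)
  has_cond <- "condition" %in% names(traces)
  has_dose <- "dose_ng_ml" %in% names(traces)
  cond <- character(n); dose <- numeric(n)

  for (i in seq_len(n)) {
    idx <- split_idx[[i]]
    o <- order(traces$time_min[idx])
    idx <- idx[o]
    tm <- traces$time_min[idx]; ac <- traces$activity[idx]; vl <- traces$valid[idx]
    tst <- responder_test_one(tm, ac, vl, schedule, windows)
    resp <- !tst$indeterminate && is.finite(tst$p) && tst$p < windows$alpha &&
      (windows$direction_policy == "any" || tst$direction == "increase")
    ids[i] <- traces$cell_id[idx[1]]
    n_pairs[i] <- tst$n_pairs
    statistic[i] <- tst$statistic
    p_value[i] <- tst$p
    direction[i] <- if (resp || tst$indeterminate) tst$direction
                    else if (!is.finite(tst$p) || tst$p >= windows$alpha) "none"
                    else tst$direction
    is_resp[i] <- resp
    indet[i] <- tst$indeterminate
    if (resp) {
      amp[i] <- amplitude_internal(tm, ac, vl, schedule, windows)
      a <- auc_internal(tm, ac, vl, schedule, windows)
      auc[i] <- a$value; auc_lc[i] <- a$low_confidence
    }
    cond[i] <- if (has_cond) as.character(traces$condition[idx[1]]) else NA_character_
    dose[i] <- if (has_dose) traces$dose_ng_ml[idx[1]] else NA_real_
  }
  tibble::tibble(
    cell_id = ids, n_pairs = n_pairs, statistic = statistic,
    p_value = p_value, direction = direction, is_responder = is_resp,
    indeterminate = indet, amplitude = amp, auc = auc,
    auc_low_confidence = auc_lc, condition = cond, dose_ng_ml = dose
  )
}

#' Responder fraction with a Wilson 95% confidence interval
#'
#' @param calls Tibble from [call_responders()]. Indeterminate cells are
#'   excluded from the denominator.
#' @return One-row tibble: `n`, `n_responders`, `fraction`, `ci_low`,
#'   `ci_high`.
#' @export
responder_fraction <- function(calls) {
  require_columns(calls, c("is_responder"), "`calls`")
  if ("indeterminate" %in% names(calls)) {
    calls <- calls[!calls$indeterminate, , drop = FALSE]
  }
  n <- nrow(calls)
  if (n == 0) stop("no determinate responder calls", call. = FALSE)
  k <- sum(calls$is_responder)
  ci <- wilson_ci(k, n)
  tibble::tibble(n = n, n_responders = k, fraction = k / n,
                 ci_low = ci[["low"]], ci_high = ci[["high"]])
}

#' Assign a response class to an ensemble of responder traces
#'
#' Computes the ensemble-mean baseline-subtracted response `r(t)` over the
#' 12 h after treatment, then two scale-free indices: persistence
#' `P = r(12 h) / max r` and normalized duration
#' `D = AUC(r, 12 h) / (max r * 12 h)`. The ensemble is class 3
#' (sustained) when `P >= 0.5`, class 1 (transient) when `D <= 0.25`, and
#' class 2 (prolonged but waning) otherwise. The thresholds operationalize
#' the qualitative transient / waning / sustained distinction; an ensemble
#' whose peak response is not positive is unclassifiable (`NA`).
#'
#' @param traces Normalized trace tibble restricted to responder cells
#'   (at least 20).
#' @param schedule An [acquisition_schedule()].
#' @param windows An [analysis_windows()] object (supplies the pre-window
#'   for the baseline and the 12 h horizon).
#' @return One-row tibble: `response_class` (integer or `NA`),
#'   `persistence`, `duration_index`, `peak_response`, `n_cells`.
#' @export
classify_response_class <- function(traces, schedule, windows = analysis_windows()) {
  require_columns(traces, c("cell_id", "time_min", "activity", "valid"), "`traces`")
  n_cells <- length(unique(traces$cell_id))
  if (n_cells < 20) {
    stop("classification requires at least 20 responder traces", call. = FALSE)
  }
  ok <- traces$valid & is.finite(traces$activity)
  mean_tr <- tapply(ifelse(ok, traces$activity, NA_real_), traces$time_min,
                    mean, na.rm = TRUE)
  tt <- as.numeric(names(mean_tr))
  o <- order(tt); tt <- tt[o]; mean_tr <- as.numeric(mean_tr)[o]

  tx <- schedule$treatment_time
  eps <- schedule$frame_interval * 1e-9
  b0 <- mean(mean_tr[tt <= tx + eps & tt > tx - windows$pre_window + eps])
  in_win <- tt >= tx - eps & tt <= tx + windows$auc_window + eps
  r <- mean_tr[in_win] - b0
  tw <- tt[in_win]
  peak <- max(r)
  if (!is.finite(peak) || peak <= 0) {
    return(tibble::tibble(response_class = NA_integer_, persistence = NA_real_,
                          duration_index = NA_real_, peak_response = peak,
                          n_cells = n_cells))
  }
  r_end <- r[length(r)]
  pers <- r_end / peak
  dur <- trapz(tw / 60, r) / (peak * windows$auc_window / 60)
  cls <- if (pers >= 0.5) 3L else if (dur <= 0.25) 1L else 2L
  tibble::tibble(response_class = cls, persistence = pers,
                 duration_index = dur, peak_response = peak,
                 n_cells = n_cells)
}
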