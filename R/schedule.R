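#' Define a live-cell acquisition schedule
#'
#' Describes the timing of a KTR live-cell experiment: frames collected at a
#' fixed interval, a ligand-free baseline, growth-factor addition at the end
#' of the baseline, a post-treatment observation window, and a terminal MEK
#' inhibitor (MEKi) window during which ERK activity falls to its floor. The
#' MEKi floor is the reference used by [normalize_traces()].
#'
#' All durations are minutes. Event times are snapped to the frame grid.
#' The defaults mirror a common KTR protocol: one frame every 6 minutes,
#' 4 h of baseline, 15 h after ligand addition, then 1 h under MEKi.
#'
#' @param frame_interval Minutes between consecutive frames (default 6).
#' @param baseline_duration Minutes of baseline imaging before treatment
#'   (default 240). Treatment occurs at the end of the baseline.
#' @param post_duration Minutes between treatment and MEKi addition
#'   (default 900).
#' @param meki_window Minutes imaged after MEKi addition (default 60). The
#'   tail of this window serves as the ERK-activity floor.
#' @return An object of class `ktrq_schedule`: a list with the snapped event
#'   times (`treatment_time`, `meki_time`, minutes), the frame time grid
#'   `times`, and `n_frames`.
#' @examples
#' sched <- acquisition_schedule()
#' sched$n_frames
#' @export
acquisition_schedule <- function(frame_interval = 6,
                                 baseline_duration = 240,
                                 post_duration = 900,
                                 meki_window = 60) {
  assert_scalar_num(frame_interval, "frame_interval", positive = TRUE)
  assert_scalar_num(baseline_duration, "baseline_duration", positive = TRUE)
  assert_scalar_num(post_duration, "post_duration", positive = TRUE)
  assert_scalar_num(meki_window, "meki_window", min = 0)

  snap <- function(t) round(t / frame_interval) * frame_interval
  treatment_time <- snap(baseline_duration)
  meki_time <- snap(treatment_time + post_duration)
  end_time <- snap(meki_time + meki_window)
  if (meki_time <= treatment_time) {
    stop("MEKi addition must come after treatment", call. = FALSE)
  }
  times <- seq(0, end_time, by = frame_interval)
  structure(
    list(
      frame_interval = frame_interval,
      treatment_time = treatment_time,
      meki_time = meki_time,
      meki_window = end_time - meki_time,
      end_time = end_time,
      times = times,
      n_frames = length(times)
    ),
    class = "ktrq_schedule"
  )
}

#' @export
print.ktrq_schedule <- function(x, ...) {
  cat("<ktrq_schedule>\n")
  cat(sprintf("  %d frames every %g min (0 .. %g min)\n",
              x$n_frames, x$frame_interval, x$end_time))
  cat(sprintf("  treatment at %g min, MEKi at %g min (%g min floor window)\n",
              x$treatment_time, x$meki_time, x$meki_window))
  invisible(x)
}

# Frame indices whose times fall in (from, to] (default) or [from, to].
schedule_frames <- function(schedule, from, to, include_left = FALSE) {
  t <- schedule$times
  eps <- schedule$frame_interval * 1e-9
  if (include_left) which(t >= from - eps & t <= to + eps)
  else which(t > from + eps & t <= to + eps)
}

# Frames used as the MEKi activity floor: the last `floor_window` minutes of
# acquisition (default: final 40% of the MEKi window, skipping the initial
# relaxation transient after inhibitor addition).
floor_frames <- function(schedule, floor_window = NULL) {
  fw <- floor_window %||% (0.4 * schedule$meki_window)
  which(schedule$times >= schedule$end_time - fw - schedule$frame_interval * 1e-9)
}
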