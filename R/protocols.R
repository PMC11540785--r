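#' Exercise protocol constants
#'
#' Returns the protocol definition for one of the three resistance exercises
#' (squat, knee-up, reverse lunge) under one of the two experimental
#' conditions: `"max"` (maximum-effort repetitions for a short, fixed
#' duration with no pace constraint) or `"const"` (metronome-paced
#' repetitions at a fixed target cadence for a longer duration).
#'
#' The constants are: squat 45 s max / 60 RPM for 90 s const; knee-up 60 s
#' max / 132 RPM for 180 s const; reverse lunge 60 s max / 48 RPM for 120 s
#' const. The initial-speed window is 10 repetitions for squat and lunge and
#' 30 for knee-up.
#'
#' @param exercise one of `"squat"`, `"kneeup"`, `"lunge"`.
#' @param condition one of `"max"`, `"const"`.
#' @return a list of class `"exercise_protocol"` with fields `exercise`,
#'   `condition`, `duration_s`, `target_rpm` (`NA` for the max condition),
#'   `initial_speed_window_reps` and `nominal_interval_s` (the expected
#'   inter-repetition interval used to seed peak detection).
#' @export
#' @examples
#' exercise_protocol("squat", "const")
exercise_protocol <- function(exercise = c("squat", "kneeup", "lunge"),
                              condition = c("max", "const")) {
  exercise <- match.arg(exercise)
  condition <- match.arg(condition)
  tab <- list(
    squat  = list(max_duration = 45, const_duration = 90,  rpm = 60,
                  window = 10, max_nominal_interval = 10 / 8.47),
    kneeup = list(max_duration = 60, const_duration = 180, rpm = 132,
                  window = 30, max_nominal_interval = 10 / 24),
    lunge  = list(max_duration = 60, const_duration = 120, rpm = 48,
                  window = 10, max_nominal_interval = 10 / 9)
  )[[exercise]]
  if (condition == "const") {
    duration <- tab$const_duration
    target_rpm <- tab$rpm
    nominal <- 60 / tab$rpm
  } else {
    duration <- tab$max_duration
    target_rpm <- NA_real_
    nominal <- tab$max_nominal_interval
  }
  structure(list(
    exercise = exercise,
    condition = condition,
    duration_s = duration,
    target_rpm = target_rpm,
    initial_speed_window_reps = tab$window,
    nominal_interval_s = nominal
  ), class = "exercise_protocol")
}

#' All six exercise-by-condition protocols
#'
#' @return a named list of the six [exercise_protocol()] objects, named
#'   `"squat_max"`, `"squat_const"`, ..., `"lunge_const"`.
#' @export
all_protocols <- function() {
  out <- list()
  for (ex in c("squat", "kneeup", "lunge"))
    for (cond in c("max", "const"))
      out[[paste(ex, cond, sep = "_")]] <- exercise_protocol(ex, cond)
  out
}

#' @export
print.exercise_protocol <- function(x, ...) {
  pace <- if (is.na(x$target_rpm)) "free pace" else
    sprintf("%g RPM", x$target_rpm)
  cat(sprintf("<exercise_protocol> %s / %s: %g s, %s, IS window %d reps\n",
              x$exercise, x$condition, x$duration_s, pace,
              x$initial_speed_window_reps))
  invisible(x)
}
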