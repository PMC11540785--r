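#' Number of repetitions
#'
#' @param series a [rep_series()].
#' @return count of detected repetition peaks (0 for an empty series).
#' @export
number_of_repetitions <- function(series) {
  stopifnot(inherits(series, "rep_series"))
  length(series$peak_times)
}

#' Initial speed over the opening repetitions
#'
#' Mean repetition speed, in repetitions per 10 s, over the first
#' `window_reps` intervals (or all available intervals when fewer). With
#' fewer than two detected peaks the metric is undefined and `NA` is
#' returned, so missingness propagates instead of masquerading as zero.
#'
#' @param series a [rep_series()].
#' @param window_reps number of opening repetitions to average (10 for
#'   squat and lunge, 30 for knee-up).
#' @return speed in reps per 10 s, or `NA_real_`.
#' @export
initial_speed <- function(series, window_reps) {
  stopifnot(inherits(series, "rep_series"), window_reps >= 1)
  if (length(series$peak_times) < 2L) return(NA_real_)
  k <- min(window_reps, length(series$intervals))
  mean(series$speeds_per10s[seq_len(k)])
}

#' Constant-speed-zone segmentation
#'
#' An interval deviates when it differs from the metronome target interval
#' (60/`target_rpm`) by more than `rel_tol` of that target. The constant
#' zone ends at the first run of `persistence` consecutive deviating
#' intervals; repetitions before that boundary count toward the zone. When
#' no such run exists the zone spans the whole series. With the very first
#' `persistence` intervals deviating the zone holds only the first peak
#' (one repetition precedes any compliant interval).
#'
#' @param series a [rep_series()].
#' @param target_rpm metronome cadence, repetitions per minute (> 0).
#' @param rel_tol relative tolerance on the interval (0 < rel_tol < 1),
#'   default 0.10.
#' @param persistence consecutive deviating intervals required to end the
#'   zone (>= 1), default 3.
#' @return list of class `"zone_segmentation"`: `constant_zone_reps`,
#'   `constant_zone_end_index` (first rep index beyond the zone, `NA` when
#'   the zone spans the series), `deviation_flags` (per interval).
#' @export
constant_speed_zone <- function(series, target_rpm, rel_tol = 0.10,
                                persistence = 3) {
  stopifnot(inherits(series, "rep_series"))
  if (!is.numeric(target_rpm) || target_rpm <= 0)
    stop("constant_speed_zone: target_rpm must be positive")
  if (rel_tol <= 0 || rel_tol >= 1)
    stop("constant_speed_zone: rel_tol must lie in (0, 1)")
  if (persistence < 1) stop("constant_speed_zone: persistence must be >= 1")
  target <- 60 / target_rpm
  nrep <- length(series$peak_times)
  flags <- abs(series$intervals - target) > rel_tol * target
  boundary <- NA_integer_
  if (length(flags) >= persistence) {
    run <- 0L
    for (i in seq_along(flags)) {
      run <- if (flags[i]) run + 1L else 0L
      if (run == persistence) {
        boundary <- i - persistence + 1L
        break
      }
    }
  }
  cz <- if (is.na(boundary)) nrep else boundary
  structure(list(constant_zone_reps = cz,
                 constant_zone_end_index = if (is.na(boundary)) NA_integer_
                 else boundary + 1L,
                 deviation_flags = flags),
            class = "zone_segmentation")
}

# windows for the amplitude/iEMG deltas: first and last `window` seconds
delta_windows <- function(trace, window) {
  n <- length(trace$samples)
  w <- round(window * trace$rate)
  if (n < 2 * w) return(NULL)
  list(first = trace$samples[seq_len(w)],
       last = trace$samples[seq.int(n - w + 1L, n)],
       w = w)
}

#' sEMG amplitude change between the opening and closing window
#'
#' RMS amplitude over the final `window` seconds minus RMS over the initial
#' `window` seconds of an MVIC-normalized envelope. A positive value means
#' the muscle worked harder late in the bout, the classic sub-maximal
#' fatigue signature.
#'
#' @param trace an envelope or MVIC-normalized [signal_trace()].
#' @param window window length, s (default 10); the trace must span at
#'   least two windows, otherwise `NA` is returned.
#' @return amplitude delta in the trace's units, or `NA_real_`.
#' @export
semg_amplitude_delta <- function(trace, window = 10) {
  stopifnot(inherits(trace, "signal_trace"))
  wins <- delta_windows(trace, window)
  if (is.null(wins)) return(NA_real_)
  sqrt(mean(wins$last^2)) - sqrt(mean(wins$first^2))
}

#' iEMG change between the opening and closing window
#'
#' Trapezoidal time integral of the rectified MVIC-normalized signal over
#' the final `window` seconds minus the same integral over the initial
#' `window` seconds.
#'
#' @inheritParams semg_amplitude_delta
#' @return iEMG delta (MVIC units x s), or `NA_real_`.
#' @export
iemg_delta <- function(trace, window = 10) {
  stopifnot(inherits(trace, "signal_trace"))
  wins <- delta_windows(trace, window)
  if (is.null(wins)) return(NA_real_)
  dt <- 1 / trace$rate
  tgrid <- dt * (seq_len(wins$w) - 1)
  pracma::trapz(tgrid, abs(wins$last)) - pracma::trapz(tgrid, abs(wins$first))
}

# average a per-channel metric over the 8 MVIC-normalized envelopes
channel_mean <- function(envelopes, fn, ...) {
  vals <- vapply(envelopes, fn, numeric(1), ...)
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Names of the 27 performance-metric columns
#'
#' Repetition count (NR), initial speed (IS), sEMG amplitude delta and
#' iEMG delta under both conditions for each exercise, plus one
#' constant-speed-zone (CZ) count per exercise.
#'
#' @return character vector of length 27.
#' @export
metric_names <- function() {
  ex <- c("Squat", "Kneeup", "Lunge")
  c(paste0(rep(ex, each = 2), "_NR_", c("Max", "Const")),
    paste0(rep(ex, each = 2), "_IS_", c("Max", "Const")),
    paste0(ex, "_CZ"),
    paste0(rep(ex, each = 2), "_sEMG_amp_", c("Max", "Const")),
    paste0(rep(ex, each = 2), "_sEMG_iEMG_", c("Max", "Const")))
}

# metrics for one session: returns a named list
session_metrics <- function(session, rel_tol = 0.10, persistence = 3,
                            delta_window = 10, envelope_window = 0.1,
                            mains_freq = 60) {
  prot <- session$protocol
  ex <- c(squat = "Squat", kneeup = "Kneeup", lunge = "Lunge")[[prot$exercise]]
  cond <- c(max = "Max", const = "Const")[[prot$condition]]
  series <- detect_rep_peaks(session$torque, prot)
  out <- list()
  out[[paste0(ex, "_NR_", cond)]] <- number_of_repetitions(series)
  out[[paste0(ex, "_IS_", cond)]] <-
    initial_speed(series, prot$initial_speed_window_reps)
  if (prot$condition == "const")
    out[[paste0(ex, "_CZ")]] <-
      constant_speed_zone(series, prot$target_rpm, rel_tol,
                          persistence)$constant_zone_reps
  envs <- lapply(session$semg, process_semg, ref = session$mvic,
                 mains_freq = mains_freq, window = envelope_window)
  out[[paste0(ex, "_sEMG_amp_", cond)]] <-
    channel_mean(envs, semg_amplitude_delta, window = delta_window)
  out[[paste0(ex, "_sEMG_iEMG_", cond)]] <-
    channel_mean(envs, iemg_delta, window = delta_window)
  out
}

#' Build the participants-by-metrics table
#'
#' Computes all 27 performance metrics from each participant's sessions.
#' A missing session leaves its metrics `NA` (with a warning) but keeps the
#' participant's row.
#'
#' @param sessions named list: one entry per participant (named by
#'   participant id), each a list of `exo_session` objects.
#' @param rel_tol,persistence constant-speed-zone parameters.
#' @param delta_window amplitude/iEMG window, s.
#' @param envelope_window moving-RMS window, s.
#' @param mains_freq notch frequency, Hz.
#' @return data.frame: `id` plus the 27 [metric_names()] columns.
#' @export
build_metric_table <- function(sessions, rel_tol = 0.10, persistence = 3,
                               delta_window = 10, envelope_window = 0.1,
                               mains_freq = 60) {
  stopifnot(is.list(sessions), length(sessions) >= 1)
  cols <- metric_names()
  rows <- lapply(names(sessions), function(pid) {
    row <- stats::setNames(as.list(rep(NA_real_, length(cols))), cols)
    got <- character(0)
    for (s in sessions[[pid]]) {
      m <- session_metrics(s, rel_tol, persistence, delta_window,
                           envelope_window, mains_freq)
      row[names(m)] <- m
      got <- c(got, paste(s$protocol$exercise, s$protocol$condition))
    }
    missing <- setdiff(
      as.vector(outer(c("squat", "kneeup", "lunge"), c("max", "const"),
                      paste)), got)
    if (length(missing))
      warning(sprintf("participant %s: missing session(s) %s", pid,
                      paste(missing, collapse = ", ")), call. = FALSE)
    cbind(data.frame(id = pid, stringsAsFactors = FALSE),
          as.data.frame(row, check.names = FALSE))
  })
  do.call(rbind, rows)
}
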