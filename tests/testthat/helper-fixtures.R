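# shared fixtures: short custom protocols and probe signals

# a protocol object with arbitrary duration/pace, for fast signal tests
make_protocol <- function(exercise = "squat", condition = "const",
                          duration = 10, rpm = 60, window = 10,
                          nominal = if (!is.na(rpm)) 60 / rpm else 1.18) {
  structure(list(exercise = exercise, condition = condition,
                 duration_s = duration, target_rpm = rpm,
                 initial_speed_window_reps = window,
                 nominal_interval_s = nominal),
            class = "exercise_protocol")
}

sine_trace <- function(freq, rate = 2000, duration = 2, amp = 1) {
  t <- seq(0, duration, by = 1 / rate)
  signal_trace(amp * sin(2 * pi * freq * t), rate, "probe", "semg_raw")
}

rms <- function(x) sqrt(mean(x^2))

# a rep_series from explicit intervals, first peak at t0
series_from_intervals <- function(intervals, t0 = 0.5) {
  rep_series(cumsum(c(t0, intervals)))
}

# quiet config for noiseless ground-truth tests
noiseless_config <- function(...) {
  simulation_config(noise_sd = 0, mains_amp = 0, ...)
}

# brute-force constant-speed-zone oracle: scan every window of
# `persistence` consecutive deviating intervals
cz_oracle <- function(intervals, target, rel_tol, persistence) {
  nrep <- length(intervals) + 1L
  flags <- abs(intervals - target) > rel_tol * target
  if (length(flags) >= persistence)
    for (i in seq_len(length(flags) - persistence + 1L))
      if (all(flags[i:(i + persistence - 1L)])) return(i)
  nrep
}
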