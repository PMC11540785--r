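test_that("notch filter removes the mains line and spares the passband", {
  # steady-state attenuation: central section, away from edge transients
  mains <- sine_trace(60, duration = 10)
  out <- notch_filter(mains, 60)
  core <- 4001:16000
  expect_lt(rms(out$samples[core]), 0.1 * rms(mains$samples[core]))

  low <- sine_trace(5, duration = 10)
  keep <- notch_filter(low, 60)
  expect_lt(abs(rms(keep$samples[core]) - rms(low$samples[core])) /
              rms(low$samples[core]), 0.05)

  # periodogram of filtered white noise: >= 20 dB down in the 60 Hz bin
  # relative to neighboring passband bins
  set.seed(2)
  noise <- signal_trace(rnorm(2^15), 2000, "probe", "semg_raw")
  filtered <- notch_filter(noise, 60)
  keep_idx <- 2001:30000 # drop edge transients before the FFT
  spec <- Mod(fft(filtered$samples[keep_idx]))^2
  freqs <- (seq_along(spec) - 1) * 2000 / length(spec)
  at <- function(f, hw) mean(spec[abs(freqs - f) <= hw])
  expect_gt(10 * log10(mean(c(at(50, 2), at(70, 2))) / at(60, 0.25)), 20)

  expect_error(notch_filter(sine_trace(60), mains_freq = 1200), "Nyquist")
})

test_that("band-pass filter keeps 20-500 Hz and rejects out-of-band energy", {
  drift <- sine_trace(5)
  expect_lt(rms(bandpass_filter(drift)$samples), 0.1 * rms(drift$samples))

  mid <- sine_trace(100)
  expect_lt(abs(rms(bandpass_filter(mid)$samples) - rms(mid$samples)) /
              rms(mid$samples), 0.1)

  hi <- sine_trace(800)
  atten <- 20 * log10(rms(hi$samples) / rms(bandpass_filter(hi)$samples))
  expect_gt(atten, 20)

  expect_error(bandpass_filter(sine_trace(100), high = 1500), "Nyquist")
})

test_that("filters are linear", {
  set.seed(3)
  x <- signal_trace(rnorm(4000), 2000, "probe", "semg_raw")
  ax <- signal_trace(3.7 * x$samples, 2000, "probe", "semg_raw")
  expect_equal(notch_filter(ax, 60)$samples,
               3.7 * notch_filter(x, 60)$samples, tolerance = 1e-9)
  expect_equal(bandpass_filter(ax)$samples,
               3.7 * bandpass_filter(x)$samples, tolerance = 1e-9)
})

test_that("moving-RMS envelope matches analytic levels", {
  const <- signal_trace(rep(-2.5, 1000), 2000, "probe", "semg_raw")
  expect_equal(rectified_envelope(const, 0.05)$samples, rep(2.5, 1000))

  zero <- signal_trace(rep(0, 500), 2000, "probe", "semg_raw")
  expect_equal(rectified_envelope(zero, 0.01)$samples, rep(0, 500))

  # window much longer than the period: RMS of a unit sinusoid is 1/sqrt(2)
  s <- sine_trace(100, duration = 1)
  env <- rectified_envelope(s, 0.5)
  mid <- env$samples[500:1500]
  expect_lt(max(abs(mid - 1 / sqrt(2))), 0.01)

  expect_error(rectified_envelope(zero, 1), "longer than the trace")
  expect_error(rectified_envelope(zero, 1e-4), "2 samples")
})

test_that("MVIC normalization is the documented affine map", {
  ref <- mvic_reference(semg_max = c(probe = 1.1),
                        semg_rest = c(probe = 0.1))
  tr <- function(v) signal_trace(rep(v, 10), 2000, "probe", "envelope")
  expect_equal(mvic_normalize(tr(0.1), ref)$samples, rep(0, 10))
  expect_equal(mvic_normalize(tr(1.1), ref)$samples, rep(1, 10))
  expect_equal(mvic_normalize(tr(0.6), ref)$samples, rep(0.5, 10))
  expect_equal(mvic_normalize(tr(0.6), ref)$kind, "semg_mvic")

  # order-preserving on an arbitrary envelope
  set.seed(4)
  env <- signal_trace(abs(rnorm(100)), 2000, "probe", "envelope")
  out <- mvic_normalize(env, ref)
  expect_identical(order(out$samples), order(env$samples))

  degen <- list(semg_max = c(probe = 0.5), semg_rest = c(probe = 0.5))
  expect_error(mvic_normalize(tr(0.6), degen), "probe")
  expect_error(mvic_reference(c(a = 1), c(a = 1.5)), "exceed")
})

test_that("repetition peaks are recovered from planted sessions", {
  # noiseless metronome squat: 90 reps at exactly 60 RPM
  cfg <- noiseless_config(n_participants = 2, master_seed = 3)
  coh <- generate_cohort(cfg)
  relaxed <- fatigue_model(onset_time = 1000, drift_noise_sd = 0)
  s <- generate_session(coh[1, ], exercise_protocol("squat", "const"),
                        relaxed, cfg)
  rs <- detect_rep_peaks(s$torque, s$protocol)
  expect_equal(length(rs$peak_times), 90)
  expect_lt(max(abs(rs$intervals - 1.0)), 1 / cfg$sampling_rate + 1e-12)
  expect_lt(max(abs(rs$peak_times - s$rep_times)), 1 / cfg$sampling_rate)

  # flat trace: empty series with a warning, not an error
  flat <- signal_trace(rep(0, 1000), 2000, "torque", "torque")
  expect_warning(empty <- detect_rep_peaks(flat, s$protocol), "no")
  expect_equal(length(empty$peak_times), 0)

  # default-noise session: exact count, timing within 25 ms
  cfgn <- simulation_config(n_participants = 2, master_seed = 9)
  cohn <- generate_cohort(cfgn)
  sn <- generate_session(cohn[1, ], exercise_protocol("squat", "max"),
                         fatigue_model(), cfgn)
  rsn <- detect_rep_peaks(sn$torque, sn$protocol)
  expect_equal(length(rsn$peak_times), length(sn$rep_times))
  expect_lte(max(abs(rsn$peak_times - sn$rep_times)), 0.025)
})

test_that("torque- and sEMG-derived repetition series agree", {
  cfg <- simulation_config(n_participants = 2, master_seed = 13)
  coh <- generate_cohort(cfg)
  s <- generate_session(coh[1, ], exercise_protocol("squat", "max"),
                        fatigue_model(), cfg)
  torque_rs <- detect_rep_peaks(s$torque, s$protocol)
  env <- process_semg(s$semg$RF_R, s$mvic, cfg$mains_freq)
  semg_rs <- detect_rep_peaks(env, s$protocol)
  expect_gte(series_agreement(torque_rs, semg_rs, 0.15), 0.95)

  expect_equal(series_agreement(torque_rs, torque_rs, 0.1), 1.0)
  shifted <- rep_series(torque_rs$peak_times + 100)
  expect_equal(series_agreement(torque_rs, shifted, 0.1), 0.0)
  expect_error(series_agreement(torque_rs, semg_rs, tol = 0), "positive")
})

test_that("speed fields of a repetition series are mutually consistent", {
  rs <- series_from_intervals(c(1, 1.25, 0.8, 2))
  expect_equal(rs$speeds_per10s, rs$speeds_rpm / 6)
  expect_equal(rs$speeds_rpm, 60 / rs$intervals)
  expect_error(rep_series(c(2, 1)), "ascending")
})
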