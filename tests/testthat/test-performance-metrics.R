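test_that("repetition count and initial speed follow their definitions", {
  rs <- series_from_intervals(rep(1.0, 89))
  expect_equal(number_of_repetitions(rs), 90)
  expect_equal(number_of_repetitions(rep_series(numeric(0))), 0)

  expect_equal(initial_speed(rs, 10), 10.0) # 60 RPM = 10 reps per 10 s
  alt <- series_from_intervals(rep(c(1.0, 1.25), 5))
  expect_equal(initial_speed(alt, 10), 9.0) # mean of {10, 8}
  expect_true(is.na(initial_speed(rep_series(1.5), 10)))

  # fewer intervals than the window: average what is available
  short <- series_from_intervals(c(1, 1))
  expect_equal(initial_speed(short, 10), 10.0)
})

test_that("metronome-paced knee-up initial speed equals the planted cadence", {
  cfg <- simulation_config(n_participants = 2, master_seed = 21)
  coh <- generate_cohort(cfg)
  relaxed <- fatigue_model(onset_time = 1e4, drift_noise_sd = 0)
  plan <- plant_session_reps(coh[1, ], exercise_protocol("kneeup", "const"),
                             relaxed, cfg)
  rs <- rep_series(plan$peak_times)
  expect_equal(initial_speed(rs, 30), 22.0, tolerance = 1e-9) # 132 RPM / 6
})

test_that("constant-speed zone follows the persistence rule", {
  on_target <- series_from_intervals(rep(1.0, 20))
  z <- constant_speed_zone(on_target, 60)
  expect_equal(z$constant_zone_reps, 21)
  expect_true(is.na(z$constant_zone_end_index))

  # first `persistence` intervals already deviating: only the first peak
  bad_start <- series_from_intervals(rep(1.25, 10))
  expect_equal(constant_speed_zone(bad_start, 60, 0.1, 3)$constant_zone_reps,
               1)

  # isolated deviations shorter than the persistence run do not end the zone
  iso <- series_from_intervals(c(1, 1, 1.3, 1, 1.3, 1.3, 1, 1, 1))
  expect_equal(constant_speed_zone(iso, 60, 0.1, 3)$constant_zone_reps, 10)

  expect_error(constant_speed_zone(on_target, -60), "target_rpm")
  expect_error(constant_speed_zone(on_target, 60, rel_tol = 1.5), "rel_tol")
})

test_that("constant-speed zone matches the brute-force oracle", {
  set.seed(99)
  for (i in 1:200) {
    n_iv <- sample(1:40, 1)
    iv <- 60 / 60 * exp(rnorm(n_iv, 0, 0.15))
    pers <- sample(1:4, 1)
    tol <- runif(1, 0.05, 0.3)
    got <- constant_speed_zone(series_from_intervals(iv), 60, tol,
                               pers)$constant_zone_reps
    expect_equal(got, cz_oracle(iv, 1.0, tol, pers))
  }
})

test_that("sEMG amplitude delta reflects the planted drift", {
  rate <- 2000
  # stationary signal: delta near zero
  set.seed(5)
  x <- rnorm(25 * rate, 0, 0.5)
  st <- signal_trace(x, rate, "probe", "semg_mvic")
  expect_lt(abs(semg_amplitude_delta(st, 10)), 0.02)

  # amplitude doubled between windows with unit initial RMS: delta ~ +1
  gain <- c(rep(1, 10 * rate), seq(1, 2, length.out = 5 * rate),
            rep(2, 10 * rate))
  ramp <- x / 0.5 * gain
  expect_equal(semg_amplitude_delta(signal_trace(ramp, rate, "p",
                                                 "semg_mvic"), 10),
               1, tolerance = 0.05)

  # too-short trace: undefined, not zero
  expect_true(is.na(semg_amplitude_delta(signal_trace(x[1:rate], rate, "p",
                                                      "semg_mvic"), 10)))

  # fatiguing synthetic session: delta sign equals the configured drift sign
  cfg <- simulation_config(n_participants = 2, master_seed = 31)
  coh <- generate_cohort(cfg)
  s <- generate_session(coh[1, ], exercise_protocol("squat", "const"),
                        fatigue_model(emg_amp_drift = 0.4), cfg)
  envs <- lapply(s$semg, process_semg, ref = s$mvic)
  deltas <- vapply(envs, semg_amplitude_delta, numeric(1), window = 10)
  expect_gt(mean(deltas), 0)
})

test_that("iEMG delta matches rectangle and dense-grid oracles", {
  rate <- 2000
  lvl <- signal_trace(c(rep(0.3, 10 * rate), rep(0.3, 5 * rate),
                        rep(0.6, 10 * rate)), rate, "p", "semg_mvic")
  expect_equal(iemg_delta(lvl, 10), 0.3 * 10, tolerance = 1e-3)

  const <- signal_trace(rep(0.4, 25 * rate), rate, "p", "semg_mvic")
  expect_equal(iemg_delta(const, 10), 0, tolerance = 1e-12)

  # smooth analytic signal: trapezoid at 2 kHz vs oracle at 20 kHz
  f <- function(t) 0.4 + 0.2 * sin(2 * pi * 0.31 * t) + 0.1 * cos(2 * pi * 0.07 * t)
  t1 <- seq(0, 25, by = 1 / rate)
  t2 <- seq(0, 25, by = 1 / (10 * rate))
  coarse <- iemg_delta(signal_trace(f(t1), rate, "p", "semg_mvic"), 10)
  fine <- iemg_delta(signal_trace(f(t2), 10 * rate, "p", "semg_mvic"), 10)
  expect_lt(abs(coarse - fine) / abs(fine), 0.001)
})

test_that("metric table assembles all 27 metrics with honest missingness", {
  expect_length(metric_names(), 27)

  cfg <- noiseless_config(n_participants = 2, master_seed = 17)
  coh <- generate_cohort(cfg)
  fm <- fatigue_model(drift_noise_sd = 0)
  prots <- all_protocols()
  sessions <- list()
  for (i in 1:2) {
    keep <- if (i == 2) setdiff(names(prots), "lunge_const") else names(prots)
    sessions[[coh$id[i]]] <- lapply(prots[keep], function(p)
      generate_session(coh[i, ], p, fm, cfg))
  }
  expect_warning(tab <- build_metric_table(sessions), "lunge const")
  expect_equal(nrow(tab), 2)
  expect_setequal(setdiff(names(tab), "id"), metric_names())

  # noiseless sessions: detected counts equal planted counts
  for (i in 1:2) {
    plan <- plant_session_reps(coh[i, ], prots$squat_max, fm, cfg)
    expect_equal(tab$Squat_NR_Max[i], length(plan$peak_times))
  }
  # the dropped session is missing, its siblings are not
  expect_true(is.na(tab$Lunge_NR_Const[2]))
  expect_false(is.na(tab$Lunge_NR_Max[2]))
  expect_false(is.na(tab$Squat_NR_Const[2]))

  # constant-condition invariant: CZ never exceeds NR
  expect_true(all(tab$Squat_CZ <= tab$Squat_NR_Const, na.rm = TRUE))

  # permutation equivariance over participants
  tab_rev <- suppressWarnings(build_metric_table(rev(sessions)))
  expect_equal(tab_rev[order(tab_rev$id), , drop = FALSE],
               tab[order(tab$id), , drop = FALSE],
               ignore_attr = "row.names")
})

test_that("free-pace repetition count and initial speed co-vary with strength", {
  cfg <- simulation_config(n_participants = 30, master_seed = 23)
  coh <- generate_cohort(cfg)
  prot <- exercise_protocol("squat", "max")
  stats <- t(vapply(seq_len(30), function(i) {
    plan <- plant_session_reps(coh[i, ], prot, fatigue_model(), cfg)
    rs <- rep_series(plan$peak_times)
    c(nr = number_of_repetitions(rs),
      is = initial_speed(rs, prot$initial_speed_window_reps))
  }, numeric(2)))
  expect_gt(cor(stats[, "nr"], stats[, "is"]), 0.5)
})
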