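#' Fatigue model for planted repetition sequences
#'
#' Describes how a simulated participant fatigues within a session: the
#' inter-repetition interval is held at the paced (or strength-derived)
#' value until `onset_time`, after which each successive interval lengthens
#' by a fixed fraction per repetition; sEMG burst amplitude drifts linearly
#' from the first to the last repetition.
#'
#' @param onset_time fatigue onset, seconds from session start. Onset beyond
#'   the session duration means no variable-speed zone.
#' @param interval_drift_rate fractional lengthening of the inter-rep
#'   interval per repetition after onset (e.g. 0.03 = 3\% per rep).
#' @param emg_amp_drift fractional change in sEMG burst amplitude from the
#'   first to the last repetition; positive values model the amplitude rise
#'   classically seen in sub-maximal fatiguing contractions.
#' @param drift_noise_sd standard deviation of multiplicative log-normal
#'   noise applied to every planted interval (0 = perfectly metronomic).
#' @return a list of class `"fatigue_model"`.
#' @export
fatigue_model <- function(onset_time = 40,
                          interval_drift_rate = 0.03,
                          emg_amp_drift = 0.3,
                          drift_noise_sd = 0.02) {
  if (!is.numeric(onset_time) || length(onset_time) != 1L || onset_time < 0)
    stop("fatigue_model: 'onset_time' must be a single non-negative number")
  if (!is.numeric(interval_drift_rate) || interval_drift_rate < 0)
    stop("fatigue_model: 'interval_drift_rate' must be non-negative")
  if (!is.numeric(drift_noise_sd) || drift_noise_sd < 0)
    stop("fatigue_model: 'drift_noise_sd' must be non-negative")
  structure(list(onset_time = onset_time,
                 interval_drift_rate = interval_drift_rate,
                 emg_amp_drift = emg_amp_drift,
                 drift_noise_sd = drift_noise_sd),
            class = "fatigue_model")
}

#' Default per-parameter loadings of muscle parameters on latent strength
#'
#' Each raw muscle parameter is generated as
#' `intercept + loading * latent_strength + N(0, noise_sd)`.
#' Units: vertical jump in cm, one-repetition-maximum leg extension/curl in
#' kg, isometric leg extension/curl in N.
#'
#' @return a data.frame with columns `parameter`, `intercept`, `loading`,
#'   `noise_sd`.
#' @export
default_muscle_loadings <- function() {
  data.frame(
    parameter = c("vj", "rm_le", "rm_lc", "iso_le", "iso_lc"),
    intercept = c(38, 55, 35, 400, 250),
    loading   = c(6, 12, 8, 80, 50),
    noise_sd  = c(2, 4, 3, 30, 20),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic cohorts and sessions
#'
#' Collects every tunable of the synthetic-data generator. The defaults are
#' calibrated so that the planted squat initial speed (reps per 10 s, mean
#' 8.47, SD 2.0) correlates 0.873 with the composite strength index at the
#' population level, matching the strength-to-speed relationship the
#' regression model is designed to recover.
#'
#' @param n_participants cohort size (>= 2).
#' @param sampling_rate signal sampling rate in Hz (> 1000, so the 500 Hz
#'   band-pass edge stays below Nyquist); default 2000.
#' @param mains_freq power-line interference frequency in Hz (default 60).
#' @param mains_amp amplitude of the mains sinusoid added to raw sEMG (a.u.).
#' @param noise_sd SD of broadband white noise added to raw sEMG (a.u.).
#' @param weight_mean,weight_sd body weight moments, kg (66.43 +/- 9.8).
#' @param height_mean,height_sd stature moments, cm (170.93 +/- 8.5).
#' @param age_mean,age_sd age moments, years (26.1 +/- 2.8).
#' @param male_prob probability of male sex (19/30).
#' @param strength_to_speed list with `intercept`, `slope`, `noise_sd`
#'   mapping latent strength (z) to squat initial speed in reps per 10 s.
#'   The default slope 1.959 and noise SD 0.4027 split the total speed SD of
#'   2.0 so that corr(speed, latent) * corr(latent, composite) = 0.873 under
#'   the default muscle loadings.
#' @param target_correlation intended population correlation between squat
#'   initial speed and the composite strength index (default 0.873).
#' @param muscle_param_loadings data.frame as [default_muscle_loadings()].
#' @param pace_scale named per-exercise multipliers applied to the squat
#'   speed mapping to set free-pace speeds for knee-up and lunge.
#' @param fatigue_onset_per_strength shift of fatigue onset per latent SD,
#'   seconds (stronger participants fatigue later).
#' @param torque_amp peak flexion torque in Nm (device ceiling 10 Nm).
#' @param emg_burst_amp baseline sEMG burst envelope amplitude (a.u.).
#' @param master_seed integer seed governing all randomness.
#' @return a list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_participants = 30,
                              sampling_rate = 2000,
                              mains_freq = 60,
                              mains_amp = 0.05,
                              noise_sd = 0.02,
                              weight_mean = 66.43, weight_sd = 9.8,
                              height_mean = 170.93, height_sd = 8.5,
                              age_mean = 26.1, age_sd = 2.8,
                              male_prob = 19 / 30,
                              strength_to_speed = list(intercept = 8.47,
                                                       slope = 1.959,
                                                       noise_sd = 0.4027),
                              target_correlation = 0.873,
                              muscle_param_loadings = default_muscle_loadings(),
                              pace_scale = c(squat = 1, kneeup = 24 / 8.47,
                                             lunge = 9 / 8.47),
                              fatigue_onset_per_strength = 5,
                              torque_amp = 8,
                              emg_burst_amp = 0.5,
                              master_seed = 20260924) {
  bad <- function(field, msg)
    stop(sprintf("simulation_config: invalid '%s': %s", field, msg))
  if (!is.numeric(n_participants) || n_participants < 2)
    bad("n_participants", "must be >= 2")
  if (!is.numeric(sampling_rate) || sampling_rate <= 1000)
    bad("sampling_rate", "must exceed 1000 Hz to honor the 500 Hz band edge")
  if (!is.numeric(target_correlation) ||
      target_correlation <= 0 || target_correlation >= 1)
    bad("target_correlation", "must lie strictly between 0 and 1")
  if (weight_sd < 0) bad("weight_sd", "must be non-negative")
  need <- c("intercept", "slope", "noise_sd")
  if (!all(need %in% names(strength_to_speed)))
    bad("strength_to_speed", "needs intercept, slope, noise_sd")
  req_cols <- c("parameter", "intercept", "loading", "noise_sd")
  if (!all(req_cols %in% names(muscle_param_loadings)))
    bad("muscle_param_loadings",
        "needs columns parameter, intercept, loading, noise_sd")
  structure(list(
    n_participants = as.integer(n_participants),
    sampling_rate = sampling_rate,
    mains_freq = mains_freq,
    mains_amp = mains_amp,
    noise_sd = noise_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    height_mean = height_mean, height_sd = height_sd,
    age_mean = age_mean, age_sd = age_sd,
    male_prob = male_prob,
    strength_to_speed = strength_to_speed,
    target_correlation = target_correlation,
    muscle_param_loadings = muscle_param_loadings,
    pace_scale = pace_scale,
    fatigue_onset_per_strength = fatigue_onset_per_strength,
    torque_amp = torque_amp,
    emg_burst_amp = emg_burst_amp,
    master_seed = as.integer(master_seed)
  ), class = "simulation_config")
}

#' Calibrated squat-only generative model
#'
#' The reduced bivariate model behind the squat-only regression: squat
#' initial speed x ~ N(mean, sd) in reps per 10 s, and composite strength
#' y = slope * x + intercept + N(0, residual_sd). The default residual SD is
#' chosen so that corr(x, y) equals `beta`; with slope 0.659, intercept
#' -5.58, predictor SD 2.0 and beta 0.873 this gives residual SD 0.7363 and
#' a closed-form slope standard error of 0.068 at n = 30.
#'
#' @param slope,intercept linear map from speed to composite strength.
#' @param x_mean,x_sd predictor moments (reps per 10 s).
#' @param beta intended standardized coefficient (= correlation).
#' @return list of class `"squat_only_config"` including the implied
#'   `residual_sd` and `y_sd`.
#' @export
squat_only_config <- function(slope = 0.659, intercept = -5.58,
                              x_mean = 8.47, x_sd = 2.0, beta = 0.873) {
  stopifnot(x_sd > 0, beta > 0, beta < 1)
  y_sd <- abs(slope) * x_sd / beta
  residual_sd <- y_sd * sqrt(1 - beta^2)
  structure(list(slope = slope, intercept = intercept,
                 x_mean = x_mean, x_sd = x_sd, beta = beta,
                 y_sd = y_sd, residual_sd = residual_sd),
            class = "squat_only_config")
}

#' Simulate a cohort from the squat-only generative model
#'
#' @param n cohort size.
#' @param config a [squat_only_config()].
#' @return data.frame with columns `squat_is_max` (reps per 10 s) and
#'   `total_performance` (z-sum).
#' @export
simulate_squat_cohort <- function(n, config = squat_only_config()) {
  stopifnot(inherits(config, "squat_only_config"), n >= 2)
  x <- stats::rnorm(n, config$x_mean, config$x_sd)
  y <- config$slope * x + config$intercept +
    stats::rnorm(n, 0, config$residual_sd)
  data.frame(squat_is_max = x, total_performance = y)
}

#' Derive a reproducible child seed from a master seed and a stage name
#'
#' Stable string hash (polynomial in the UTF-8 bytes) folded with the master
#' seed modulo 2^31 - 1, so each pipeline stage draws from an independent,
#' reproducible stream.
#'
#' @param master_seed integer.
#' @param stage character stage name.
#' @return integer in [1, 2^31 - 2].
#' @export
child_seed <- function(master_seed, stage) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 1) + 1)
}
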