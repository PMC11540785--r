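# sEMG montage: four muscles per thigh, both legs
semg_channels <- function() {
  c("RF_L", "RF_R", "VL_L", "VL_R", "BF_L", "BF_R", "ST_L", "ST_R")
}

# relative burst amplitude per channel (rectus femoris strongest driver in
# hip-flexion resistance work; left side slightly attenuated for asymmetry)
channel_scales <- function() {
  base <- c(RF = 1.0, VL = 0.9, BF = 0.8, ST = 0.7)
  side <- c(L = 0.95, R = 1.0)
  ch <- semg_channels()
  vapply(ch, function(x) {
    parts <- strsplit(x, "_")[[1]]
    unname(base[parts[1]] * side[parts[2]])
  }, numeric(1))
}

#' Plant the repetition-time sequence for one session
#'
#' Produces flexion-peak times on a fixed pace (metronome target for the
#' constant condition, strength-derived free pace for the max condition)
#' until fatigue onset, after which each interval lengthens geometrically by
#' `interval_drift_rate` per repetition; every interval carries
#' multiplicative log-normal noise of SD `drift_noise_sd`. Uses the current
#' RNG stream.
#'
#' @param base_interval paced inter-repetition interval, s.
#' @param duration session duration, s.
#' @param fatigue a [fatigue_model()].
#' @param onset_shift additive shift of the fatigue onset, s (may be
#'   negative; effective onset is floored at 0).
#' @return list: `peak_times` (s), `intervals` (s, length = reps - 1).
#' @export
plant_rep_times <- function(base_interval, duration, fatigue, onset_shift = 0) {
  stopifnot(base_interval > 0, duration > 0, inherits(fatigue, "fatigue_model"))
  onset <- max(0, fatigue$onset_time + onset_shift)
  times <- numeric(0)
  t <- 0.6 * base_interval
  post <- 0L
  while (t <= duration - 0.1) {
    times <- c(times, t)
    if (t >= onset) post <- post + 1L
    step <- base_interval * (1 + fatigue$interval_drift_rate)^post
    if (fatigue$drift_noise_sd > 0)
      step <- step * exp(stats::rnorm(1, 0, fatigue$drift_noise_sd))
    t <- t + step
  }
  list(peak_times = times, intervals = diff(times))
}

#' Plant the repetition schedule of one participant's session
#'
#' The cheap deterministic core of [generate_session()]: derives the paced
#' interval (metronome target or strength-derived free pace), the fatigue
#' onset shift, and the planted repetition times, under the same
#' per-session child seed the signal synthesis uses. Useful when only the
#' ground-truth repetition structure is needed (e.g. large-cohort
#' calibration checks) without paying for 2000 Hz signal synthesis.
#'
#' @inheritParams generate_session
#' @return list: `peak_times`, `intervals`, `base_interval`.
#' @export
plant_session_reps <- function(profile, protocol, fatigue = fatigue_model(),
                               config = simulation_config()) {
  stopifnot(is.data.frame(profile), nrow(profile) == 1L)
  base <- session_base_interval(profile, protocol, config)
  onset_shift <- config$fatigue_onset_per_strength * profile$latent_strength
  seed <- child_seed(profile$seed,
                     paste("plan", protocol$exercise, protocol$condition,
                           sep = "_"))
  plan <- withr_seed(seed, plant_rep_times(base, protocol$duration_s,
                                           fatigue, onset_shift))
  plan$base_interval <- base
  plan
}

# paced interval for one participant row under one protocol
session_base_interval <- function(profile, protocol, config) {
  if (protocol$condition == "const") {
    60 / protocol$target_rpm
  } else {
    speed <- planted_initial_speed(profile, config) # reps per 10 s, squat scale
    scale <- config$pace_scale[[protocol$exercise]]
    10 / max(speed * scale, 0.5)
  }
}

#' MVIC normalization reference for one participant
#'
#' Per-channel maximum and resting envelope levels, standing in for the
#' reference recordings taken during the 1RM and isometric contraction
#' tests. The maximum scales with the participant's burst amplitude
#' (including fatigue headroom); rest is the broadband + mains noise floor.
#'
#' @param profile one-row data.frame from [generate_cohort()].
#' @param config a [simulation_config()].
#' @param fatigue a [fatigue_model()] (sets the amplitude headroom).
#' @return list of class `"mvic_reference"`: `semg_max`, `semg_rest`, named
#'   numeric vectors over the 8 channels.
#' @export
generate_mvic_reference <- function(profile, config = simulation_config(),
                                    fatigue = fatigue_model()) {
  amp <- config$emg_burst_amp * (1 + 0.15 * profile$latent_strength)
  peak <- amp * channel_scales() * (1 + max(0, fatigue$emg_amp_drift))
  rest <- sqrt(config$noise_sd^2 + config$mains_amp^2 / 2)
  structure(list(semg_max = 1.25 * peak,
                 semg_rest = stats::setNames(rep(rest, 8), semg_channels())),
            class = "mvic_reference")
}

#' Generate one synthetic exercise session
#'
#' Synthesizes the joint-torque trace and the eight raw sEMG channels for
#' one participant under one protocol, plus the planted ground-truth
#' repetition times. Torque is one positive raised-cosine lobe (flexion)
#' and one negative lobe (extension) per repetition cycle; each sEMG
#' channel is band-limited (20-450 Hz) carrier noise under a Gaussian
#' per-repetition burst envelope whose amplitude drifts with fatigue, plus
#' a mains sinusoid and white noise.
#'
#' @param profile one-row data.frame from [generate_cohort()].
#' @param protocol an [exercise_protocol()].
#' @param fatigue a [fatigue_model()].
#' @param config a [simulation_config()].
#' @return list of class `"exo_session"`: `torque` ([signal_trace()]),
#'   `semg` (named list of 8 raw traces), `rep_times` (planted flexion-peak
#'   times, s), `intervals`, `protocol`, `participant`, `mvic`
#'   (the participant's [generate_mvic_reference()]).
#' @export
generate_session <- function(profile, protocol, fatigue = fatigue_model(),
                             config = simulation_config()) {
  stopifnot(inherits(protocol, "exercise_protocol"),
            inherits(fatigue, "fatigue_model"),
            is.data.frame(profile), nrow(profile) == 1L)
  fs <- config$sampling_rate
  dur <- protocol$duration_s
  seed <- child_seed(profile$seed,
                     paste("signals", protocol$exercise, protocol$condition,
                           sep = "_"))
  plan <- plant_session_reps(profile, protocol, fatigue, config)
  base <- plan$base_interval

  withr_seed(seed, {
    tt <- plan$peak_times
    nrep <- length(tt)
    n <- round(dur * fs)
    tgrid <- (seq_len(n) - 1) / fs

    # torque: raised-cosine flexion (+) and extension (-) lobe per cycle
    iv <- if (nrep >= 2) c(plan$intervals, plan$intervals[nrep - 1]) else
      rep(base, max(nrep, 0))
    torque <- numeric(n)
    add_lobe <- function(center, width, amp) {
      i0 <- max(1L, ceiling((center - width / 2) * fs) + 1L)
      i1 <- min(n, floor((center + width / 2) * fs) + 1L)
      if (i0 > i1) return(invisible())
      tp <- tgrid[i0:i1]
      torque[i0:i1] <<- torque[i0:i1] +
        amp * 0.5 * (1 + cos(2 * pi * (tp - center) / width))
    }
    for (k in seq_len(nrep)) {
      w <- 0.35 * iv[k]
      add_lobe(tt[k], w, config$torque_amp)
      add_lobe(tt[k] + 0.5 * iv[k], w, -0.75 * config$torque_amp)
    }
    if (config$noise_sd > 0)
      torque <- torque + stats::rnorm(n, 0, config$noise_sd * config$torque_amp)

    # sEMG: Gaussian burst envelope * band-limited carrier + mains + noise
    amp0 <- config$emg_burst_amp * (1 + 0.15 * profile$latent_strength)
    drift <- fatigue$emg_amp_drift
    rep_amp <- if (nrep > 1)
      amp0 * (1 + drift * (seq_len(nrep) - 1) / (nrep - 1)) else rep(amp0, nrep)
    scales <- channel_scales()
    semg <- vector("list", 8)
    names(semg) <- semg_channels()
    bp <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
    for (ch in semg_channels()) {
      env <- numeric(n)
      for (k in seq_len(nrep)) {
        sdw <- 0.12 * iv[k]
        i0 <- max(1L, ceiling((tt[k] - 4 * sdw) * fs) + 1L)
        i1 <- min(n, floor((tt[k] + 4 * sdw) * fs) + 1L)
        if (i0 > i1) next
        tp <- tgrid[i0:i1]
        env[i0:i1] <- env[i0:i1] +
          rep_amp[k] * scales[[ch]] * exp(-(tp - tt[k])^2 / (2 * sdw^2))
      }
      carrier <- as.numeric(signal::filtfilt(bp, stats::rnorm(n)))
      crms <- sqrt(mean(carrier^2))
      if (crms > 0) carrier <- carrier / crms
      x <- env * carrier
      if (config$mains_amp > 0)
        x <- x + config$mains_amp *
          sin(2 * pi * config$mains_freq * tgrid + stats::runif(1, 0, 2 * pi))
      if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
      semg[[ch]] <- signal_trace(x, fs, channel = ch, kind = "semg_raw")
    }

    structure(list(
      torque = signal_trace(torque, fs, channel = "torque", kind = "torque"),
      semg = semg,
      rep_times = tt,
      intervals = plan$intervals,
      protocol = protocol,
      participant = profile$id,
      mvic = generate_mvic_reference(profile, config, fatigue)
    ), class = "exo_session")
  })
}

#' @export
print.exo_session <- function(x, ...) {
  cat(sprintf("<exo_session> %s %s/%s: %d planted reps, %d samples @ %g Hz\n",
              x$participant, x$protocol$exercise, x$protocol$condition,
              length(x$rep_times), length(x$torque$samples), x$torque$rate))
  invisible(x)
}

#' Write a session as a delimited text bundle
#'
#' One comment-headed CSV per session (`# rate_hz=`, `# exercise=` ... then
#' one row per sample, columns torque + 8 sEMG channels) plus a sidecar
#' `<path>_reps.csv` with the planted ground truth (`rep_index,peak_time_s`).
#'
#' @param session an `exo_session`.
#' @param path output file path for the signal bundle.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "exo_session"))
  chans <- c("torque", names(session$semg))
  hdr <- c(sprintf("# rate_hz=%g", session$torque$rate),
           sprintf("# exercise=%s", session$protocol$exercise),
           sprintf("# condition=%s", session$protocol$condition),
           sprintf("# participant=%s", session$participant),
           sprintf("# channels=%s", paste(chans, collapse = ",")))
  mat <- cbind(session$torque$samples,
               do.call(cbind, lapply(session$semg, `[[`, "samples")))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(signif(mat, 7), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  gt <- data.frame(rep_index = seq_along(session$rep_times),
                   peak_time_s = session$rep_times)
  utils::write.csv(gt, paste0(tools::file_path_sans_ext(path), "_reps.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a session bundle written by [write_session()]
#'
#' @param path signal bundle path.
#' @return list with `torque`, `semg`, `rep_times` (NULL when no sidecar),
#'   `exercise`, `condition`, `participant`, `rate`.
#' @export
read_session <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("read_session: missing header '", key, "'")
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  rate <- as.numeric(field("rate_hz"))
  chans <- strsplit(field("channels"), ",")[[1]]
  mat <- as.matrix(utils::read.table(path, sep = ",", comment.char = "#"))
  colnames(mat) <- chans
  semg <- lapply(setdiff(chans, "torque"), function(ch)
    signal_trace(mat[, ch], rate, channel = ch, kind = "semg_raw"))
  names(semg) <- setdiff(chans, "torque")
  side <- paste0(tools::file_path_sans_ext(path), "_reps.csv")
  rep_times <- if (file.exists(side))
    utils::read.csv(side)$peak_time_s else NULL
  list(torque = signal_trace(mat[, "torque"], rate, "torque", "torque"),
       semg = semg, rep_times = rep_times,
       exercise = field("exercise"), condition = field("condition"),
       participant = field("participant"), rate = rate)
}
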