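#' Construct a signal trace
#'
#' A uniformly sampled single-channel signal with rate and role metadata:
#' the common currency of the signal-processing stage.
#'
#' @param samples numeric vector, length >= 2, all finite.
#' @param rate sampling rate, Hz (> 0).
#' @param channel channel label (e.g. `"torque"`, `"RF_L"`).
#' @param kind one of `"torque"`, `"semg_raw"`, `"semg_mvic"`, `"envelope"`.
#' @return list of class `"signal_trace"`.
#' @export
signal_trace <- function(samples, rate, channel = "signal",
                         kind = c("torque", "semg_raw", "semg_mvic",
                                  "envelope")) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("signal_trace: need at least 2 samples")
  if (!all(is.finite(samples))) stop("signal_trace: non-finite samples")
  if (!is.numeric(rate) || rate <= 0) stop("signal_trace: rate must be > 0")
  structure(list(samples = samples, rate = rate, channel = channel,
                 kind = kind), class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s [%s]: %d samples @ %g Hz (%.2f s)\n",
              x$channel, x$kind, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

# zero-phase application of an IIR filter, preserving trace metadata
apply_zero_phase <- function(trace, filt, kind = trace$kind) {
  y <- as.numeric(signal::filtfilt(filt, trace$samples))
  signal_trace(y, trace$rate, trace$channel, kind)
}

#' Notch filter for power-line interference
#'
#' Second-order Butterworth band-stop of width `mains_freq / q` centered on
#' the mains frequency, applied forward-backward (zero phase). Attenuation
#' at the mains frequency exceeds 20 dB relative to the passband.
#'
#' @param trace a [signal_trace()].
#' @param mains_freq line frequency, Hz (default 60; must be below Nyquist).
#' @param q quality factor; the stop band spans `mains_freq +/- mains_freq/(2q)`.
#' @return filtered [signal_trace()] of equal length and rate.
#' @export
notch_filter <- function(trace, mains_freq = 60, q = 30) {
  stopifnot(inherits(trace, "signal_trace"))
  ny <- trace$rate / 2
  if (mains_freq <= 0 || mains_freq >= ny)
    stop("notch_filter: mains_freq must lie in (0, Nyquist)")
  bw <- mains_freq / q
  edges <- c(mains_freq - bw / 2, mains_freq + bw / 2) / ny
  filt <- signal::butter(2, edges, type = "stop")
  apply_zero_phase(trace, filt)
}

#' Band-pass filter for sEMG conditioning
#'
#' Fourth-order Butterworth band-pass applied forward-backward (zero
#' phase). The default 20-500 Hz band keeps the physiological sEMG
#' spectrum; the 20 Hz low edge doubles as the high-pass that removes
#' low-frequency mechanical artifact.
#'
#' @param trace a [signal_trace()].
#' @param low,high band edges, Hz; `high` must not exceed Nyquist.
#' @return filtered [signal_trace()] of equal length.
#' @export
bandpass_filter <- function(trace, low = 20, high = 500) {
  stopifnot(inherits(trace, "signal_trace"))
  ny <- trace$rate / 2
  if (!(low > 0 && low < high)) stop("bandpass_filter: need 0 < low < high")
  if (high > ny) stop("bandpass_filter: high edge exceeds Nyquist")
  hi <- min(high / ny, 0.999)
  filt <- signal::butter(4, c(low / ny, hi), type = "pass")
  apply_zero_phase(trace, filt)
}

#' Moving-RMS envelope of a rectified signal
#'
#' Square, moving-average over a reflected-padded window, square root:
#' the amplitude envelope used both for repetition-burst detection and as
#' the substrate of MVIC normalization.
#'
#' @param trace a [signal_trace()].
#' @param window window length in seconds (>= 2 samples, <= trace length).
#' @return a [signal_trace()] of kind `"envelope"`, same length.
#' @export
rectified_envelope <- function(trace, window = 0.1) {
  stopifnot(inherits(trace, "signal_trace"))
  n <- length(trace$samples)
  w <- round(window * trace$rate)
  if (w < 2) stop("rectified_envelope: window shorter than 2 samples")
  if (w > n) stop("rectified_envelope: window longer than the trace")
  half <- floor(w / 2)
  x2 <- trace$samples^2
  rlen <- w - half - 1
  padded <- c(if (half > 0) x2[half:1] else numeric(0), x2,
              if (rlen > 0) x2[n:(n - rlen + 1)] else numeric(0))
  cs <- c(0, cumsum(padded))
  ms <- (cs[(w + 1):(w + n)] - cs[1:n]) / w
  signal_trace(sqrt(pmax(ms, 0)), trace$rate, trace$channel, "envelope")
}

#' MVIC normalization reference constructor
#'
#' Per-channel maximum and resting envelope levels. The maximum is the
#' highest moving-RMS value over the maximal-contraction reference
#' recordings; rest is the (robust, median) envelope level of a rest
#' recording.
#'
#' @param semg_max named numeric vector of per-channel maxima (a.u.).
#' @param semg_rest named numeric vector (or scalar) of resting levels.
#' @return list of class `"mvic_reference"`.
#' @export
mvic_reference <- function(semg_max, semg_rest) {
  if (length(semg_rest) == 1L)
    semg_rest <- stats::setNames(rep(semg_rest, length(semg_max)),
                                 names(semg_max))
  if (any(semg_rest < 0)) stop("mvic_reference: resting level must be >= 0")
  if (any(semg_max <= semg_rest))
    stop("mvic_reference: semg_max must exceed semg_rest on every channel")
  structure(list(semg_max = semg_max, semg_rest = semg_rest),
            class = "mvic_reference")
}

#' Normalize an sEMG envelope to MVIC units
#'
#' Affine map `(x - rest) / (max - rest)`: 0 at the resting level, 1 at the
#' maximal-contraction level.
#'
#' @param trace a rectified or envelope [signal_trace()].
#' @param ref an [mvic_reference()] (or compatible list) covering the
#'   trace's channel.
#' @return a [signal_trace()] of kind `"semg_mvic"`.
#' @export
mvic_normalize <- function(trace, ref) {
  stopifnot(inherits(trace, "signal_trace"))
  ch <- trace$channel
  pick <- function(v) if (!is.null(names(v)) && ch %in% names(v)) v[[ch]]
    else if (length(v) == 1L) v[[1]]
    else stop("mvic_normalize: reference has no entry for channel '", ch, "'")
  mx <- pick(ref$semg_max); rs <- pick(ref$semg_rest)
  if (mx == rs)
    stop("mvic_normalize: semg_max equals semg_rest on channel '", ch,
         "' (division by zero)")
  signal_trace((trace$samples - rs) / (mx - rs), trace$rate, ch, "semg_mvic")
}
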