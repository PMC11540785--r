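#' Construct a repetition series
#'
#' Ordered repetition-peak times with the derived inter-peak intervals and
#' speeds. The interval between successive flexion peaks is one repetition
#' cycle, so speed in RPM is 60/interval and speed per 10 s is 10/interval.
#'
#' @param peak_times strictly ascending peak times, s (may be empty).
#' @param source `"torque"` or `"semg"`.
#' @return list of class `"rep_series"` with `peak_times`, `intervals`,
#'   `speeds_rpm`, `speeds_per10s`, `source`.
#' @export
rep_series <- function(peak_times, source = c("torque", "semg")) {
  source <- match.arg(source)
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) >= 2L) {
    iv <- diff(peak_times)
    if (any(iv <= 0)) stop("rep_series: peak times must be strictly ascending")
  } else iv <- numeric(0)
  structure(list(peak_times = peak_times, intervals = iv,
                 speeds_rpm = 60 / iv, speeds_per10s = 10 / iv,
                 source = source), class = "rep_series")
}

#' @export
print.rep_series <- function(x, ...) {
  cat(sprintf("<rep_series> %d peaks from %s", length(x$peak_times),
              x$source))
  if (length(x$intervals))
    cat(sprintf(", median interval %.3f s (%.1f RPM)",
                stats::median(x$intervals), 60 / stats::median(x$intervals)))
  cat("\n")
  invisible(x)
}

# local maxima of x (plateau tie broken to the earlier sample), then
# amplitude gating and greedy minimum-distance enforcement by height
find_peaks_min_dist <- function(x, min_height, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  # order by height descending, earlier sample wins ties
  cand <- cand[order(-x[cand], cand)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect repetition peaks in a torque trace or sEMG envelope
#'
#' Local-maxima search with an amplitude gate at 30\% of the trace's 95th
#' percentile and a minimum inter-peak distance of half the protocol's
#' expected repetition interval, which keeps one peak per repetition cycle
#' (the flexion-phase positive peak for torque, the burst maximum for an
#' envelope) while rejecting the smaller extension-phase peak and noise.
#'
#' @param trace a [signal_trace()] (torque or envelope/MVIC kind).
#' @param protocol an [exercise_protocol()] supplying the expected pace.
#' @param min_rel_height amplitude gate as a fraction of the 95th-percentile
#'   amplitude (default 0.3).
#' @return a [rep_series()]; empty (with a warning) when no peaks clear the
#'   gate, since zero detected repetitions is itself a meaningful result.
#' @export
detect_rep_peaks <- function(trace, protocol, min_rel_height = 0.3) {
  stopifnot(inherits(trace, "signal_trace"),
            inherits(protocol, "exercise_protocol"))
  x <- trace$samples
  src <- if (trace$kind == "torque") "torque" else "semg"
  ref <- stats::quantile(x, 0.95, names = FALSE)
  if (!is.finite(ref) || ref <= 0) {
    warning("detect_rep_peaks: no positive activity in trace; empty series")
    return(rep_series(numeric(0), src))
  }
  min_dist <- 0.5 * protocol$nominal_interval_s * trace$rate
  idx <- find_peaks_min_dist(x, min_rel_height * ref, min_dist)
  if (!length(idx)) {
    warning("detect_rep_peaks: no peaks found; empty series")
    return(rep_series(numeric(0), src))
  }
  rep_series((idx - 1) / trace$rate, src)
}

#' Fraction of repetition peaks matched between two series
#'
#' Greedy one-to-one matching of peak times within a tolerance; the
#' returned fraction is matches divided by the larger series length, so the
#' measure is symmetric. Used to confirm that torque-derived and
#' sEMG-derived repetition timings agree.
#'
#' @param a,b [rep_series()] objects from the same session.
#' @param tol matching tolerance, s (> 0).
#' @return matched fraction in [0, 1] (1 when both series are empty).
#' @export
series_agreement <- function(a, b, tol = 0.15) {
  stopifnot(inherits(a, "rep_series"), inherits(b, "rep_series"))
  if (tol <= 0) stop("series_agreement: tol must be positive")
  ta <- a$peak_times; tb <- b$peak_times
  if (!length(ta) && !length(tb)) return(1)
  if (!length(ta) || !length(tb)) return(0)
  used <- logical(length(tb))
  matched <- 0L
  for (t in ta) {
    d <- abs(tb - t)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / max(length(ta), length(tb))
}

#' Standard sEMG conditioning chain
#'
#' Notch at the mains frequency, band-pass 20-500 Hz, moving-RMS envelope,
#' MVIC normalization: raw sEMG in, MVIC-scaled envelope out.
#'
#' @param trace raw sEMG [signal_trace()].
#' @param ref an [mvic_reference()].
#' @param mains_freq line frequency, Hz.
#' @param window envelope window, s.
#' @return a [signal_trace()] of kind `"semg_mvic"`.
#' @export
process_semg <- function(trace, ref, mains_freq = 60, window = 0.1) {
  hi <- min(500, 0.999 * trace$rate / 2)
  env <- rectified_envelope(
    bandpass_filter(notch_filter(trace, mains_freq), 20, hi), window)
  mvic_normalize(env, ref)
}
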