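#' ECG record container
#'
#' @param samples numeric voltage trace (mV). `NA` samples are treated as
#'   gaps.
#' @param fs sampling rate, Hz (> 0).
#' @param t0 absolute start time in seconds (offset applied to derived beat
#'   times).
#' @param subject,day optional identifiers.
#' @param gaps optional logical missing-sample mask, same length as
#'   `samples`; merged with `is.na(samples)`.
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, t0 = 0, subject = NA_character_,
                       day = NA_integer_, gaps = NULL) {
  stopifnot(fs > 0, length(samples) > 0)
  if (is.null(gaps)) gaps <- rep(FALSE, length(samples))
  stopifnot(length(gaps) == length(samples))
  gaps <- gaps | is.na(samples)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0,
                 subject = subject, day = day, gaps = gaps),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %.1f s at %g Hz (%d samples, %.1f%% gap)\n",
              length(x$samples) / x$fs, x$fs, length(x$samples),
              100 * mean(x$gaps)))
  invisible(x)
}

# second-order IIR notch (RBJ biquad), returns signal::Arma
notch_filter <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1L], a = a / a[1L])
}

#' Filter an ECG record for beat detection
#'
#' Applies a fifth-order 0.5 Hz Butterworth high-pass and a second-order
#' powerline notch (60 Hz, Q = 30), both zero-phase (forward-backward), so
#' fiducial timing is preserved. Gap-free segments are filtered independently;
#' gaps are propagated as `NA`, never interpolated. Segments shorter than
#' `min_segment_s` are too short for the filter warm-up and are flagged as
#' gap (excluded from beat detection).
#'
#' @param ecg an [ecg_record()].
#' @param hp_hz high-pass corner frequency, Hz.
#' @param hp_order Butterworth order.
#' @param notch_hz powerline frequency, Hz (`NULL` disables the notch).
#' @param notch_q notch quality factor.
#' @param min_segment_s minimum filterable segment length, seconds.
#' @return A filtered [ecg_record()].
#' @export
ecg_preprocess <- function(ecg, hp_hz = 0.5, hp_order = 5, notch_hz = 60,
                           notch_q = 30, min_segment_s = 2) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (ecg$fs < 250) stop("fs must be >= 250 Hz")
  if (length(ecg$samples) / ecg$fs < 10) stop("need at least 10 s of data")
  hp <- signal::butter(hp_order, hp_hz / (ecg$fs / 2), type = "high")
  nt <- if (!is.null(notch_hz)) notch_filter(notch_hz, ecg$fs, notch_q) else NULL
  out <- rep(NA_real_, length(ecg$samples))
  gaps <- ecg$gaps
  runs <- logical_runs(!gaps)
  min_n <- as.integer(min_segment_s * ecg$fs)
  if (nrow(runs) > 0) {
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, 1L]; b <- runs[i, 2L]
      if (b - a + 1L < min_n) { gaps[a:b] <- TRUE; next }
      seg <- ecg$samples[a:b]
      seg <- signal::filtfilt(hp, seg)
      if (!is.null(nt)) seg <- signal::filtfilt(nt, seg)
      out[a:b] <- seg
    }
  }
  ecg_record(out, fs = ecg$fs, t0 = ecg$t0, subject = ecg$subject,
             day = ecg$day, gaps = gaps)
}

#' Detect R peaks from the gradient of the ECG
#'
#' QRS complexes are located from the steepness of the absolute gradient of
#' the signal: the smoothed absolute gradient is compared against a slowly
#' varying average; supra-threshold episodes longer than a minimum fraction of
#' the mean episode length are taken as QRS complexes, and the R peak is the
#' signal maximum within each episode. A physiological refractory period
#' (default 200 ms) suppresses double detections, keeping the larger peak.
#'
#' @param ecg a preprocessed [ecg_record()].
#' @param smooth_s,avg_s smoothing and averaging windows for the gradient, s.
#' @param grad_weight threshold multiplier on the averaged gradient.
#' @param min_len_weight minimum QRS episode length, as a fraction of the mean
#'   episode length.
#' @param refractory_s minimum peak-to-peak spacing, s.
#' @return Integer vector of 1-based R-peak sample indices (empty, with a
#'   warning, if no QRS episodes are found in a non-empty record).
#' @export
detect_r_peaks <- function(ecg, smooth_s = 0.08, avg_s = 0.75,
                           grad_weight = 1.35, min_len_weight = 0.4,
                           refractory_s = 0.2) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  x <- ecg$samples
  x[ecg$gaps] <- 0
  absgrad <- abs(num_gradient(x))
  smoothgrad <- moving_average(absgrad, smooth_s * fs)
  avggrad <- moving_average(smoothgrad, avg_s * fs)
  qrs <- smoothgrad > grad_weight * avggrad
  qrs[ecg$gaps] <- FALSE
  runs <- logical_runs(qrs)
  if (nrow(runs) == 0L) {
    warning("no QRS episodes found")
    return(integer(0))
  }
  lens <- runs[, 2L] - runs[, 1L] + 1L
  runs <- runs[lens >= min_len_weight * mean(lens), , drop = FALSE]
  if (nrow(runs) == 0L) {
    warning("no QRS episodes found")
    return(integer(0))
  }
  peaks <- integer(nrow(runs))
  amps <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- runs[i, 1L]:runs[i, 2L]
    j <- seg[which.max(x[seg])]
    peaks[i] <- j
    amps[i] <- x[j]
  }
  # refractory: drop the smaller of any pair closer than refractory_s
  min_gap <- refractory_s * fs
  keep <- rep(TRUE, length(peaks))
  last <- 1L
  for (i in seq_along(peaks)[-1L]) {
    if (peaks[i] - peaks[last] < min_gap) {
      if (amps[i] > amps[last]) { keep[last] <- FALSE; last <- i }
      else keep[i] <- FALSE
    } else last <- i
  }
  peaks[keep]
}

#' Binarize an analog treatment-event trace into intervals
#'
#' The trace is rectified and thresholded at half its maximum; contiguous
#' supra-threshold runs become (onset, offset) intervals, and runs shorter
#' than `min_duration_s` are discarded.
#'
#' @param trace numeric analog event signal.
#' @param fs sampling rate of the trace, Hz.
#' @param min_duration_s minimum believable session duration, s.
#' @param merge_gap_s sub-threshold gaps shorter than this are bridged before
#'   the duration filter (a noisy sample inside a session must not split it).
#' @return data frame with columns `onset`, `offset` (1-based sample indices,
#'   offset inclusive); zero rows for an all-zero trace.
#' @export
binarize_events <- function(trace, fs = 1, min_duration_s = 60,
                            merge_gap_s = 5) {
  r <- abs(trace)
  m <- max(r, na.rm = TRUE)
  if (!is.finite(m) || m == 0) {
    return(data.frame(onset = integer(0), offset = integer(0)))
  }
  on <- !is.na(r) & r > m / 2
  runs <- logical_runs(on)
  if (nrow(runs) > 1L) {
    gaps <- (runs[-1L, 1L] - runs[-nrow(runs), 2L] - 1L) / fs
    merged <- list(runs[1L, ])
    for (i in seq_along(gaps)) {
      if (gaps[i] < merge_gap_s) {
        merged[[length(merged)]][2L] <- runs[i + 1L, 2L]
      } else {
        merged[[length(merged) + 1L]] <- runs[i + 1L, ]
      }
    }
    runs <- do.call(rbind, merged)
  }
  if (nrow(runs) > 0L) {
    lens <- (runs[, 2L] - runs[, 1L] + 1L) / fs
    runs <- runs[lens >= min_duration_s, , drop = FALSE]
  }
  data.frame(onset = as.integer(runs[, 1L]), offset = as.integer(runs[, 2L]))
}
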