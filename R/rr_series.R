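#' RR-interval series
#'
#' Container for a sequence of RR (inter-beat) intervals with per-interval
#' validity flags. `times` holds the time of the beat that *closes* each
#' interval, in seconds from the start of the recording; `rr` is the interval
#' length in milliseconds. Flags classify each interval as `"valid"`,
#' `"outlier"` (non-physiological duration) or `"ectopic"` (abrupt jump from
#' the previous retained interval).
#'
#' @param times numeric, strictly increasing beat times in seconds.
#' @param rr numeric, positive interval lengths in ms, same length as `times`.
#' @param flags optional character vector of per-interval flags; defaults to
#'   all `"valid"`.
#' @return An object of class `rr_series`: a data frame with columns `time`,
#'   `rr`, `flag`.
#' @seealso [clean_rr()], [hrv_time()], [hrv_freq()]
#' @export
rr_series <- function(times, rr, flags = NULL) {
  stopifnot(length(times) == length(rr), length(rr) > 0)
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("rr intervals must be positive and finite")
  if (any(diff(times) <= 0)) stop("beat times must be strictly increasing")
  if (is.null(flags)) flags <- rep("valid", length(rr))
  if (!all(flags %in% c("valid", "outlier", "ectopic"))) {
    stop("flags must be one of 'valid', 'outlier', 'ectopic'")
  }
  out <- data.frame(time = as.numeric(times), rr = as.numeric(rr),
                    flag = flags, stringsAsFactors = FALSE)
  class(out) <- c("rr_series", "data.frame")
  out
}

#' @export
print.rr_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<rr_series> %d intervals over %.1f s; mean RR %.0f ms; flags: %s\n",
              n, diff(range(x$time)),
              mean(x$rr[x$flag == "valid"]),
              paste(sprintf("%s=%d", names(table(x$flag)), table(x$flag)),
                    collapse = ", ")))
  invisible(x)
}

valid_rr <- function(rr) rr$rr[rr$flag == "valid"]

# Successive differences between intervals that are valid AND adjacent in the
# original series (pairs spanning a flagged interval are excluded).
valid_successive_diffs <- function(rr) {
  v <- rr$flag == "valid"
  both <- which(v[-1L] & v[-length(v)])
  rr$rr[both + 1L] - rr$rr[both]
}

#' Flag outlier and ectopic RR intervals
#'
#' Applies the two cleaning rules used throughout the pipeline, in order:
#' intervals longer than `max_rr` (2 s) or shorter than `min_rr` (300 ms) are
#' flagged as outliers; then each remaining interval is compared to the
#' previous *retained* interval and flagged ectopic when the relative
#' difference exceeds `ectopic_tol` (20%). Interval values are never mutated,
#' only flags are set.
#'
#' @param rr an [rr_series()].
#' @param min_rr,max_rr outlier bounds in ms.
#' @param ectopic_tol relative-difference threshold (fraction).
#' @return The series with updated flags.
#' @export
clean_rr <- function(rr, min_rr = 300, max_rr = 2000, ectopic_tol = 0.2) {
  stopifnot(inherits(rr, "rr_series"), nrow(rr) > 0)
  flag <- rep("valid", nrow(rr))
  flag[rr$rr > max_rr | rr$rr < min_rr] <- "outlier"
  prev <- NA_real_
  for (i in seq_len(nrow(rr))) {
    if (flag[i] == "outlier") next
    if (!is.na(prev) && abs(rr$rr[i] - prev) / prev > ectopic_tol) {
      flag[i] <- "ectopic"
    } else {
      prev <- rr$rr[i]
    }
  }
  rr$flag <- flag
  if (all(flag != "valid")) {
    warning("all RR intervals flagged; downstream metrics will be NA")
  }
  rr
}

#' Mean heart rate from valid RR intervals
#'
#' @param rr an [rr_series()].
#' @return Heart rate in bpm (`60000 / mean(valid RR)`), or `NA` if no valid
#'   intervals remain.
#' @export
heart_rate <- function(rr) {
  v <- valid_rr(rr)
  if (length(v) == 0L) return(NA_real_)
  60000 / mean(v)
}

#' Bazett heart-rate correction of the QT interval
#'
#' QTc = QT / sqrt(RR) with RR in seconds, i.e. the QT interval rescaled to a
#' standard 60 bpm heart rate.
#'
#' @param qt QT interval(s) in ms.
#' @param rr RR interval(s) in seconds.
#' @return QTc in ms.
#' @export
qtc_bazett <- function(qt, rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("rr must be positive (seconds)")
  qt / sqrt(rr)
}

#' Fraction of prolonged QTc intervals
#'
#' Prolonged is defined as QTc >= `threshold` (500 ms).
#'
#' @param qtc QTc values in ms.
#' @param threshold prolongation threshold in ms.
#' @return Percentage in \[0, 100\].
#' @export
prolonged_qtc_fraction <- function(qtc, threshold = 500) {
  qtc <- qtc[is.finite(qtc)]
  if (length(qtc) == 0L) stop("no QTc values")
  100 * mean(qtc >= threshold)
}

#' Time-domain heart rate variability
#'
#' RMSSD, SDNN and pNNI_50 over the valid intervals of a cleaned series.
#' Successive differences are taken only between adjacent valid intervals, so
#' pairs spanning a flagged beat never contribute. SDNN uses the sample
#' (n-1) standard deviation; pNNI_50 counts differences strictly greater than
#' 50 ms.
#'
#' @param rr an [rr_series()].
#' @return list with `rmssd` (ms), `sdnn` (ms), `pnni50` (%); entries are `NA`
#'   when fewer than 2 usable successive pairs (rmssd, pnni50) or fewer than 3
#'   valid intervals (sdnn) are available.
#' @export
hrv_time <- function(rr) {
  v <- valid_rr(rr)
  d <- valid_successive_diffs(rr)
  sdnn <- if (length(v) >= 3L) stats::sd(v) else NA_real_
  if (length(d) >= 2L) {
    rmssd <- sqrt(mean(d^2))
    pnni50 <- 100 * mean(abs(d) > 50)
  } else {
    rmssd <- NA_real_
    pnni50 <- NA_real_
  }
  list(rmssd = rmssd, sdnn = sdnn, pnni50 = pnni50)
}

#' Frequency-domain heart rate variability
#'
#' The valid RR intervals are resampled to an even grid (cubic spline across
#' flagged beats) and a Welch periodogram is computed. Total power is the
#' integral of the PSD below `f_max` (0.4 Hz); normalized high-frequency power
#' is the HF band (0.15-0.4 Hz) integral divided by total power.
#'
#' @param rr an [rr_series()].
#' @param resample_fs resampling rate, Hz.
#' @param hf_band,f_max HF band limits and total-power upper limit, Hz.
#' @param seg_s Welch segment length in seconds (shrunk automatically for
#'   short records).
#' @return list with `total_power` (ms^2) and `nhf_power` (fraction in
#'   \[0, 1\]); `NA` when fewer than 120 s of valid data are available.
#' @export
hrv_freq <- function(rr, resample_fs = 4, hf_band = c(0.15, 0.4), f_max = 0.4,
                     seg_s = 120) {
  v <- rr$flag == "valid"
  if (sum(v) < 8L) return(list(total_power = NA_real_, nhf_power = NA_real_))
  t <- rr$time[v]; y <- rr$rr[v]
  span <- t[length(t)] - t[1L]
  if (span < 120) return(list(total_power = NA_real_, nhf_power = NA_real_))
  grid <- seq(t[1L], t[length(t)], by = 1 / resample_fs)
  yi <- stats::spline(t, y, xout = grid, method = "natural")$y
  seg <- min(seg_s, span / 2)
  ps <- welch_psd(yi, fs = resample_fs, seg_s = seg, overlap = 0.5)
  total <- band_power(ps$freq, ps$psd, 0, f_max)
  hf <- band_power(ps$freq, ps$psd, hf_band[1L], hf_band[2L])
  nhf <- if (total > 0) hf / total else NA_real_
  list(total_power = total, nhf_power = nhf)
}

#' Lorenz-plot (Poincare) vagal and sympathetic indices
#'
#' SD1/SD2 are the minor/major axes of the Poincare scatter of successive
#' valid RR pairs. Following the Toichi convention the longitudinal and
#' transverse lengths are L = 4 SD2 and T = 4 SD1, giving the cardiac
#' sympathetic index CSI = L / T and the cardiac vagal index
#' CVI = log10(L * T).
#'
#' @param rr an [rr_series()].
#' @return list with `cvi`, `csi`, `sd1`, `sd2`; `NA` when fewer than 10 valid
#'   successive pairs exist or the scatter is degenerate (SD1 = 0).
#' @export
lorenz_indices <- function(rr) {
  d <- valid_successive_diffs(rr)
  v <- valid_rr(rr)
  if (length(d) < 10L || length(v) < 3L) {
    return(list(cvi = NA_real_, csi = NA_real_, sd1 = NA_real_, sd2 = NA_real_))
  }
  sd1 <- sqrt(stats::var(d) / 2)
  sdnn <- stats::sd(v)
  sd2sq <- 2 * sdnn^2 - sd1^2
  sd2 <- sqrt(max(sd2sq, 0))
  if (sd1 == 0 || sd2 == 0) {
    return(list(cvi = NA_real_, csi = NA_real_, sd1 = sd1, sd2 = sd2))
  }
  L <- 4 * sd2; Tt <- 4 * sd1
  list(cvi = log10(L * Tt), csi = L / Tt, sd1 = sd1, sd2 = sd2)
}

#' All HRV / cardiac metrics for one record
#'
#' Convenience wrapper computing the full metric set used by the daily and
#' event-locked analyses: heart rate, RMSSD, SDNN, pNNI_50, total power,
#' normalized HF power, CVI, CSI, and (when per-beat QT values are supplied)
#' mean/median Bazett QTc and the prolonged-QTc percentage.
#'
#' @param rr an [rr_series()] (cleaned; [clean_rr()] is applied if all flags
#'   are still `"valid"` and `auto_clean` is TRUE).
#' @param qt optional per-beat QT in ms, aligned with the intervals of `rr`.
#' @param auto_clean run [clean_rr()] when the series carries no flags yet.
#' @return Named list of metrics (see [hrv_time()], [hrv_freq()],
#'   [lorenz_indices()]).
#' @export
hrv_metrics <- function(rr, qt = NULL, auto_clean = TRUE) {
  if (auto_clean && all(rr$flag == "valid")) rr <- clean_rr(rr)
  td <- hrv_time(rr)
  fd <- hrv_freq(rr)
  lz <- lorenz_indices(rr)
  out <- list(hr = heart_rate(rr),
              rmssd = td$rmssd, sdnn = td$sdnn, pnni50 = td$pnni50,
              total_power = fd$total_power, nhf_power = fd$nhf_power,
              cvi = lz$cvi, csi = lz$csi,
              qtc_mean = NA_real_, qtc_median = NA_real_,
              prolonged_qtc_pct = NA_real_)
  if (!is.null(qt)) {
    ok <- rr$flag == "valid" & is.finite(qt)
    if (any(ok)) {
      qtc <- qtc_bazett(qt[ok], rr$rr[ok] / 1000)
      out$qtc_mean <- mean(qtc)
      out$qtc_median <- stats::median(qtc)
      out$prolonged_qtc_pct <- prolonged_qtc_fraction(qtc)
    }
  }
  out
}
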