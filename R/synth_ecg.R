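#' Synthesize an ECG trace from an RR series with exact ground truth
#'
#' Renders each beat as a fixed template of Gaussian bumps (P, Q, R, S, T)
#' stretched per beat, so every fiducial landmark is known analytically. The T
#' bump is placed so that the QT interval (QRS onset to T offset) equals the
#' value returned by `qt_fun` for that beat, e.g. `qt_fun = function(rr_s)
#' 400 * sqrt(rr_s)` makes every beat's Bazett QTc exactly 400 ms. Optional
#' additive white noise and a powerline sinusoid can be superimposed.
#'
#' Template geometry (relative to the R peak, bump SDs in parentheses): P at
#' -160 ms (25 ms, 0.15 mV), Q at -25 ms (8 ms, -0.10 mV), R at 0 (10 ms,
#' 1.0 mV), S at +25 ms (8 ms, -0.15 mV); wave onsets/offsets are defined at
#' 2.5 SD from the bump center. The T bump (50 ms SD, 0.35 mV) is centered
#' 125 ms (2.5 SD) before the prescribed T offset.
#'
#' @param rr an [rr_series()].
#' @param qt_fun function mapping RR in seconds to QT in ms (vectorized), or
#'   `NULL` to omit T waves entirely.
#' @param fs sampling rate in Hz (>= 250; T-wave delineation needs it).
#' @param noise_sd additive Gaussian noise SD, mV.
#' @param powerline_amp amplitude of an additive `powerline_hz` sinusoid, mV.
#' @param powerline_hz powerline frequency, Hz.
#' @return list with `ecg` (an [ecg_record()]) and `truth`: a data frame of
#'   per-beat 1-based sample indices (`p_onset`, `p_peak`, `p_offset`,
#'   `qrs_onset`, `r_peak`, `qrs_offset`, `t_peak`, `t_offset`) plus `qt_ms`
#'   and `rr_ms`.
#' @export
synthesize_ecg <- function(rr, qt_fun = function(rr_s) 400 * sqrt(rr_s),
                           fs = 500, noise_sd = 0, powerline_amp = 0,
                           powerline_hz = 60) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 250) stop("fs must be >= 250 Hz for reliable T-wave delineation")
  rr_ms <- rr$rr
  r_time <- rr$time  # beat (R peak) times in s
  qt_ms <- if (is.null(qt_fun)) rep(NA_real_, length(rr_ms)) else qt_fun(rr_ms / 1000)
  if (!is.null(qt_fun) && any(qt_ms >= rr_ms)) {
    stop("QT >= RR for at least one beat: waves would overlap")
  }

  # template constants (seconds / mV)
  tpl <- list(
    p = list(mu = -0.160, sd = 0.025, amp = 0.15),
    q = list(mu = -0.025, sd = 0.008, amp = -0.10),
    r = list(mu = 0.000, sd = 0.010, amp = 1.00),
    s = list(mu = 0.025, sd = 0.008, amp = -0.15),
    t_sd = 0.050, t_amp = 0.35, edge = 2.5
  )
  qrs_on_rel <- tpl$q$mu - tpl$edge * tpl$q$sd      # -45 ms
  qrs_off_rel <- tpl$s$mu + tpl$edge * tpl$s$sd     # +45 ms

  dur <- r_time[length(r_time)] + 0.6
  n <- as.integer(ceiling(dur * fs))
  x <- numeric(n)
  tt <- (seq_len(n) - 1L) / fs

  add_bump <- function(x, center_s, sd_s, amp) {
    lo <- max(1L, as.integer(floor((center_s - 4 * sd_s) * fs)) + 1L)
    hi <- min(n, as.integer(ceiling((center_s + 4 * sd_s) * fs)) + 1L)
    if (lo > hi) return(x)
    seg <- tt[lo:hi]
    x[lo:hi] <- x[lo:hi] + amp * exp(-(seg - center_s)^2 / (2 * sd_s^2))
    x
  }

  nb <- length(rr_ms)
  truth <- data.frame(p_onset = integer(nb), p_peak = integer(nb),
                      p_offset = integer(nb), qrs_onset = integer(nb),
                      r_peak = integer(nb), qrs_offset = integer(nb),
                      t_peak = rep(NA_integer_, nb),
                      t_offset = rep(NA_integer_, nb),
                      qt_ms = qt_ms, rr_ms = rr_ms)
  s_of <- function(t_s) as.integer(round(t_s * fs)) + 1L

  for (k in seq_len(nb)) {
    rc <- r_time[k]
    for (w in c("p", "q", "r", "s")) {
      b <- tpl[[w]]
      x <- add_bump(x, rc + b$mu, b$sd, b$amp)
    }
    truth$p_onset[k] <- s_of(rc + tpl$p$mu - tpl$edge * tpl$p$sd)
    truth$p_peak[k] <- s_of(rc + tpl$p$mu)
    truth$p_offset[k] <- s_of(rc + tpl$p$mu + tpl$edge * tpl$p$sd)
    truth$qrs_onset[k] <- s_of(rc + qrs_on_rel)
    truth$r_peak[k] <- s_of(rc)
    truth$qrs_offset[k] <- s_of(rc + qrs_off_rel)
    if (!is.null(qt_fun)) {
      t_off <- rc + qrs_on_rel + qt_ms[k] / 1000
      t_ctr <- t_off - tpl$edge * tpl$t_sd
      x <- add_bump(x, t_ctr, tpl$t_sd, tpl$t_amp)
      truth$t_peak[k] <- s_of(t_ctr)
      truth$t_offset[k] <- s_of(t_off)
    }
  }

  if (powerline_amp > 0) x <- x + powerline_amp * sin(2 * pi * powerline_hz * tt)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)

  list(ecg = ecg_record(x, fs = fs), truth = truth)
}
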