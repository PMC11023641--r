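# Metric evaluated on the beats falling in [a, b); NA when the window is not
# fully covered (leading/trailing/internal gap > max_gap_s) or too sparse.
window_metric <- function(rr, a, b, metric, qt = NULL, max_gap_s = 3) {
  sel <- which(rr$time >= a & rr$time < b)
  if (length(sel) < 4L) return(NA_real_)
  t <- rr$time[sel]
  if (t[1L] - a > max_gap_s || b - t[length(t)] > max_gap_s ||
      max(diff(t)) > max_gap_s) return(NA_real_)
  sub <- rr[sel, , drop = FALSE]
  class(sub) <- c("rr_series", "data.frame")
  switch(metric,
         hr = heart_rate(sub),
         rmssd = hrv_time(sub)$rmssd,
         sdnn = hrv_time(sub)$sdnn,
         pnni50 = hrv_time(sub)$pnni50,
         total_power = hrv_freq(sub)$total_power,
         nhf_power = hrv_freq(sub)$nhf_power,
         cvi = lorenz_indices(sub)$cvi,
         csi = lorenz_indices(sub)$csi,
         qtc_mean = {
           if (is.null(qt)) return(NA_real_)
           q <- qt[sel]
           ok <- sub$flag == "valid" & is.finite(q)
           if (!any(ok)) return(NA_real_)
           mean(qtc_bazett(q[ok], sub$rr[ok] / 1000))
         },
         stop("unknown metric: ", metric))
}

#' 24-hour (whole-recording) summary of one subject-day
#'
#' Computes the full cardiac metric set over all valid beats of a day's
#' recording plus daily vitals means. Days with insufficient valid ECG
#' coverage return `NA` metrics with the reason attached.
#'
#' @param rr the day's [rr_series()] (cleaned with [clean_rr()] beforehand,
#'   or auto-cleaned here).
#' @param qt optional per-beat QT (ms) aligned with `rr`.
#' @param vitals optional data frame with columns among `bp`, `icp`, `ppi`,
#'   `resp` (1 Hz samples); daily means are taken.
#' @param day_length_s nominal day length used for the coverage check.
#' @param min_coverage_s minimum summed valid-RR time (default 4 h).
#' @return Named list of metrics, or a list with `reason` when coverage
#'   fails.
#' @export
daily_summary <- function(rr, qt = NULL, vitals = NULL,
                          day_length_s = 24 * 3600,
                          min_coverage_s = 4 * 3600) {
  if (all(rr$flag == "valid")) rr <- clean_rr(rr)
  coverage <- sum(rr$rr[rr$flag == "valid"]) / 1000
  if (coverage < min_coverage_s) {
    return(list(reason = sprintf("coverage %.0f s below minimum %.0f s",
                                 coverage, min_coverage_s)))
  }
  out <- hrv_metrics(rr, qt = qt, auto_clean = FALSE)
  out$coverage_s <- coverage
  for (v in c("bp", "icp", "ppi", "resp")) {
    out[[v]] <- if (!is.null(vitals) && v %in% names(vitals)) {
      mean(vitals[[v]], na.rm = TRUE)
    } else NA_real_
  }
  out
}

.daily_metrics <- c("hr", "rmssd", "sdnn", "pnni50", "total_power",
                    "nhf_power", "cvi", "csi", "qtc_mean", "qtc_median",
                    "prolonged_qtc_pct", "bp", "icp", "ppi", "resp")

#' Daily summary table for a whole synthetic trial
#'
#' Applies [daily_summary()] to every subject-day of a generated trial and
#' appends change-from-day-1 columns (`d_<metric>`), which are zero on day 1
#' by construction and `NA` when day 1 failed coverage.
#'
#' @param trial output of [generate_trial()].
#' @param min_coverage_s coverage minimum; defaults to half the trial's
#'   synthetic day duration.
#' @return Data frame, one row per subject-day that met coverage.
#' @export
trial_daily_summaries <- function(trial, min_coverage_s = NULL) {
  if (is.null(min_coverage_s)) min_coverage_s <- 0.5 * trial$spec$day_duration_s
  rows <- list()
  for (rec in trial$days) {
    s <- daily_summary(rec$rr, qt = rec$qt_ms, vitals = rec$vitals,
                       day_length_s = trial$spec$day_duration_s,
                       min_coverage_s = min_coverage_s)
    if (!is.null(s$reason)) next
    rows[[length(rows) + 1L]] <-
      data.frame(subject = rec$subject, arm = rec$arm, day = rec$day,
                 s[.daily_metrics], row.names = NULL)
  }
  out <- do.call(rbind, rows)
  for (m in .daily_metrics) {
    d1 <- out[out$day == 1L, c("subject", m)]
    out[[paste0("d_", m)]] <- out[[m]] - d1[[m]][match(out$subject, d1$subject)]
  }
  out
}

#' Assign days to three-day analysis bins
#'
#' Day 1 is the change baseline and never binned; days 2-13 fall into the
#' non-overlapping bins Day 2-4, 5-7, 8-10 and 11-13; later days are
#' excluded. Each subject-day stays one independent observation.
#'
#' @param summaries data frame with a `day` column (e.g. from
#'   [trial_daily_summaries()]).
#' @return The rows with day in 2-13, with an added `bin` factor.
#' @export
bin_days <- function(summaries) {
  keep <- summaries$day >= 2L & summaries$day <= 13L
  out <- summaries[keep, , drop = FALSE]
  out$bin <- cut(out$day, breaks = c(1, 4, 7, 10, 13),
                 labels = c("Day 2-4", "Day 5-7", "Day 8-10", "Day 11-13"))
  out
}

#' Event-locked sliding-window metrics around treatment sessions
#'
#' For each session, computes a metric in 6-minute windows stepping
#' bi-directionally by 3 minutes from the treatment onset and offset, and
#' normalizes each window value against a daily reference: the mean and SD of
#' the same sliding-window metric tiled across the entire day. Pre- (20 min
#' before onset), during- (onset to offset) and post-treatment (20 min after
#' offset) period means are taken over fully contained windows, and the
#' during-pre and post-pre deltas are returned per session in both raw metric
#' units and daily-SD (normalized) units.
#'
#' @param rr the day's cleaned [rr_series()].
#' @param sessions data frame with `onset`, `offset` in seconds.
#' @param metric one of `"hr"`, `"rmssd"`, `"sdnn"`, `"pnni50"`,
#'   `"total_power"`, `"nhf_power"`, `"cvi"`, `"csi"`, `"qtc_mean"`.
#' @param qt per-beat QT (ms), required for `"qtc_mean"`.
#' @param window_s,step_s sliding-window length and step, s.
#' @param period_s pre/post period length, s.
#' @param day_length_s day length for the reference tiling.
#' @return list with `windows` (per-session aligned series: `session`,
#'   `align`, `offset_s`, `value`, `norm`), `periods` (per-session period
#'   means and deltas), and `reference` (`mean`, `sd`, `n`). Normalized
#'   values are `NA` when the daily SD is zero.
#' @export
event_locked <- function(rr, sessions, metric = "hr", qt = NULL,
                         window_s = 360, step_s = 180, period_s = 1200,
                         day_length_s = NULL) {
  if (all(rr$flag == "valid")) rr <- clean_rr(rr)
  if (is.null(day_length_s)) day_length_s <- max(rr$time)
  ref_starts <- seq(0, day_length_s - window_s, by = step_s)
  ref_vals <- vapply(ref_starts, function(a)
    window_metric(rr, a, a + window_s, metric, qt), numeric(1L))
  ref_vals <- ref_vals[is.finite(ref_vals)]
  ref_mean <- mean(ref_vals)
  ref_sd <- stats::sd(ref_vals)
  norm <- function(v) if (isTRUE(ref_sd > 0)) (v - ref_mean) / ref_sd else v * NA_real_

  win_rows <- list(); per_rows <- list()
  period_mean <- function(a, b) {
    starts <- seq(a, b - window_s, by = step_s)
    starts <- starts[starts >= a & starts + window_s <= b]
    v <- vapply(starts, function(s0)
      window_metric(rr, s0, s0 + window_s, metric, qt), numeric(1L))
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  for (s in seq_len(nrow(sessions))) {
    on <- sessions$onset[s]; off <- sessions$offset[s]
    for (align in c("onset", "offset")) {
      anchor <- if (align == "onset") on else off
      kmin <- ceiling((-anchor) / step_s)
      kmax <- floor((day_length_s - window_s - anchor) / step_s)
      kk <- seq(max(kmin, -10L), min(kmax, 10L))
      v <- vapply(kk, function(k)
        window_metric(rr, anchor + k * step_s, anchor + k * step_s + window_s,
                      metric, qt), numeric(1L))
      win_rows[[length(win_rows) + 1L]] <-
        data.frame(session = s, align = align, offset_s = kk * step_s,
                   value = v, norm = norm(v))
    }
    pre <- period_mean(on - period_s, on)
    dur <- period_mean(on, off)
    pst <- period_mean(off, off + period_s)
    per_rows[[length(per_rows) + 1L]] <-
      data.frame(session = s, pre = pre, during = dur, post = pst,
                 d_during_pre = dur - pre, d_post_pre = pst - pre,
                 pre_norm = norm(pre), during_norm = norm(dur),
                 post_norm = norm(pst),
                 d_during_pre_norm = norm(dur) - norm(pre),
                 d_post_pre_norm = norm(pst) - norm(pre))
  }
  list(windows = do.call(rbind, win_rows),
       periods = do.call(rbind, per_rows),
       reference = list(mean = ref_mean, sd = ref_sd, n = length(ref_vals)))
}
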