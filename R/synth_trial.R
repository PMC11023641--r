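#' Specification of a synthetic two-arm stimulation trial
#'
#' Defines the study conditions for the synthetic-trial generator: arm sizes,
#' recording duration, twice-daily 20-minute treatment sessions, arm-specific
#' effects on the daily metric trajectories, an acute per-session heart-rate
#' response linked to clinical outcome, and a gap model for monitoring
#' restarts. Defaults mirror a 24-patient ICU trial: 11 active (taVNS) and 13
#' sham subjects, about 11 recording days per subject, and standardized
#' arm effects (Cohen's d of the change-from-day-1) of +0.42 on RMSSD, -0.57
#' on QTc, -0.49 on the perfusion index and +0.37 on respiration rate.
#'
#' Each synthetic "day" is represented by a continuous recording of
#' `day_duration_s` seconds containing the day's two sessions with full
#' pre/post margins; daily metrics are computed over that recording.
#'
#' @param n_tavns,n_sham subjects per arm.
#' @param days_mean,days_sd recording duration distribution (days); realized
#'   per-subject counts are clipped to \[3, 13\].
#' @param sessions_per_day,session_minutes treatment schedule.
#' @param fs_ecg,fs_vitals nominal sampling rates, Hz.
#' @param arm_effects named vector of standardized effect sizes (Cohen's d)
#'   added to the active arm's change-from-day-1; names among `hr`, `rmssd`,
#'   `sdnn`, `qtc_mean`, `bp`, `icp`, `ppi`, `resp`.
#' @param acute list of mixed-model coefficients for the per-subject acute
#'   post-treatment heart-rate response (bpm): `b0`, `b_tavns`, `b_mrs`,
#'   `b_interaction`, `subject_sd`, `resid_sd`.
#' @param ppi_resp_corr correlation between daily PPI and respiration-rate
#'   changes, per arm (`tavns`, `sham`).
#' @param gap_fraction fraction of each day's recording lost to monitoring
#'   gaps, in \[0, 1).
#' @param ectopic_rate,outlier_rate injected RR anomaly rates.
#' @param day_duration_s length of each day's continuous recording, s.
#' @param seed root seed; all randomness flows from it.
#' @return list of class `synth_trial_spec`.
#' @export
synth_trial_spec <- function(n_tavns = 11, n_sham = 13,
                             days_mean = 11.1, days_sd = 6.8,
                             sessions_per_day = 2, session_minutes = 20,
                             fs_ecg = 500, fs_vitals = 1,
                             arm_effects = c(hr = -0.01, rmssd = 0.42,
                                             sdnn = 0.10, qtc_mean = -0.57,
                                             bp = 0, icp = 0,
                                             ppi = -0.49, resp = 0.37),
                             acute = list(b0 = 0.73, b_tavns = -0.29,
                                          b_mrs = 1.47, b_interaction = -1.85,
                                          subject_sd = 1, resid_sd = 2),
                             ppi_resp_corr = c(tavns = -0.37, sham = -0.08),
                             gap_fraction = 0.03,
                             ectopic_rate = 0, outlier_rate = 0,
                             day_duration_s = 9000, seed = 1) {
  stopifnot(n_tavns > 0, n_sham > 0, days_mean > 0, sessions_per_day > 0,
            session_minutes > 0, fs_ecg >= 250, fs_vitals > 0,
            gap_fraction >= 0, gap_fraction < 1, day_duration_s > 0)
  if (day_duration_s < sessions_per_day * 3 * session_minutes * 60 + 1200) {
    stop("day_duration_s too short to hold the sessions with pre/post margins")
  }
  structure(as.list(environment()), class = "synth_trial_spec")
}

# population daily-change noise SDs (units of each metric)
.change_sd <- c(hr = 6, rmssd = 8, sdnn = 10, qtc_mean = 15,
                bp = 8, icp = 2, ppi = 0.5, resp = 2.5)

ar1_series <- function(n, mu, sd, phi = 0.99) {
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, 0, sd)
  for (i in 2:n) x[i] <- phi * x[i - 1L] + e[i]
  mu + x
}

#' Generate a complete synthetic trial with ground truth
#'
#' Draws subject metadata, true daily metric trajectories (with the arm
#' effects of the spec applied to change-from-day-1), and for each
#' subject-day a continuous RR-interval recording realizing the day's true
#' heart rate and HRV, a per-beat QT series consistent with the day's true
#' QTc, 1 Hz vitals (AR(1) around the day's true means), a treatment-event
#' trace (rectangular pulse train plus sub-half-maximum noise), and the true
#' session intervals. Everything derives from the spec's root seed, so a
#' fixed seed reproduces the dataset exactly.
#'
#' @param spec a [synth_trial_spec()].
#' @param metrics_only skip the per-day RR/vitals/event synthesis and return
#'   only metadata and the true daily metric trajectories (fast path for
#'   studying the trajectory model itself, e.g. realized effect sizes across
#'   many seeds).
#' @return list with `spec`, `subjects` (metadata data frame), `truth_daily`
#'   (true per-subject-day metric values and changes), and `days`: a list of
#'   per-subject-day records, each containing `subject`, `day`, `rr`
#'   ([rr_series()]), `qt_ms` (per-beat), `truth_flags`, `vitals` (1 Hz data
#'   frame), `event_trace` (1 Hz), `sessions` (true onset/offset, s), and
#'   `acute_bump_bpm` (true per-session post-treatment heart-rate change).
#' @export
generate_trial <- function(spec, metrics_only = FALSE) {
  stopifnot(inherits(spec, "synth_trial_spec"))
  set.seed(spec$seed)
  n <- spec$n_tavns + spec$n_sham
  arms <- c(rep("tavns", spec$n_tavns), rep("sham", spec$n_sham))
  ids <- sprintf("S%02d", seq_len(n))

  decades <- sample(c(30, 40, 50, 60, 70, 80), n, replace = TRUE,
                    prob = c(1, 4, 4, 7, 6, 2))
  mrs_adm <- sample(1:5, n, replace = TRUE, prob = c(1, 8, 4, 5, 6))
  mrs_change <- pmax(pmin(round(stats::rnorm(n, -0.4, 1.3)), 6 - mrs_adm),
                     -mrs_adm)
  n_days <- pmin(pmax(round(stats::rnorm(n, spec$days_mean, spec$days_sd)), 3L), 13L)

  base <- data.frame(
    hr = pmin(pmax(stats::rnorm(n, 75, 8), 55), 100),
    rmssd = pmax(stats::rnorm(n, 30, 6), 12),
    sdnn = pmax(stats::rnorm(n, 48, 8), 25),
    qtc_mean = stats::rnorm(n, 420, 15),
    bp = stats::rnorm(n, 85, 8),
    icp = pmax(stats::rnorm(n, 12, 3), 4),
    ppi = pmax(stats::rnorm(n, 2, 0.5), 0.6),
    resp = pmax(stats::rnorm(n, 17, 2), 10))
  base$rmssd <- pmin(base$rmssd, 1.2 * base$sdnn)

  subjects <- data.frame(subject = ids, arm = arms, age_decade = decades,
                         mrs_admission = mrs_adm,
                         mrs_discharge = mrs_adm + mrs_change,
                         mrs_change = mrs_change, n_days = n_days,
                         stringsAsFactors = FALSE)

  metrics <- names(.change_sd)
  eff <- setNames(rep(0, length(metrics)), metrics)
  common <- intersect(names(spec$arm_effects), metrics)
  eff[common] <- spec$arm_effects[common]

  truth_rows <- list()
  days_out <- list()
  sess_len <- spec$session_minutes * 60
  margin <- 20 * 60

  for (i in seq_len(n)) {
    is_tavns <- arms[i] == "tavns"
    rho <- unname(if (is_tavns) spec$ppi_resp_corr["tavns"] else spec$ppi_resp_corr["sham"])
    # subject-level acute HR response (bpm), linked to clinical outcome
    bump_i <- with(spec$acute,
                   b0 + b_tavns * is_tavns + b_mrs * mrs_change[i] +
                     b_interaction * is_tavns * mrs_change[i] +
                     stats::rnorm(1L, 0, subject_sd))
    for (d in seq_len(n_days[i])) {
      delta <- setNames(rep(0, length(metrics)), metrics)
      if (d > 1L) {
        z <- stats::rnorm(length(metrics))
        names(z) <- metrics
        # correlated ppi / resp daily-change noise
        z["resp"] <- rho * z["ppi"] + sqrt(1 - rho^2) * z["resp"]
        delta <- z * .change_sd
        if (is_tavns) delta <- delta + eff * .change_sd
      }
      vals <- unlist(base[i, metrics]) + delta
      vals["rmssd"] <- max(vals["rmssd"], 8)
      vals["sdnn"] <- max(vals["sdnn"], vals["rmssd"] / 1.8, 15)
      vals["hr"] <- min(max(vals["hr"], 45), 140)
      vals["ppi"] <- max(vals["ppi"], 0.2)
      vals["resp"] <- max(vals["resp"], 8)
      vals["icp"] <- max(vals["icp"], 1)

      if (metrics_only) {
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(subject = ids[i], arm = arms[i], day = d,
                     as.list(vals), row.names = NULL)
        next
      }

      # --- RR recording for the day ---
      # clamp the RMSSD/SDNN ratio to what the two-band spectral model can
      # realize at this heart rate (all power in HF / all power in LF bounds);
      # the recorded ground truth below is the realized series, so extreme
      # trajectory draws saturate rather than misreport
      dt <- (60000 / vals["hr"]) / 1000
      r_max <- sqrt(2 * (1 - cos(2 * pi * 0.25 * dt)))
      r_min <- sqrt(2 * (1 - cos(2 * pi * 0.10 * dt)))
      vals["rmssd"] <- min(max(vals["rmssd"], 1.05 * r_min * vals["sdnn"]),
                           0.95 * r_max * vals["sdnn"])
      prm <- rr_gen_params(mean_rr = 60000 / vals["hr"],
                           sdnn_target = vals["sdnn"],
                           rmssd_target = vals["rmssd"],
                           ectopic_rate = spec$ectopic_rate,
                           outlier_rate = spec$outlier_rate)
      gen <- generate_rr_series(prm, spec$day_duration_s)
      rr <- gen$rr
      # ground truth records what the day's recording actually realizes
      vals["hr"] <- gen$truth$hr
      vals["rmssd"] <- gen$truth$rmssd
      vals["sdnn"] <- gen$truth$sdnn

      # session placement: fixed clock slots with jitter
      slots <- (seq_len(spec$sessions_per_day) - 0.5) *
        spec$day_duration_s / spec$sessions_per_day - sess_len / 2
      onsets <- slots + stats::runif(spec$sessions_per_day, -300, 300)
      onsets <- pmin(pmax(onsets, margin + 60),
                     spec$day_duration_s - sess_len - margin - 60)
      sessions <- data.frame(onset = onsets, offset = onsets + sess_len)

      # acute heart-rate response: scale RR inside during/post periods
      bump_s <- bump_i + stats::rnorm(nrow(sessions), 0, spec$acute$resid_sd)
      rr_mod <- rr$rr
      for (s in seq_len(nrow(sessions))) {
        dur <- rr$time >= sessions$onset[s] & rr$time < sessions$offset[s]
        pst <- rr$time >= sessions$offset[s] & rr$time < sessions$offset[s] + margin
        rr_mod[dur] <- rr_mod[dur] * vals["hr"] / (vals["hr"] + 0.5 * bump_s[s])
        rr_mod[pst] <- rr_mod[pst] * vals["hr"] / (vals["hr"] + bump_s[s])
      }
      rr <- rr_series(cumsum(rr_mod) / 1000, rr_mod)

      # monitoring gaps: drop beats in random windows
      truth_flags <- gen$truth_flags
      if (spec$gap_fraction > 0) {
        total_gap <- spec$gap_fraction * spec$day_duration_s
        gstarts <- sort(stats::runif(max(1L, round(total_gap / 90)), 0,
                                     spec$day_duration_s - 90))
        drop <- rep(FALSE, nrow(rr))
        for (gs in gstarts) drop <- drop | (rr$time >= gs & rr$time < gs + 90)
        if (any(!drop)) {
          rr <- rr[!drop, , drop = FALSE]
          class(rr) <- c("rr_series", "data.frame")
          truth_flags <- truth_flags[!drop]
        }
      }

      qt <- vals["qtc_mean"] * sqrt(rr$rr / 1000)  # Bazett-constant beats

      # vitals at 1 Hz
      nv <- as.integer(spec$day_duration_s * spec$fs_vitals)
      vitals <- data.frame(
        t = seq_len(nv) / spec$fs_vitals,
        bp = ar1_series(nv, vals["bp"], 5),
        icp = ar1_series(nv, vals["icp"], 1.5),
        ppi = pmax(ar1_series(nv, vals["ppi"], 0.25), 0.05),
        resp = pmax(ar1_series(nv, vals["resp"], 1.2), 5))

      trace <- stats::rnorm(nv, 0, 0.08)
      for (s in seq_len(nrow(sessions))) {
        sel <- vitals$t >= sessions$onset[s] & vitals$t < sessions$offset[s]
        trace[sel] <- trace[sel] + 1
      }

      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(subject = ids[i], arm = arms[i], day = d,
                   as.list(vals), row.names = NULL)
      days_out[[length(days_out) + 1L]] <-
        list(subject = ids[i], day = d, arm = arms[i], rr = rr, qt_ms = qt,
             truth_flags = truth_flags, vitals = vitals, event_trace = trace,
             sessions = sessions, acute_bump_bpm = bump_s)
    }
  }

  truth_daily <- do.call(rbind, truth_rows)
  # change-from-day-1 columns
  for (m in metrics) {
    d1 <- truth_daily[truth_daily$day == 1L, c("subject", m)]
    truth_daily[[paste0("d_", m)]] <-
      truth_daily[[m]] - d1[[m]][match(truth_daily$subject, d1$subject)]
  }
  list(spec = spec, subjects = subjects, truth_daily = truth_daily,
       days = days_out)
}

#' Write a synthetic trial to disk as plain-text CSV
#'
#' Emits `subjects.csv`, `truth_daily.csv`, and per subject-day
#' `rr_<id>_d<day>.csv` (beat time, RR ms, QT ms, truth flag),
#' `vitals_<id>_d<day>.csv`, `events_<id>_d<day>.csv` (1 Hz trace) and
#' `sessions_<id>_d<day>.csv`.
#'
#' @param trial output of [generate_trial()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(trial$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(trial$truth_daily, file.path(dir, "truth_daily.csv"), row.names = FALSE)
  for (rec in trial$days) {
    tag <- sprintf("%s_d%02d", rec$subject, rec$day)
    utils::write.csv(data.frame(time_s = rec$rr$time, rr_ms = rec$rr$rr,
                                qt_ms = rec$qt_ms, truth_flag = rec$truth_flags),
                     file.path(dir, paste0("rr_", tag, ".csv")), row.names = FALSE)
    utils::write.csv(rec$vitals, file.path(dir, paste0("vitals_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(trace = rec$event_trace),
                     file.path(dir, paste0("events_", tag, ".csv")), row.names = FALSE)
    utils::write.csv(rec$sessions, file.path(dir, paste0("sessions_", tag, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
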