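#' Parameters for synthetic RR-interval generation
#'
#' The generator uses a two-band spectral model of heart rate variability: a
#' low-frequency band (baroreflex-related, default centered at 0.10 Hz) and a
#' high-frequency band (respiratory sinus arrhythmia, default 0.25 Hz). Band
#' variances are solved so that the realized SDNN and RMSSD of the
#' beat-sampled series match the requested targets, which gives independent
#' control over overall variability and short-term (parasympathetic)
#' variability.
#'
#' @param mean_rr mean RR interval, ms (300-2000).
#' @param sdnn_target,rmssd_target time-domain HRV targets, ms.
#' @param lf_center,hf_center band center frequencies, Hz.
#' @param lf_width,hf_width Gaussian band widths (SD), Hz.
#' @param ectopic_rate,outlier_rate fraction of beats replaced by ectopic /
#'   outlier intervals, each in \[0, 0.2\].
#' @param seed optional integer seed.
#' @return list of class `rr_gen_params`.
#' @export
rr_gen_params <- function(mean_rr = 800, sdnn_target = 50, rmssd_target = 30,
                          lf_center = 0.1, hf_center = 0.25,
                          lf_width = 0.02, hf_width = 0.04,
                          ectopic_rate = 0, outlier_rate = 0, seed = NULL) {
  if (!(mean_rr > 300 && mean_rr < 2000)) stop("mean_rr must be in (300, 2000) ms")
  if (sdnn_target <= 0 || rmssd_target <= 0) stop("HRV targets must be positive")
  if (rmssd_target > 2 * sdnn_target) {
    stop("infeasible targets: rmssd_target > 2 * sdnn_target")
  }
  if (ectopic_rate < 0 || ectopic_rate > 0.2 || outlier_rate < 0 || outlier_rate > 0.2) {
    stop("anomaly rates must be in [0, 0.2]")
  }
  structure(list(mean_rr = mean_rr, sdnn_target = sdnn_target,
                 rmssd_target = rmssd_target,
                 lf_center = lf_center, hf_center = hf_center,
                 lf_width = lf_width, hf_width = hf_width,
                 ectopic_rate = ectopic_rate, outlier_rate = outlier_rate,
                 seed = seed),
            class = "rr_gen_params")
}

# One unit-variance narrowband Gaussian series on an even grid, by inverse FFT
# of a Gaussian spectral envelope with uniform random phases.
narrowband_series <- function(n, fs, f_center, f_width) {
  freq <- (0:(n - 1)) * fs / n
  half <- freq > fs / 2
  freq[half] <- freq[half] - fs
  amp <- exp(-(abs(freq) - f_center)^2 / (2 * f_width^2))
  amp[1L] <- 0
  phase <- stats::runif(n, 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  (x - mean(x)) / s
}

#' Generate a synthetic RR-interval series with known ground truth
#'
#' Draws an RR tachogram from the two-band spectral model of
#' [rr_gen_params()], beat-samples it, rescales the two band amplitudes so the
#' realized SDNN and RMSSD hit the targets, and optionally injects labeled
#' ectopic beats (> 20% jump from the previous interval) and outliers
#' (> 2 s or < 300 ms). Every injected anomaly is recorded in the returned
#' truth flags, so interval-cleaning recall can be scored exactly.
#'
#' @param params an [rr_gen_params()].
#' @param duration_s recording length in seconds (>= 120).
#' @return list with `rr` (an [rr_series()], flags all `"valid"`, anomalies
#'   included unflagged), `truth_flags` (character, the injected label per
#'   interval), and `truth` (realized clean-series metrics: `sdnn`, `rmssd`,
#'   `mean_rr`, `hr`).
#' @export
generate_rr_series <- function(params, duration_s) {
  stopifnot(inherits(params, "rr_gen_params"))
  if (duration_s < 120) stop("duration_s must be >= 120 s")
  if (!is.null(params$seed)) set.seed(params$seed)

  fs_grid <- 4
  n_grid <- as.integer(ceiling(duration_s * fs_grid)) + 8L
  u_lf <- narrowband_series(n_grid, fs_grid, params$lf_center, params$lf_width)
  u_hf <- narrowband_series(n_grid, fs_grid, params$hf_center, params$hf_width)

  # beat-sample the band series at nominal beat times
  n_beats <- as.integer(floor(duration_s * 1000 / params$mean_rr))
  t_nom <- (seq_len(n_beats)) * params$mean_rr / 1000
  idx <- pmin(pmax(1L, as.integer(round(t_nom * fs_grid)) + 1L), n_grid)
  bl <- u_lf[idx]; bh <- u_hf[idx]

  # Solve band amplitudes a, b so that realized SDNN and RMSSD match targets:
  # sdnn^2 and rmssd^2 are exact quadratic forms in (a, b) for this
  # realization, so two Newton steps on the 2x2 moment system suffice.
  S2 <- params$sdnn_target^2
  R2 <- params$rmssd_target^2
  dl <- diff(bl); dh <- diff(bh)
  v_ll <- stats::var(bl); v_hh <- stats::var(bh); v_lh <- stats::cov(bl, bh)
  m_ll <- mean(dl^2); m_hh <- mean(dh^2); m_lh <- mean(dl * dh)
  obj <- function(p) {
    a <- p[1L]; b <- p[2L]
    s2 <- a^2 * v_ll + 2 * a * b * v_lh + b^2 * v_hh
    r2 <- a^2 * m_ll + 2 * a * b * m_lh + b^2 * m_hh
    (s2 - S2)^2 / S2^2 + (r2 - R2)^2 / R2^2
  }
  # analytic start ignoring cross-moments
  den <- v_ll * m_hh - v_hh * m_ll
  b2 <- (R2 * v_ll - S2 * m_ll) / den
  a2 <- (S2 * m_hh - R2 * v_hh) / den
  start <- sqrt(pmax(c(a2, b2), 1e-6))
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 0), control = list(maxit = 200))
  a <- fit$par[1L]; b <- fit$par[2L]

  rr <- params$mean_rr + a * bl + b * bh
  rr <- pmin(pmax(rr, 320), 1950)  # keep the clean series inside outlier bounds

  truth <- list(sdnn = stats::sd(rr),
                rmssd = sqrt(mean(diff(rr)^2)),
                mean_rr = mean(rr),
                hr = 60000 / mean(rr))

  truth_flags <- rep("valid", n_beats)
  if (params$outlier_rate > 0) {
    k <- stats::rbinom(1L, n_beats, params$outlier_rate)
    if (k > 0) {
      pick <- sample(n_beats, k)
      long <- stats::runif(k) < 0.5
      rr[pick] <- ifelse(long, stats::runif(k, 2100, 2600),
                         stats::runif(k, 150, 280))
      truth_flags[pick] <- "outlier"
    }
  }
  if (params$ectopic_rate > 0) {
    candidates <- which(truth_flags == "valid")
    candidates <- candidates[candidates > 1L]
    # never right after an outlier: the ectopic rule compares to the previous
    # retained interval
    candidates <- candidates[truth_flags[candidates - 1L] == "valid"]
    k <- stats::rbinom(1L, length(candidates), params$ectopic_rate)
    if (k > 0) {
      pick <- sort(sample(candidates, k))
      pick <- pick[c(TRUE, diff(pick) > 1L)]  # no adjacent ectopics
      frac <- stats::runif(length(pick), 0.25, 0.45)
      sgn <- ifelse(stats::runif(length(pick)) < 0.5, -1, 1)
      prop <- rr[pick - 1L] * (1 + sgn * frac)
      # keep injected ectopics inside the outlier bounds so the labels stay
      # exclusive
      bad <- prop < 310 | prop > 1990
      prop[bad] <- rr[pick - 1L][bad] * (1 + frac[bad])
      rr[pick] <- prop
      truth_flags[pick] <- "ectopic"
    }
  }

  times <- cumsum(rr) / 1000
  list(rr = rr_series(times, rr),
       truth_flags = truth_flags,
       truth = truth)
}
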