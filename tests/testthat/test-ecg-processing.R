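test_that("preprocessing removes DC and attenuates powerline by >= 20 dB", {
  fs <- 500
  dc <- ecg_record(rep(1, 30 * fs), fs = fs)
  out <- ecg_preprocess(dc)
  mid <- out$samples[(5 * fs):(25 * fs)]
  expect_lt(max(abs(mid)), 0.01)

  tt <- (0:(30 * fs - 1)) / fs
  pl <- ecg_record(sin(2 * pi * 60 * tt), fs = fs)
  filt <- ecg_preprocess(pl)
  power_in <- mean(pl$samples[(5 * fs):(25 * fs)]^2)
  power_out <- mean(filt$samples[(5 * fs):(25 * fs)]^2, na.rm = TRUE)
  expect_gt(10 * log10(power_in / power_out), 20)
})

test_that("filtering preserves R-peak deflections of clean ECG within 5%", {
  # the high-pass removes the baseline (DC) level by design, so amplitude is
  # measured as the R-to-S deflection, which filtering must not attenuate
  syn <- make_clean_ecg(duration_s = 60, seed = 9)
  filt <- ecg_preprocess(syn$ecg)
  r <- syn$truth$r_peak
  r <- r[r > 5 * 500 & r < length(filt$samples) - 5 * 500]
  deflect <- function(x) vapply(r, function(i) x[i] - min(x[i:(i + 20)]),
                                numeric(1))
  amp_in <- deflect(syn$ecg$samples)
  amp_out <- deflect(filt$samples)
  expect_lt(max(abs(amp_out - amp_in) / amp_in), 0.05)
})

test_that("gaps are propagated, not interpolated, and short segments are excluded", {
  syn <- make_clean_ecg(duration_s = 40, seed = 2)
  gaps <- rep(FALSE, length(syn$ecg$samples))
  gaps[5000:6000] <- TRUE
  ecg <- ecg_record(syn$ecg$samples, fs = 500, gaps = gaps)
  # carve out a stranded segment shorter than the warm-up
  gaps2 <- gaps; gaps2[6300:20000] <- TRUE  # leaves 6001..6299 isolated
  ecg2 <- ecg_record(syn$ecg$samples, fs = 500, gaps = gaps2)
  out <- ecg_preprocess(ecg)
  expect_true(all(is.na(out$samples[5000:6000])))
  out2 <- ecg_preprocess(ecg2)
  expect_true(all(out2$gaps[6001:6299]))  # flagged, excluded from detection
})

test_that("R-peak detection is near-perfect on clean data and robust to noise", {
  syn <- make_clean_ecg(duration_s = 300, seed = 4)
  filt <- ecg_preprocess(syn$ecg)
  peaks <- detect_r_peaks(filt)
  m <- match_peaks(peaks, syn$truth$r_peak, fs = 500)
  expect_gte(m$sensitivity, 0.995)
  expect_gte(m$precision, 0.995)
  expect_lte(m$mae_ms, 4)
  # refractory: no two peaks closer than 200 ms
  expect_true(all(diff(peaks) >= 0.2 * 500))

  # SNR 10 dB additive noise
  sig_pow <- mean(syn$ecg$samples^2)
  noisy <- ecg_record(syn$ecg$samples +
                        rnorm(length(syn$ecg$samples), 0, sqrt(sig_pow / 10)),
                      fs = 500)
  mn <- match_peaks(detect_r_peaks(ecg_preprocess(noisy)),
                    syn$truth$r_peak, fs = 500)
  expect_gte(mn$sensitivity, 0.99)
})

test_that("flat-line input yields zero peaks with a warning", {
  flat <- ecg_record(rep(0, 15 * 500), fs = 500)
  expect_warning(p <- detect_r_peaks(ecg_preprocess(flat)), "no QRS")
  expect_length(p, 0)
})

test_that("delineation recovers QT and T offset within tolerance on clean ECG", {
  syn <- make_clean_ecg(duration_s = 180, seed = 6)
  filt <- ecg_preprocess(syn$ecg)
  peaks <- detect_r_peaks(filt)
  fid <- delineate(filt, peaks)
  near <- vapply(fid$r_peak, function(i) which.min(abs(syn$truth$r_peak - i)),
                 integer(1))
  ok <- abs(syn$truth$r_peak[near] - fid$r_peak) < 25
  expect_gt(mean(ok), 0.99)
  qt_err <- mean(fid$qt_ms[ok] - syn$truth$qt_ms[near][ok], na.rm = TRUE)
  expect_lt(abs(qt_err), 10)
  t_err <- mean(abs(fid$t_offset - syn$truth$t_offset[near])[ok], na.rm = TRUE) / 500 * 1000
  expect_lte(t_err, 12)
})

test_that("beats without a T wave carry absent T fields", {
  rrs <- rr_series((1:100) * 0.8, rep(800, 100))
  syn <- synthesize_ecg(rrs, qt_fun = NULL, fs = 500)
  filt <- ecg_preprocess(syn$ecg)
  fid <- delineate(filt, detect_r_peaks(filt))
  expect_gt(nrow(fid), 50)
  expect_true(all(is.na(fid$t_peak)))
  expect_true(all(is.na(fid$qt_ms)))
})

test_that("delineation is invariant to signal amplitude scaling", {
  syn <- make_clean_ecg(duration_s = 60, seed = 13)
  filt <- ecg_preprocess(syn$ecg)
  peaks <- detect_r_peaks(filt)
  fid1 <- delineate(filt, peaks)
  doubled <- ecg_record(filt$samples * 2, fs = 500)
  fid2 <- delineate(doubled, peaks)
  expect_identical(fid1$qrs_onset, fid2$qrs_onset)
  expect_identical(fid1$t_offset, fid2$t_offset)
})

test_that("emitted fiducials always respect the ordering invariant", {
  syn <- make_clean_ecg(duration_s = 120, seed = 17, noise_sd = 0.05)
  filt <- ecg_preprocess(syn$ecg)
  fid <- delineate(filt, detect_r_peaks(filt))
  cols <- c("p_onset", "p_peak", "p_offset", "qrs_onset", "r_peak",
            "qrs_offset", "t_peak", "t_offset")
  ok <- apply(fid[, cols], 1, function(v) all(diff(v[!is.na(v)]) > 0))
  expect_true(all(ok))
})

test_that("detected beat count agrees with an independent amplitude-based oracle", {
  # oracle: local maxima above half the 95th-percentile amplitude with a
  # 300 ms spacing constraint -- a different route from the gradient detector
  oracle_count <- function(x, fs) {
    thr <- 0.5 * quantile(x, 0.95)
    cand <- which(x > thr)
    cand <- cand[c(TRUE, diff(cand) > 1)]
    n <- 0L; last <- -Inf
    for (i in cand) {
      if (i - last > 0.3 * fs) { n <- n + 1L; last <- i }
    }
    n
  }
  set.seed(31)
  for (rep in 1:25) {
    p <- rr_gen_params(mean_rr = runif(1, 650, 1100),
                       sdnn_target = runif(1, 25, 60),
                       rmssd_target = runif(1, 15, 35))
    g <- generate_rr_series(p, 120)
    syn <- synthesize_ecg(g$rr, fs = 500)
    filt <- ecg_preprocess(syn$ecg)
    n_det <- length(detect_r_peaks(filt))
    n_oracle <- oracle_count(filt$samples, 500)
    expect_lte(abs(n_det - n_oracle) / n_oracle, 0.005)
  }
})

test_that("event binarization recovers pulse trains and honors the duration filter", {
  fs <- 1
  trace <- rep(0, 7200)
  trace[1001:2200] <- 1   # 20-min pulse
  trace[4001:5200] <- 1
  iv <- binarize_events(trace, fs = fs)
  expect_equal(iv$onset, c(1001L, 4001L))
  expect_equal(iv$offset, c(2200L, 5200L))

  set.seed(14)
  noisy <- trace + rnorm(length(trace), 0, 0.1)
  ivn <- binarize_events(noisy, fs = fs)
  expect_equal(nrow(ivn), 2L)
  expect_lte(max(abs(ivn$onset - iv$onset)), 2)
  expect_lte(max(abs(ivn$offset - iv$offset)), 2)

  blip <- rep(0, 600); blip[100:109] <- 1
  expect_equal(nrow(binarize_events(blip, fs = 1, min_duration_s = 60)), 0L)
  expect_equal(nrow(binarize_events(rep(0, 100), fs = 1)), 0L)
})
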