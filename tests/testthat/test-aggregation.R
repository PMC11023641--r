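test_that("daily summary enforces the coverage minimum", {
  g <- generate_rr_series(rr_gen_params(seed = 1), 3600)  # 1 h of data
  s <- daily_summary(clean_rr(g$rr), min_coverage_s = 4 * 3600)
  expect_match(s$reason, "coverage")
  s2 <- daily_summary(clean_rr(g$rr), min_coverage_s = 1800)
  expect_null(s2$reason)
  expect_equal(s2$hr, g$truth$hr, tolerance = 0.01)
})

test_that("trial summaries recover true daily HR and HRV on clean data", {
  spec <- synth_trial_spec(n_tavns = 2, n_sham = 2, days_mean = 3,
                           days_sd = 0.1, gap_fraction = 0,
                           acute = list(b0 = 0, b_tavns = 0, b_mrs = 0,
                                        b_interaction = 0, subject_sd = 0,
                                        resid_sd = 0),
                           day_duration_s = 8400, seed = 11)
  tr <- generate_trial(spec)
  daily <- trial_daily_summaries(tr)
  truth <- tr$truth_daily
  j <- match(paste(daily$subject, daily$day), paste(truth$subject, truth$day))
  expect_lt(max(abs(daily$hr - truth$hr[j])), 1)          # HR within 1 bpm
  expect_lt(max(abs(daily$rmssd / truth$rmssd[j] - 1)), 0.05)
  expect_lt(max(abs(daily$sdnn / truth$sdnn[j] - 1)), 0.05)
  expect_lt(max(abs(daily$qtc_mean - truth$qtc_mean[j])), 1)
  # change columns are zero on day 1 by construction
  expect_true(all(daily$d_hr[daily$day == 1] == 0))
  expect_true(all(daily$d_rmssd[daily$day == 1] == 0))
})

test_that("three-day bins partition days 2-13 and exclude the baseline", {
  df <- data.frame(day = 1:15, x = rnorm(15))
  b <- bin_days(df)
  expect_false(1 %in% b$day)
  expect_false(any(b$day > 13))
  expect_equal(as.character(b$bin[b$day == 4]), "Day 2-4")
  expect_equal(as.character(b$bin[b$day == 5]), "Day 5-7")
  expect_equal(as.character(b$bin[b$day == 11]), "Day 11-13")
  expect_equal(unname(table(b$bin)["Day 2-4"]), 3L)
})

test_that("a 20-minute period holds exactly five fully contained windows", {
  g <- generate_rr_series(rr_gen_params(seed = 3), 5000)
  rr <- clean_rr(g$rr)
  sess <- data.frame(onset = 2000, offset = 3200)
  el <- event_locked(rr, sess, metric = "hr", day_length_s = 5000)
  # windows at offsets 0,3,6,9,12 min inside each 20-min period
  on_win <- el$windows[el$windows$align == "onset" &
                         el$windows$offset_s >= 0 &
                         el$windows$offset_s + 360 <= 1200, ]
  expect_equal(nrow(on_win), 5L)
  expect_equal(on_win$offset_s, c(0, 180, 360, 540, 720))
  expect_true(all(is.finite(el$periods$d_during_pre)))
})

test_that("a constant metric yields zero daily SD and absent normalized values", {
  rr <- clean_rr(rr_series((1:6000) * 0.8, rep(800, 6000)))
  sess <- data.frame(onset = 2000, offset = 3200)
  el <- event_locked(rr, sess, metric = "hr", day_length_s = 4800)
  expect_equal(el$reference$sd, 0)
  expect_true(all(is.na(el$windows$norm)))
  expect_true(all(is.na(el$periods$d_post_pre_norm)))
})

test_that("z-score normalization is idempotent and shift-invariant", {
  g <- generate_rr_series(rr_gen_params(seed = 8), 5000)
  rr <- clean_rr(g$rr)
  sess <- data.frame(onset = 1800, offset = 3000)
  el1 <- event_locked(rr, sess, metric = "hr", day_length_s = 5000)
  v <- el1$windows$norm[is.finite(el1$windows$norm)]
  # z-scoring an already z-scored series changes nothing: the normalized
  # reference distribution has mean ~0, SD ~1
  ref_w <- seq(0, 5000 - 360, by = 180)
  zvals <- (vapply(ref_w, function(a)
    hrvtrial:::window_metric(rr, a, a + 360, "hr"), numeric(1)) -
      el1$reference$mean) / el1$reference$sd
  zvals <- zvals[is.finite(zvals)]
  expect_equal(mean(zvals), 0, tolerance = 1e-8)
  expect_equal(sd(zvals), 1, tolerance = 1e-8)

  # adding a constant to the metric leaves normalized deltas unchanged:
  # shift HR by scaling all RR by a constant factor
  rr2 <- rr_series(rr$time, rr$rr * 0.9, rr$flag)
  el2 <- event_locked(rr2, sess, metric = "hr", day_length_s = 5000)
  expect_lt(max(abs(el2$periods$d_post_pre_norm - el1$periods$d_post_pre_norm)),
            0.2)
})

test_that("an injected half-SD heart-rate bump is recovered in normalized units", {
  # deterministic slow HR profile, so the daily-window SD is dominated by the
  # known diurnal swing rather than beat-level noise; the session sits
  # symmetrically on a crest so pre and post see the same baseline
  day_len <- 7200
  sess <- data.frame(onset = 3000, offset = 4200)
  crest <- 3540  # midpoint of the pre- and post-period window centers
  hr_of <- function(t) 75 + 5 * cos(2 * pi * (t - crest) / day_len)
  t <- 0; times <- c(); rrv <- c()
  while (t < day_len) {
    rr_ms <- 60000 / hr_of(t)
    t <- t + rr_ms / 1000
    times <- c(times, t); rrv <- c(rrv, rr_ms)
  }
  rr <- clean_rr(rr_series(times, rrv))
  el0 <- event_locked(rr, sess, metric = "hr", day_length_s = day_len)
  bump <- 0.5 * el0$reference$sd
  post <- rr$time >= sess$offset & rr$time < sess$offset + 1200
  v <- rr$rr
  v[post] <- v[post] * hr_of(sess$offset + 600) /
    (hr_of(sess$offset + 600) + bump)
  rr_b <- clean_rr(rr_series(cumsum(v) / 1000, v))
  el <- event_locked(rr_b, sess, metric = "hr", day_length_s = day_len)
  expect_lt(abs(el$periods$d_post_pre_norm - 0.5), 0.1)
})

test_that("windows touching flagged-out stretches are dropped", {
  g <- generate_rr_series(rr_gen_params(seed = 9), 5000)
  rr <- clean_rr(g$rr)
  drop <- rr$time >= 2500 & rr$time < 2700  # simulated monitoring gap
  rr2 <- rr[!drop, , drop = FALSE]
  class(rr2) <- c("rr_series", "data.frame")
  val <- hrvtrial:::window_metric(rr2, 2400, 2760, "hr")
  expect_true(is.na(val))
  val_ok <- hrvtrial:::window_metric(rr2, 1000, 1360, "hr")
  expect_true(is.finite(val_ok))
})
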