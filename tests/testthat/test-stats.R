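test_that("group comparison gates on normality and reports pooled-SD effect size", {
  set.seed(1)
  a <- rnorm(40); b <- rnorm(40, 0.8)
  r <- compare_groups(a, b)
  expect_equal(r$test, "t-test")
  sp <- sqrt((39 * var(a) + 39 * var(b)) / 78)
  expect_equal(r$d, (mean(a) - mean(b)) / sp)

  # heavy-tailed data routes to Mann-Whitney
  a2 <- rcauchy(60); b2 <- rcauchy(60)
  r2 <- compare_groups(a2, b2)
  expect_equal(r2$test, "Mann-Whitney U")

  # identical tied groups: no effect, p = 1
  same <- rep(c(1, 2, 3), 10)
  r3 <- compare_groups(same, same)
  expect_equal(r3$d, 0)
  expect_equal(r3$p, 1)
})

test_that("Bonferroni correction caps at 1 and preserves p ordering", {
  set.seed(4)
  ps <- replicate(20, {
    r <- compare_groups(rnorm(10), rnorm(10), bonferroni_factor = 6)
    c(r$p, r$p_corrected)
  })
  expect_true(all(ps[2, ] <= 1))
  expect_true(all(ps[2, ] >= ps[1, ]))
  expect_false(is.unsorted(ps[2, order(ps[1, ])]))  # ordering preserved
  expect_equal(ps[2, ], pmin(1, ps[1, ] * 6))
})

test_that("rejection frequency under d = 0.5 matches the analytic power", {
  set.seed(7)
  rej <- mean(replicate(400, {
    r <- compare_groups(rnorm(94), rnorm(95, -0.5))
    r$p < 0.05
  }))
  expect_equal(rej, power_two_sample_t(94, 95, 0.5, 0.05), tolerance = 0.05)
})

test_that("signed-rank test behaves at the null, under shift, and rejects zeros", {
  sym <- rep(c(2, -2), 15)
  r <- signed_rank_vs_zero(sym)
  expect_gt(r$p, 0.5)

  r2 <- signed_rank_vs_zero(abs(rnorm(20)) + 0.1)
  expect_lt(r2$p, 0.001)

  expect_error(signed_rank_vs_zero(rep(0, 10)), "nonzero")
})

test_that("TOST declares equivalence only inside the margin", {
  set.seed(12)
  a <- rnorm(100); b <- rnorm(100)
  expect_true(tost_equivalence(a, b, margin = 2)$equivalent)

  # mean difference exactly at the margin: one-sided p ~ 0.5, not equivalent
  b2 <- rnorm(100)
  a2 <- b2 + 2 + rnorm(100, 0, 0.001)
  r <- tost_equivalence(a2, b2, margin = 2)
  expect_false(r$equivalent)
  expect_equal(r$p_upper, 0.5, tolerance = 0.15)

  # ICP-like scenario: true difference 0, margin 2 mmHg, SD 2, n ~ 95
  a3 <- rnorm(94, 10, 2); b3 <- rnorm(95, 10, 2)
  r3 <- tost_equivalence(a3, b3, margin = 2)
  expect_lt(r3$p_lower, 1e-5)
  expect_lt(r3$p_upper, 1e-5)
  expect_error(tost_equivalence(a, b, margin = -1), "margin")
})

test_that("noncentral-t power is monotone and consistent with required_n", {
  expect_equal(power_two_sample_t(10, 10, 0, 0.05), 0.05, tolerance = 1e-10)
  expect_lt(power_two_sample_t(10, 10, 0.5), power_two_sample_t(40, 40, 0.5))
  expect_lt(power_two_sample_t(40, 40, 0.3), power_two_sample_t(40, 40, 0.6))
  # round trip: required_n(power achieved at n) <= n
  for (n in c(30, 64, 100)) {
    pw <- power_two_sample_t(n, n, 0.5)
    expect_lte(required_n(pw - 1e-9, 0.5), n)
  }
})

test_that("interaction regression recovers a known slope difference", {
  set.seed(9)
  n_sub <- 40
  tab <- expand.grid(day = 2:12, id = 1:n_sub)
  tab$arm <- ifelse(tab$id <= n_sub / 2, "tavns", "sham")
  tab$d_rmssd <- -1.5 * tab$day + 2.0 * tab$day * (tab$arm == "tavns") +
    rnorm(nrow(tab), 0, 3)
  fit <- interaction_regression(tab)
  expect_equal(unname(fit$interaction), 2.0, tolerance = 0.15)

  # identical arms: interaction ~ 0
  tab0 <- tab
  tab0$d_rmssd <- -1.5 * tab0$day + rnorm(nrow(tab0), 0, 3)
  expect_lt(abs(interaction_regression(tab0)$interaction), 0.2)

  # OLS equals the normal equations on a small table
  small <- data.frame(day = rep(1:5, 2), arm = rep(c("sham", "tavns"), each = 5),
                      d_rmssd = c(1, 3, 2, 5, 4, 2, 6, 7, 9, 11))
  fit2 <- interaction_regression(small)
  X <- model.matrix(~ day * relevel(factor(small$arm), "sham"), small)
  beta <- solve(t(X) %*% X, t(X) %*% small$d_rmssd)
  expect_equal(unname(fit2$coefficients[, 1]), as.numeric(beta))
})

test_that("mixed model degenerates to OLS without subject variance", {
  set.seed(15)
  d <- expand.grid(session = 1:6, subject = sprintf("s%02d", 1:12))
  d$arm <- ifelse(as.integer(factor(d$subject)) <= 6, "tavns", "sham")
  d$mrs_change <- rep(sample(-2:1, 12, replace = TRUE), each = 6)
  e <- rnorm(nrow(d))
  e <- e - ave(e, d$subject)  # exactly zero between-subject variance
  d$d_hr <- 0.5 + 1.2 * d$mrs_change + e
  expect_warning(fit <- fit_mixed_model(d, response = "d_hr"), "singular|OLS")
  ols <- lm(d_hr ~ relevel(factor(arm), "sham") * mrs_change, data = d)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-6)

  d0 <- d; d0$d_hr <- 0
  expect_warning(f0 <- fit_mixed_model(d0, response = "d_hr"))
  expect_equal(unname(f0$coefficients$estimate), rep(0, 4), tolerance = 1e-10)
})

test_that("mixed model estimates the arm-by-outcome interaction", {
  set.seed(22)
  d <- expand.grid(session = 1:8, subject = sprintf("s%02d", 1:24))
  arm_of <- rep(c("tavns", "sham"), c(11, 13))
  d$arm <- arm_of[as.integer(factor(d$subject))]
  mrs <- sample(-3:1, 24, replace = TRUE)
  d$mrs_change <- mrs[as.integer(factor(d$subject))]
  u <- rnorm(24, 0, 1)
  d$d_hr <- 0.73 - 0.29 * (d$arm == "tavns") + 1.47 * d$mrs_change -
    1.85 * (d$arm == "tavns") * d$mrs_change +
    u[as.integer(factor(d$subject))] + rnorm(nrow(d), 0, 2)
  fit <- fit_mixed_model(d, response = "d_hr")
  est <- fit$coefficients["arm_x_mrs_change", ]
  expect_lt(abs(est$estimate - -1.85), 3 * est$se)
  expect_lt(est$se, 0.8)
  expect_true(est$ci_lo < est$estimate && est$ci_hi > est$estimate)
  expect_gt(fit$subject_sd, 0.2)
})

test_that("ANCOVA adjusts the arm effect for age", {
  set.seed(30)
  n <- 200
  arm <- rep(c("tavns", "sham"), each = n / 2)
  age <- sample(seq(35, 85, 10), n, replace = TRUE)
  # age-driven decline, no true arm effect
  y <- -0.4 * age + rnorm(n, 0, 3)
  fit <- ancova_age(data.frame(d_rmssd = y, arm = arm, age = age))
  expect_equal(fit$age_coef, -0.4, tolerance = 0.1)
  expect_lt(abs(fit$arm_effect), 1)

  # age uncorrelated with outcome: adjusted ~ unadjusted arm effect
  y2 <- 2 * (arm == "tavns") + rnorm(n)
  fit2 <- ancova_age(data.frame(d_rmssd = y2, arm = arm, age = age))
  raw <- mean(y2[arm == "tavns"]) - mean(y2[arm == "sham"])
  expect_equal(fit2$arm_effect, raw, tolerance = 0.15)

  # matches OLS brute force
  small <- data.frame(d_rmssd = c(1, 2, 3, 4, 6, 5, 8, 7),
                      arm = rep(c("sham", "tavns"), 4),
                      age = c(40, 50, 60, 70, 45, 55, 65, 75))
  f3 <- ancova_age(small)
  X <- model.matrix(~ relevel(factor(arm), "sham") + age, small)
  beta <- solve(t(X) %*% X, t(X) %*% small$d_rmssd)
  expect_equal(f3$arm_effect, beta[2], tolerance = 1e-10)

  expect_warning(ancova_age(data.frame(d_rmssd = rnorm(10),
                                       arm = rep(c("a", "b"), 5), age = 60)),
                 "constant")
})

test_that("Pearson correlation recovers known coupling", {
  x <- rnorm(50)
  r <- pearson_corr(x, -x)
  expect_equal(r$r, -1)
  expect_error(pearson_corr(x, rep(1, 50)), "variance")

  set.seed(41)
  rs <- replicate(300, {
    z1 <- rnorm(130); z2 <- -0.37 * z1 + sqrt(1 - 0.37^2) * rnorm(130)
    pearson_corr(z1, z2)$r
  })
  expect_equal(mean(rs), -0.37, tolerance = 0.02)

  # type-I error near nominal under independence
  set.seed(43)
  rej <- mean(replicate(500, pearson_corr(rnorm(30), rnorm(30))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.025)
})
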