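# treatment factor with the sham/control level as reference when present
arm_factor <- function(x) {
  f <- factor(x)
  if ("sham" %in% levels(f)) f <- stats::relevel(f, ref = "sham")
  f
}

#' Cohen's d with pooled sample SD
#'
#' Signed as `(mean(a) - mean(b)) / pooled SD`; by the pipeline's convention
#' the first group is the active (taVNS) arm, so negative d means the sham
#' group is larger.
#'
#' @param a,b numeric samples.
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk is run on each group; a (pooled-variance) t-test is used only
#' when both groups pass at the 0.05 level, otherwise a two-sided
#' Mann-Whitney U test (tie-corrected, continuity-corrected normal
#' approximation for larger samples). Cohen's d with pooled SD is reported
#' regardless of the test chosen, and the Bonferroni-corrected p-value
#' (`min(1, p * factor)`) is attached.
#'
#' @param a,b numeric samples (active arm first); n >= 3 each.
#' @param alpha significance level carried in the result.
#' @param bonferroni_factor multiple-testing correction factor.
#' @param shapiro_alpha level of the normality gate.
#' @return Object of class `stat_result`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, bonferroni_factor = 1,
                           shapiro_alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L) stop("need n >= 3 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    return(structure(list(test = "undefined (zero variance)", n = c(length(a), length(b)),
                          statistic = NA_real_, p = 1, p_corrected = 1,
                          correction_factor = bonferroni_factor, d = 0,
                          normal = c(NA, NA), alpha = alpha),
                     class = "stat_result"))
  }
  sw <- function(x) {
    if (length(unique(x)) < 3L) return(FALSE)
    x <- if (length(x) > 5000L) sample(x, 5000L) else x
    stats::shapiro.test(x)$p.value >= shapiro_alpha
  }
  norm_a <- sw(a); norm_b <- sw(b)
  if (norm_a && norm_b) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    test <- "t-test"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    exact <- length(a) <= 20 && length(b) <= 20 && !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    test <- "Mann-Whitney U"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(test = test, n = c(length(a), length(b)),
                 statistic = statistic, p = p,
                 p_corrected = min(1, p * bonferroni_factor),
                 correction_factor = bonferroni_factor,
                 d = cohens_d(a, b), normal = c(norm_a, norm_b),
                 alpha = alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: n = %s, statistic = %.3g, p = %.3g (corrected x%g: %.3g), Cohen's d = %.2f\n",
              x$test, paste(x$n, collapse = "/"), x$statistic, x$p,
              x$correction_factor, x$p_corrected, x$d))
  invisible(x)
}

#' Wilcoxon signed-rank test of paired deltas against zero
#'
#' Two-sided; zero deltas are dropped (the Wilcoxon convention).
#'
#' @param deltas numeric differences.
#' @param bonferroni_factor correction factor.
#' @return `stat_result` with the one-sample effect size
#'   `d = mean / sd` of the deltas.
#' @export
signed_rank_vs_zero <- function(deltas, bonferroni_factor = 1) {
  deltas <- deltas[is.finite(deltas)]
  nz <- deltas[deltas != 0]
  if (length(nz) < 5L) stop("need >= 5 nonzero deltas")
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0,
                                            exact = length(nz) <= 25))
  d <- mean(deltas) / stats::sd(deltas)
  structure(list(test = "Wilcoxon signed-rank", n = length(nz),
                 statistic = unname(wt$statistic), p = wt$p.value,
                 p_corrected = min(1, wt$p.value * bonferroni_factor),
                 correction_factor = bonferroni_factor, d = d,
                 normal = c(NA, NA), alpha = 0.05),
            class = "stat_result")
}

#' Two one-sided tests (TOST) of equivalence
#'
#' Tests whether the mean difference between two groups lies inside
#' (-margin, +margin) with two one-sided pooled-variance t-tests; equivalence
#' is declared iff both one-sided tests reject at `alpha`.
#'
#' @param a,b numeric samples.
#' @param margin equivalence margin in the units of the metric (> 0), e.g.
#'   5 bpm for heart rate, 50 ms for QT, 2 mmHg for blood pressure.
#' @param alpha one-sided level.
#' @return list of class `equivalence_result`: `margin`, `t_lower`,
#'   `p_lower`, `t_upper`, `p_upper`, `equivalent`, `diff`, `df`.
#' @export
tost_equivalence <- function(a, b, margin, alpha = 0.05) {
  if (!is.numeric(margin) || margin <= 0) stop("margin must be > 0")
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  dif <- mean(a) - mean(b)
  t_lower <- (dif + margin) / se   # H0: diff <= -margin
  t_upper <- (dif - margin) / se   # H0: diff >= +margin
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df)
  structure(list(margin = margin, diff = dif, df = df,
                 t_lower = t_lower, p_lower = p_lower,
                 t_upper = t_upper, p_upper = p_upper,
                 equivalent = p_lower < alpha && p_upper < alpha,
                 alpha = alpha),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf("TOST (margin %g): diff = %.3g; lower t = %.2f p = %.3g; upper t = %.2f p = %.3g -> %s\n",
              x$margin, x$diff, x$t_lower, x$p_lower, x$t_upper, x$p_upper,
              if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}

#' Power of the two-sample t-test (noncentral t)
#'
#' Power of the two-sided two-sample t-test at effect size d:
#' df = n1 + n2 - 2, noncentrality d * sqrt(n1 n2 / (n1 + n2)).
#'
#' @param n1,n2 group sizes (>= 2).
#' @param d Cohen's d.
#' @param alpha two-sided level.
#' @return Power in \[0, 1\]; equals `alpha` at d = 0.
#' @export
power_two_sample_t <- function(n1, n2, d, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
}

#' Required sample size per group for a target power
#'
#' Smallest equal-arm n reaching `power` for a two-sided two-sample t-test at
#' effect size d.
#'
#' @param power target power in (0, 1).
#' @param d Cohen's d (nonzero).
#' @param alpha two-sided level.
#' @return Integer n per group.
#' @export
required_n <- function(power, d, alpha = 0.05) {
  stopifnot(power > 0, power < 1, d != 0)
  n <- 2L
  while (power_two_sample_t(n, n, d, alpha) < power) {
    n <- n + 1L
    if (n > 1e6L) stop("required n exceeds 1e6")
  }
  n
}

#' Day-by-treatment interaction regression
#'
#' Ordinary least squares of a change score on day, treatment arm and their
#' interaction (`change ~ day * arm`); the interaction coefficient measures
#' how much faster the metric declines in one arm.
#'
#' @param table data frame with columns `day` (numeric), `arm`
#'   (factor/character; the active level is taken as the non-reference one),
#'   and the response named by `response`.
#' @param response response column name.
#' @return list with `model` (the `lm` fit), `interaction` (estimate),
#'   `interaction_p`, and the full coefficient table.
#' @export
interaction_regression <- function(table, response = "d_rmssd") {
  stopifnot(all(c("day", "arm", response) %in% names(table)))
  table$arm <- arm_factor(table$arm)
  f <- stats::as.formula(paste(response, "~ day * arm"))
  fit <- stats::lm(f, data = table)
  if (any(!is.finite(stats::coef(fit)))) stop("rank-deficient design")
  ct <- summary(fit)$coefficients
  irow <- grep(":", rownames(ct))
  list(model = fit, coefficients = ct,
       interaction = ct[irow, 1L], interaction_p = ct[irow, 4L])
}

#' Linear mixed model of acute response vs clinical outcome
#'
#' Random-intercept model of per-session response (e.g. post-pre heart-rate
#' change) on treatment arm, mRS change and their interaction:
#' `response ~ arm * mrs_change + (1 | subject)`, fit by REML with
#' Satterthwaite p-values and Wald 95% confidence intervals. A singular fit
#' falls back to OLS with a warning.
#'
#' @param data data frame with the four columns below.
#' @param response,arm,mrs,subject column names.
#' @return list of class `mixed_model_result`: `coefficients` (estimate, se,
#'   p, CI bounds per fixed effect), `subject_sd` (random-intercept SD),
#'   `singular`, `model`.
#' @export
fit_mixed_model <- function(data, response = "d_hr", arm = "arm",
                            mrs = "mrs_change", subject = "subject") {
  stopifnot(all(c(response, arm, mrs, subject) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  arm = arm_factor(data[[arm]]),
                  mrs = data[[mrs]], subject = factor(data[[subject]]))
  d <- d[stats::complete.cases(d), ]
  if (min(table(d$subject)) < 2L) {
    warning("some subjects have < 2 sessions; random intercept weakly identified")
  }
  fit <- tryCatch(lmerTest::lmer(y ~ arm * mrs + (1 | subject), data = d,
                                 REML = TRUE),
                  error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular or failed mixed fit (zero subject variance); falling back to OLS")
    ols <- stats::lm(y ~ arm * mrs, data = d)
    ct <- summary(ols)$coefficients
    coefs <- data.frame(estimate = ct[, 1L], se = ct[, 2L], p = ct[, 4L],
                        ci_lo = ct[, 1L] - stats::qnorm(0.975) * ct[, 2L],
                        ci_hi = ct[, 1L] + stats::qnorm(0.975) * ct[, 2L])
    out <- list(coefficients = coefs, subject_sd = 0, singular = TRUE,
                model = ols)
  } else {
    ct <- stats::coef(summary(fit))
    coefs <- data.frame(estimate = ct[, "Estimate"], se = ct[, "Std. Error"],
                        p = ct[, "Pr(>|t|)"],
                        ci_lo = ct[, "Estimate"] - stats::qnorm(0.975) * ct[, "Std. Error"],
                        ci_hi = ct[, "Estimate"] + stats::qnorm(0.975) * ct[, "Std. Error"])
    vc <- as.data.frame(lme4::VarCorr(fit))
    out <- list(coefficients = coefs,
                subject_sd = vc$sdcor[vc$grp == "subject"][1L],
                singular = FALSE, model = fit)
  }
  orig <- rownames(out$coefficients)
  rn <- orig
  rn[orig == "(Intercept)"] <- "intercept"
  rn[grepl("^arm", orig) & grepl(":mrs$", orig)] <- "arm_x_mrs_change"
  rn[grepl("^arm", orig) & !grepl(":", orig)] <- "arm"
  rn[orig == "mrs"] <- "mrs_change"
  rownames(out$coefficients) <- rn
  class(out) <- "mixed_model_result"
  out
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("Linear mixed model (random subject intercept",
      if (x$singular) ", singular -> OLS" else "", ")\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("subject intercept SD: %.3f\n", x$subject_sd))
  invisible(x)
}

#' Age-adjusted treatment effect (ANCOVA)
#'
#' Linear model `change ~ arm + age` giving the arm effect adjusted for age
#' (decade midpoints from the metadata) and the age slope. A constant age
#' column is dropped with a warning.
#'
#' @param data data frame with the columns below.
#' @param response,arm,age column names.
#' @return list with `arm_effect`, `arm_p`, `age_coef`, `age_p`, `model`.
#' @export
ancova_age <- function(data, response = "d_rmssd", arm = "arm", age = "age") {
  stopifnot(all(c(response, arm, age) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  arm = arm_factor(data[[arm]]),
                  age = data[[age]])
  d <- d[stats::complete.cases(d), ]
  if (stats::var(d$age) == 0) {
    warning("age is constant; dropping the covariate")
    fit <- stats::lm(y ~ arm, data = d)
    ct <- summary(fit)$coefficients
    return(list(arm_effect = ct[2L, 1L], arm_p = ct[2L, 4L],
                age_coef = NA_real_, age_p = NA_real_, model = fit))
  }
  fit <- stats::lm(y ~ arm + age, data = d)
  ct <- summary(fit)$coefficients
  list(arm_effect = ct[2L, 1L], arm_p = ct[2L, 4L],
       age_coef = ct["age", 1L], age_p = ct["age", 4L], model = fit)
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors (n >= 3, non-degenerate).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
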