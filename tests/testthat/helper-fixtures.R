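# Shared fixture builders: everything is generated in code at test time.

# short clean synthetic ECG with ground truth, cached per test file run
make_clean_ecg <- function(duration_s = 120, mean_rr = 800, seed = 42,
                           fs = 500, qtc = 400, ...) {
  p <- rr_gen_params(mean_rr = mean_rr, sdnn_target = 40, rmssd_target = 25,
                     seed = seed)
  g <- generate_rr_series(p, max(duration_s, 120))
  if (duration_s < 120) {
    keep <- g$rr$time <= duration_s
    g$rr <- g$rr[keep, , drop = FALSE]
    class(g$rr) <- c("rr_series", "data.frame")
  }
  syn <- synthesize_ecg(g$rr, qt_fun = function(rr_s) qtc * sqrt(rr_s),
                        fs = fs, ...)
  syn$rr_truth <- g$truth
  syn
}

# match detected peak indices to truth within tol_s; returns sensitivity,
# precision, mean absolute error (ms)
match_peaks <- function(detected, truth, fs, tol_s = 0.05) {
  if (length(detected) == 0L) {
    return(list(sensitivity = 0, precision = NA_real_, mae_ms = NA_real_))
  }
  err <- vapply(detected, function(i) min(abs(truth - i)), numeric(1L)) / fs
  hit <- err <= tol_s
  used <- vapply(truth, function(i) min(abs(detected - i)), numeric(1L)) / fs
  list(sensitivity = mean(used <= tol_s),
       precision = mean(hit),
       mae_ms = mean(err[hit]) * 1000)
}

# small two-factor data set with known orthogonal loadings
make_factor_data <- function(n = 500, seed = 99, noise = NULL) {
  set.seed(seed)
  L <- matrix(0, 7, 2,
              dimnames = list(c("rmssd", "sdnn", "pnni50", "total_power",
                                "nhf_power", "cvi", "csi"), NULL))
  L[c("rmssd", "sdnn", "pnni50", "total_power"), 1] <- c(0.85, 0.8, 0.75, 0.7)
  L[c("nhf_power", "cvi"), 2] <- c(0.8, 0.75)
  L["csi", 2] <- -0.85
  L["rmssd", 2] <- 0.3
  f <- matrix(rnorm(n * 2), n, 2)
  if (is.null(noise)) noise <- sqrt(pmax(1 - rowSums(L^2), 0.05))
  x <- f %*% t(L) + matrix(rnorm(n * 7), n, 7) %*% diag(noise)
  colnames(x) <- rownames(L)
  list(x = x, loadings = L)
}
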