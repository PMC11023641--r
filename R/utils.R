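# Internal numeric helpers shared across modules.

# Centered moving average via cumulative sums; pads edges by shrinking the
# window (no phase shift). width in samples.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(round(width)))
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# numpy-style central-difference gradient
num_gradient <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[1L] <- x[2L] - x[1L]
  g[n] <- x[n] - x[n - 1L]
  if (n > 2L) g[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  g
}

# Runs of TRUE in a logical vector -> matrix with columns start, end (inclusive)
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Welch power spectral density estimate with Hann window.
# x: evenly sampled series, fs in Hz, seg_s segment length in seconds,
# overlap fraction in [0,1). Returns list(freq, psd) with psd in x-units^2/Hz,
# one-sided, mean removed per segment. Density normalization such that
# sum(psd) * df == variance for a long stationary series.
welch_psd <- function(x, fs, seg_s = 120, overlap = 0.5) {
  n <- length(x)
  nper <- min(n, max(16L, as.integer(round(seg_s * fs))))
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / (nper + 1)))  # Hann
  u <- sum(w^2)
  nf <- nper %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    ft <- stats::fft(seg)
    p <- Mod(ft[1:(nf + 1L)])^2 / (fs * u)
    # one-sided: double the interior bins
    if (nf >= 2L) p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  psd <- acc / length(starts)
  freq <- (0:nf) * fs / nper
  list(freq = freq, psd = psd)
}

# Trapezoidal band power from a PSD between f1 and f2 (Hz)
band_power <- function(freq, psd, f1, f2) {
  sel <- freq >= f1 & freq <= f2
  if (sum(sel) < 2L) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
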