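# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Median frequency by brute-force cumulative scan over a raw periodogram.
pgram_median <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE, detrend = FALSE)
  cs <- cumsum(sp$spec)
  sp$freq[which(cs >= cs[length(cs)] / 2)[1]]
}

# Brute-force median-frequency scan with the same interpolation convention
# as the implementation, written independently as a plain loop.
brute_force_imdf <- function(p, f_axis) {
  total <- sum(p)
  if (total <= 0) return(NA_real_)
  half <- total / 2
  acc <- 0
  for (k in seq_along(p)) {
    if (acc + p[k] >= half) {
      f_lo <- if (k > 1) f_axis[k - 1] else f_axis[1] - (f_axis[2] - f_axis[1])
      return(f_lo + (half - acc) / p[k] * (f_axis[k] - f_lo))
    }
    acc <- acc + p[k]
  }
  f_axis[length(p)]
}

# Closed-form simple linear regression.
ols_oracle <- function(t, y) {
  tb <- mean(t); yb <- mean(y)
  slope <- sum((t - tb) * (y - yb)) / sum((t - tb)^2)
  c(intercept = yb - slope * tb, slope = slope)
}

# Exact sign-flip permutation test for a paired median difference.
perm_p_paired <- function(d) {
  n <- length(d)
  stopifnot(n <= 14)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  m <- signs * matrix(abs(d), nrow(signs), n, byrow = TRUE)
  stats <- abs(apply(m, 1, median))
  mean(stats >= abs(median(d)) - 1e-12)
}

# Monte-Carlo label-permutation test for an unpaired median difference.
perm_p_unpaired <- function(a, b, R = 4000, seed = 1) {
  set.seed(seed)
  pool <- c(a, b)
  na <- length(a)
  obs <- abs(median(a) - median(b))
  stats <- replicate(R, {
    idx <- sample(length(pool), na)
    abs(median(pool[idx]) - median(pool[-idx]))
  })
  mean(stats >= obs - 1e-12)
}

# Magnitude response of a Butterworth cascade designed independently via
# signal::freqz, used as the filter-gain oracle.
butter_gain <- function(f, rate, n = 4, cutoff, type) {
  bf <- signal::butter(n, cutoff / (rate / 2), type = type)
  h <- signal::freqz(bf, Fs = rate, n = 4096)
  approx(h$f, abs(h$h), xout = f)$y
}
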