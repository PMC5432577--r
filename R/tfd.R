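# Cohen-class time-frequency analysis of SEMG segments.
#
# The distribution is the Choi-Williams (exponential-kernel) member of the
# Cohen class, computed on the analytic signal: the ambiguity-domain kernel
# exp(-theta^2 tau^2 / sigma) becomes, in the time-lag domain, a
# lag-dependent Gaussian smoothing of the instantaneous autocorrelation
# z(t + tau/2) z*(t - tau/2), followed by an FFT over lag. Negative values
# (an unavoidable feature of bilinear distributions) are clipped to zero
# before the instantaneous median frequency is read off; the clipped energy
# fraction is recorded for diagnostics.

#' Analytic signal via the frequency domain
#'
#' @param x real numeric vector.
#' @return complex vector z = x + i H(x).
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Choi-Williams time-frequency distribution of an SEMG segment
#'
#' @param x real signal segment (length >= 256 samples).
#' @param rate sampling rate in Hz.
#' @param sigma Choi-Williams kernel parameter (> 0); smaller values smooth
#'   more aggressively and suppress cross-terms harder.
#' @param n_times number of analysis instants, spread uniformly over the
#'   segment interior (a margin of one eighth of the segment is left at
#'   each edge to limit boundary leakage).
#' @param max_lag autocorrelation lag extent in samples; with the analytic
#'   signal the effective frequency resolution is `rate / (2 max_lag)` Hz.
#' @param nfft FFT length over lag; default next power of two >= twice the
#'   segment length, giving a frequency grid step of `rate / (2 nfft)` Hz
#'   up to Nyquist.
#' @param lag_window `"hanning"` (default) tapers the lag direction to tame
#'   spectral sidelobes; `"rectangular"` disables the taper.
#' @param time_smooth_s standard deviation (seconds) of the fixed Gaussian
#'   time-smoothing window convolved with the lag-dependent Choi-Williams
#'   spread, as in standard discrete Cohen-class implementations. It
#'   suppresses the broadband per-instant noise the CW kernel leaves at
#'   small lags (which negativity clipping would otherwise rectify into an
#'   upward median-frequency bias) at the cost of time resolution of the
#'   same order.
#' @param p_max cap on the time-smoothing half-width, samples.
#' @param provenance optional list (channel, cycle, phase) carried on the
#'   result for bookkeeping.
#' @return object of class `semg_tfd`: list with `P` (nonneg. power,
#'   frequency x time), `t_s`, `f_hz`, `kernel`, `clip_fraction` (fraction
#'   of absolute energy removed by negativity clipping) and `provenance`.
#' @export
choi_williams <- function(x, rate, sigma = 1, n_times = 128,
                          max_lag = NULL, nfft = NULL,
                          lag_window = c("hanning", "rectangular"),
                          time_smooth_s = 0.04, p_max = 150,
                          provenance = list()) {
  n <- length(x)
  if (n < 256) stop("segment too short for time-frequency analysis (need >= 256 samples)")
  if (sigma <= 0) stop("sigma must be positive")
  lag_window <- match.arg(lag_window)
  if (is.null(max_lag)) max_lag <- min(512L, floor((n - 1) / 2))
  if (is.null(nfft)) nfft <- next_pow2(2 * n)
  if (nfft < 2 * max_lag) stop("nfft must be at least twice max_lag")
  # reflect the segment at both ends so every analysis instant has full
  # kernel support (zero padding would leak energy across the spectrum at
  # instants near the edges)
  pad <- min(n - 1, max_lag + p_max)
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  z <- analytic_signal(xp)
  # keep analysis instants clear of the reflection joins by at least the
  # time-smoothing extent
  margin <- max(ceiling(n / 16),
                min(ceiling(2.5 * time_smooth_s * rate), p_max))
  margin <- min(margin, floor((n - 1) / 2))
  t_idx <- unique(round(seq(margin + 1, n - margin, length.out = n_times)))
  K <- cw_kernel(z, as.integer(t_idx - 1L + pad), as.integer(max_lag),
                 sigma, time_smooth_s * rate, as.integer(p_max))
  m <- 0:(max_lag - 1)
  wl <- switch(lag_window,
               hanning = 0.5 * (1 + cos(pi * m / max_lag)),
               rectangular = rep(1, max_lag))
  K <- K * wl
  # Hermitian extension over lag: K(-m) = conj(K(m)) -> real spectrum
  ext <- matrix(0 + 0i, nfft, ncol(K))
  ext[1:max_lag, ] <- K
  if (max_lag > 1)
    ext[nfft - (1:(max_lag - 1)) + 1, ] <- Conj(K[2:max_lag, , drop = FALSE])
  P <- Re(mvfft(ext)) / nfft
  neg <- P < 0
  clip_fraction <- if (any(neg)) sum(-P[neg]) / sum(abs(P)) else 0
  P[neg] <- 0
  structure(list(
    P = P,
    t_s = (t_idx - 1) / rate,
    f_hz = (0:(nfft - 1)) * rate / (2 * nfft),
    kernel = list(name = "choi-williams", sigma = sigma,
                  lag_window = lag_window, max_lag = max_lag, nfft = nfft),
    clip_fraction = clip_fraction,
    provenance = provenance), class = "semg_tfd")
}

#' Median frequency of one instantaneous spectrum
#'
#' The smallest grid frequency at which the cumulative power reaches half
#' the column total, refined by linear interpolation between the bracketing
#' bins (the bin below the first crossing, or a virtual zero-power bin one
#' grid step below the axis start).
#'
#' @param p nonnegative power column.
#' @param f_axis strictly increasing frequency axis, same length.
#' @return median frequency in Hz, or `NA` if the column has no power.
#' @export
imdf_from_tfd <- function(p, f_axis) {
  total <- sum(p)
  if (!is.finite(total) || total <= 0) return(NA_real_)
  cs <- cumsum(p)
  half <- total / 2
  k <- which(cs >= half)[1]
  if (k > 1) {
    c_prev <- cs[k - 1]
    f_prev <- f_axis[k - 1]
  } else {
    c_prev <- 0
    f_prev <- f_axis[1] - (f_axis[2] - f_axis[1])
  }
  f_prev + (half - c_prev) / (cs[k] - c_prev) * (f_axis[k] - f_prev)
}

#' Instantaneous median frequency track of a segment
#'
#' Computes the Choi-Williams distribution and reads the instantaneous
#' median frequency at each analysis instant. The segment-level summary is
#' the median of the per-instant track (robust to residual edge artifacts);
#' it is `NA` when more than half the instants are undefined.
#'
#' @param x real SEMG segment (post band-pass).
#' @param rate sampling rate in Hz.
#' @param ... passed to [choi_williams()].
#' @return object of class `imdf_track`: list with `t_s`, `imdf_hz`,
#'   `summary_hz`, `clip_fraction`.
#' @export
segment_imdf <- function(x, rate, ...) {
  tfd <- choi_williams(x, rate, ...)
  imdf <- apply(tfd$P, 2, imdf_from_tfd, f_axis = tfd$f_hz)
  miss <- mean(is.na(imdf))
  summary_hz <- if (miss > 0.5) NA_real_ else median(imdf, na.rm = TRUE)
  structure(list(t_s = tfd$t_s, imdf_hz = imdf, summary_hz = summary_hz,
                 clip_fraction = tfd$clip_fraction),
            class = "imdf_track")
}
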