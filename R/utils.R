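# Shared numeric helpers: windows, moving averages, FFT filtering, analytic
# signal. All filtering is done in the frequency domain (zero phase) because
# the pipeline is strictly offline.

#' Centered moving average
#'
#' @param x numeric vector (may contain NA).
#' @param width window width in samples; the window at index i is
#'   `[i - floor((width-1)/2), i + ceiling((width-1)/2)]`, truncated at the
#'   edges.
#' @param na.rm drop NAs within each window.
#' @return numeric vector of the same length.
#' @export
moving_average <- function(x, width, na.rm = TRUE) {
  n <- length(x)
  if (width <= 1) return(x)
  lo <- floor((width - 1) / 2)
  hi <- width - 1 - lo
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - lo):min(n, i + hi)]
    if (na.rm) w <- w[!is.na(w)]
    if (!length(w)) NA_real_ else mean(w)
  }, numeric(1))
}

# Trailing mean over (i - width, i] used by the baseline-shift analysis.
trailing_mean <- function(x, width) {
  n <- length(x)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  cnt <- cumsum(!is.na(x))
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(0, i - width)
    m <- cnt[i] - if (j > 0) cnt[j] else 0
    if (m > 0) out[i] <- (cs[i] - if (j > 0) cs[j] else 0) / m
  }
  out
}

# Periodic Hann taper (standard for short-time spectra).
hann_taper <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

# Zero-phase band-pass via FFT masking with raised-cosine transition skirts.
# `trans` is the transition half-width in Hz.
fft_bandpass <- function(x, fs, low, high, trans = 0.02) {
  n <- length(x)
  mu <- mean(x)
  X <- stats::fft(x - mu)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  gain <- rep(0, n)
  gain[f >= low & f <= high] <- 1
  ramp_lo <- f > low - trans & f < low
  gain[ramp_lo] <- 0.5 * (1 + cos(pi * (low - f[ramp_lo]) / trans))
  ramp_hi <- f > high & f < high + trans
  gain[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - high) / trans))
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

# Analytic signal (FFT implementation of the Hilbert transform).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase notch: removes [f0 - bw, f0 + bw].
fft_notch <- function(x, fs, f0, bw = 1) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  X[f >= f0 - bw & f <= f0 + bw] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Zero-phase high-pass with raised-cosine transition below `cut`.
fft_highpass <- function(x, fs, cut, trans = 0.5) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  gain <- rep(1, n)
  gain[f <= cut - trans] <- 0
  ramp <- f > cut - trans & f < cut
  gain[ramp] <- 0.5 * (1 - cos(pi * (f[ramp] - (cut - trans)) / trans))
  gain[1] <- 0
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

# Deterministic per-task seed streams derived from one master seed. Keeps
# every derived seed a valid 32-bit integer.
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + as.numeric(k) * 16807) %%
               2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
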