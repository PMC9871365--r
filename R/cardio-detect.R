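#' Detect ECG R peaks
#'
#' Polarity-robust adaptive-threshold detector: the trace is centered on its
#' median, flipped if the dominant deflection is negative, lightly smoothed,
#' and local maxima above an adaptive threshold are kept subject to a 250-ms
#' refractory constraint (larger peak wins). Peak times are refined on the
#' raw (unsmoothed) trace.
#'
#' @param ecg numeric ECG trace (mV).
#' @param fs sampling rate, Hz (>= 100).
#' @param min_duration minimum trace duration accepted, seconds.
#' @param refractory minimum peak separation, seconds.
#' @param threshold_frac adaptive threshold as a fraction of the 99.9th
#'   amplitude percentile.
#' @return numeric vector of strictly increasing R times (seconds). Empty
#'   with attribute `flagged = TRUE` when no peak clears the threshold
#'   (e.g. a flat line).
#' @export
detect_r_peaks <- function(ecg, fs, min_duration = 30, refractory = 0.25,
                           threshold_frac = 0.45) {
  if (fs < 100) stop("fs must be >= 100 Hz")
  if (length(ecg) < min_duration * fs)
    stop("ECG shorter than ", min_duration, " s")
  x <- ecg - stats::median(ecg)
  hi <- stats::quantile(x, 0.999, names = FALSE)
  lo <- stats::quantile(x, 0.001, names = FALSE)
  if (abs(lo) > abs(hi)) { x <- -x; hi <- abs(lo) }
  if (!is.finite(hi) || hi < 1e-9 || stats::sd(x) < 1e-12) {
    out <- numeric(0); attr(out, "flagged") <- TRUE
    return(out)
  }
  xs <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  xs[is.na(xs)] <- 0
  thr <- threshold_frac * hi
  n <- length(xs)
  cand <- which(xs > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[xs[cand] >= xs[cand - 1] & xs[cand] >= xs[cand + 1]]
  if (!length(cand)) {
    out <- numeric(0); attr(out, "flagged") <- TRUE
    return(out)
  }
  # refractory pruning, larger peak wins
  keep <- integer(0)
  gap <- refractory * fs
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < gap) {
      if (xs[i] > xs[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  # refine on raw trace within +/- 10 ms
  half <- max(1, round(0.01 * fs))
  refined <- vapply(keep, function(i) {
    w <- max(1, i - half):min(n, i + half)
    w[which.max(x[w])]
  }, integer(1))
  sort(unique(refined - 1)) / fs
}

# Wide-stencil second difference used for B-point (slope-change onset)
# detection; h is the stencil half-width in samples.
second_diff <- function(x, h = 3) {
  n <- length(x)
  d <- rep(NA_real_, n)
  idx <- (h + 1):(n - h)
  d[idx] <- x[idx + h] - 2 * x[idx] + x[idx - h]
  d
}

#' Locate Q, B and X fiducials for each beat
#'
#' Per beat: Q is the ECG minimum in a window before R; B is the point of
#' maximal (wide-stencil) second derivative of the lightly smoothed dZ/dt
#' between R and the dZ/dt ejection peak -- the slope-change onset marking
#' aortic valve opening; X is the global dZ/dt minimum (incisura) in a window
#' after the peak. Beats violating Q < B < X, or whose search windows fall
#' off the trace, are marked invalid.
#'
#' @param ecg,dzdt aligned traces at rate `fs`.
#' @param r_times R times from [detect_r_peaks()], seconds.
#' @param fs sampling rate, Hz.
#' @param q_window Q search window before R, seconds `c(earliest, latest)`.
#' @param peak_window dZ/dt peak search window after R, seconds.
#' @param x_window X search window after the dZ/dt peak, seconds.
#' @param smooth_w boxcar half-width (samples) applied to dZ/dt before the
#'   second-derivative search; applied twice (triangular kernel).
#' @return a `beat_table` data.frame: `r_time, q_time, b_time, x_time, rr,
#'   hr, pep_ms, lvet_ms, valid`.
#' @export
locate_fiducials <- function(ecg, dzdt, r_times, fs,
                             q_window = c(0.06, 0.015), peak_window = 0.35,
                             x_window = 0.5, smooth_w = 2) {
  n <- length(dzdt)
  dz_s <- dzdt
  if (smooth_w > 0) {
    k <- rep(1 / (2 * smooth_w + 1), 2 * smooth_w + 1)
    dz_s <- stats::filter(stats::filter(dzdt, k, sides = 2), k, sides = 2)
    dz_s[is.na(dz_s)] <- dzdt[is.na(dz_s)]
  }
  d2 <- second_diff(as.numeric(dz_s), h = 3)
  nb <- length(r_times)
  q_time <- b_time <- x_time <- rep(NA_real_, nb)
  valid <- rep(FALSE, nb)
  for (k in seq_len(nb)) {
    r <- r_times[k]
    ri <- round(r * fs) + 1
    qi <- (ri - round(q_window[1] * fs)):(ri - round(q_window[2] * fs))
    pi_ <- (ri + 1):(ri + round(peak_window * fs))
    if (qi[1] < 1 || pi_[length(pi_)] > n) next
    q_time[k] <- (qi[which.min(ecg[qi])] - 1) / fs
    pk <- pi_[which.max(dz_s[pi_])]
    bi <- (ri + 1):(pk - 1)
    if (length(bi) < 3) next
    bscore <- d2[bi]
    if (all(is.na(bscore))) next
    b_time[k] <- (bi[which.max(bscore)] - 1) / fs
    xi <- (pk + 1):min(n, pk + round(x_window * fs))
    if (xi[length(xi)] > n || length(xi) < 3) next
    # restrict to before the next beat's R
    if (k < nb) xi <- xi[xi <= round(r_times[k + 1] * fs)]
    if (length(xi) < 3) next
    x_time[k] <- (xi[which.min(dzdt[xi])] - 1) / fs
    valid[k] <- is.finite(q_time[k]) && is.finite(b_time[k]) &&
      is.finite(x_time[k]) && q_time[k] < b_time[k] && b_time[k] < x_time[k]
  }
  rr <- c(NA, diff(r_times))
  out <- data.frame(r_time = r_times, q_time = q_time, b_time = b_time,
                    x_time = x_time, rr = rr, hr = 60 / rr,
                    pep_ms = (b_time - q_time) * 1000,
                    lvet_ms = (x_time - b_time) * 1000,
                    valid = valid)
  class(out) <- c("beat_table", "data.frame")
  out
}
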