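#' Lomb-Scargle periodogram for unevenly sampled series
#'
#' Classical least-squares spectral estimate with the per-frequency time
#' offset tau; suitable for RR-interval series sampled at beat times. The
#' normalization is such that a sinusoid of amplitude A contributes power
#' proportional to A^2 (N A^2 / 4 at its frequency).
#'
#' @param t sample times, seconds.
#' @param y sample values (centered internally).
#' @param freqs frequencies to evaluate, Hz.
#' @return numeric power at each frequency.
#' @export
lomb_scargle <- function(t, y, freqs) {
  y <- y - mean(y)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Continuous high-frequency HRV with a trailing window
#'
#' For each integer second t >= `window_s`, the RR deviations (in ms, at
#' interval midpoints) inside the trailing window `(t - window_s, t]` are
#' mean-centered and submitted to a least-squares (Lomb-Scargle) spectral
#' estimate; power is integrated over the HF band and log-transformed with a
#' small floor. Earlier timepoints, and windows with too few beats, are
#' masked -- so with the default 32-s window exactly the first 32 s of the
#' 40-s baseline (80%) carry no estimate.
#'
#' @param r_times R-point times, seconds (or a `beat_table`).
#' @param protocol a `protocol_definition`.
#' @param window_s trailing training window, seconds (default 32).
#' @param band HF band, Hz (default 0.15-0.40).
#' @param min_beats minimum RR samples per window (default 8).
#' @param epsilon log floor, added to band power before the log.
#' @return a `continuous_measure` (`HF`, log ms^2) with attribute `hf_raw`
#'   (band-integrated power, ms^2).
#' @export
hf_timecourse <- function(r_times, protocol, window_s = 32,
                          band = c(0.15, 0.40), min_beats = 8,
                          epsilon = 1e-6) {
  if (inherits(r_times, "data.frame")) r_times <- r_times$r_time
  r_times <- sort(r_times[is.finite(r_times)])
  rr <- diff(r_times)
  ok <- rr > 0.25 & rr < 3
  mid <- (r_times[-1] + r_times[-length(r_times)]) / 2
  mid <- mid[ok]; rr_ms <- rr[ok] * 1000
  grid <- time_grid(protocol)
  df <- 1 / window_s
  freqs <- seq(band[1], band[2], by = df)
  hf_raw <- rep(NA_real_, length(grid))
  for (g in seq_along(grid)) {
    t <- grid[g]
    if (t < window_s) next
    sel <- which(mid > t - window_s & mid <= t)
    if (length(sel) < min_beats) next
    p <- lomb_scargle(mid[sel], rr_ms[sel], freqs)
    hf_raw[g] <- sum(p) * df
  }
  out <- continuous_measure(log(hf_raw + epsilon), is.finite(hf_raw),
                            "HF", "log ms^2")
  attr(out, "hf_raw") <- hf_raw
  out
}

#' Respiration-correct an HF time course
#'
#' Applies the same per-subject linear residualization as
#' [respiration_correct()] to the log HF series, using the respiratory state
#' interpolated from beat times onto the 1-Hz grid.
#'
#' @param hf a `continuous_measure` from [hf_timecourse()].
#' @param state data.frame from [estimate_respiration()]`$state`
#'   (`r_time`, `state`), or a numeric state vector already on the grid.
#' @param protocol a `protocol_definition`.
#' @return corrected `continuous_measure`.
#' @export
hf_correct <- function(hf, state, protocol = make_default_protocol()) {
  if (is.data.frame(state)) {
    grid <- time_grid(protocol)
    state <- stats::approx(state$r_time, state$state, xout = grid,
                           rule = 1, ties = mean)$y
  }
  respiration_correct(hf, state)
}
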