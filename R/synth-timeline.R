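#' Simulate a beat timeline with known per-beat truth
#'
#' Beat times form an inhomogeneous point sequence whose instantaneous rate is
#' `HR(t)/60`, with respiratory sinus arrhythmia: successive RR intervals are
#' modulated sinusoidally at the respiration frequency with a depth set by the
#' HF profile. If the HF profile has value `hf` (natural log of band power in
#' ms^2), the RR modulation amplitude is `sqrt(2 * exp(hf))` ms, so a
#' band-integrated spectral estimate of the resulting RR series recovers the
#' profile up to estimator bias.
#'
#' @param profiles list of 1-Hz truth profiles on the protocol grid:
#'   `hr` (bpm, required), and optionally `pep`, `lvet`, `sv` (ms/ms/mL) and
#'   `hf` (log ms^2). Missing optional profiles fall back to constants.
#' @param protocol a `protocol_definition`.
#' @param resp_freq respiration frequency, Hz (default 0.25, inside the HF
#'   band so HF manipulations are visible to the estimator).
#' @param rr_jitter_sd additional white RR jitter SD in seconds (default 0).
#' @param seed integer seed; identical seeds give identical timelines.
#' @return data.frame of class `beat_truth`: `r_time` (s), `rr` (s, interval
#'   ending at the beat; NA for the first), `pep_ms`, `lvet_ms`, `sv_ml`.
#' @export
simulate_beat_timeline <- function(profiles, protocol, resp_freq = 0.25,
                                   rr_jitter_sd = 0, seed = 1) {
  hr <- profiles$hr
  if (is.null(hr)) stop("profiles$hr is required")
  if (any(hr <= 0)) stop("HR profile must be positive")
  total <- protocol$total_duration
  grid <- time_grid(protocol)
  at <- function(p, t, default) {
    if (is.null(p)) return(rep(default, length(t)))
    stats::approx(grid, p, xout = pmin(pmax(t, 0), max(grid)), rule = 2)$y
  }
  set.seed(seed)
  t0 <- stats::runif(1, 0, 0.5)
  times <- numeric(0)
  t <- t0
  # generous preallocation of jitter draws keeps the stream length fixed
  max_beats <- ceiling(total * max(hr) / 60) + 10
  jit <- if (rr_jitter_sd > 0) stats::rnorm(max_beats, 0, rr_jitter_sd)
         else numeric(max_beats)
  k <- 0
  while (t < total && k < max_beats) {
    k <- k + 1
    times[k] <- t
    rr_base <- 60 / at(hr, t, 60)
    hf_t <- at(profiles$hf, t, -Inf)
    amp_s <- if (is.finite(hf_t)) sqrt(2 * exp(hf_t)) / 1000 else 0
    rr <- rr_base + amp_s * sin(2 * pi * resp_freq * t) + jit[k]
    t <- t + max(rr, 0.3)
  }
  times <- times[seq_len(k)]
  out <- data.frame(
    r_time = times,
    rr = c(NA, diff(times)),
    pep_ms = at(profiles$pep, times, 83),
    lvet_ms = at(profiles$lvet, times, 288),
    sv_ml = at(profiles$sv, times, 37.6)
  )
  class(out) <- c("beat_truth", "data.frame")
  attr(out, "resp_freq") <- resp_freq
  out
}
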