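#' Calibration constants for the impedance stroke-volume formula
#'
#' The Kubicek estimate is `SV = rho * (L / Z0)^2 * LVET * max(dZ/dt)` with
#' blood resistivity `rho` (Ohm cm) and electrode distance `L` (cm). The
#' generator inverts the same formula when drawing dZ/dt amplitudes, so
#' extraction with matching constants recovers the true stroke volume.
#'
#' @param rho blood resistivity, Ohm cm.
#' @param L electrode distance, cm.
#' @return list of class `calibration_constants`.
#' @export
default_calibration <- function(rho = 135, L = 30) {
  stopifnot(rho > 0, L > 0)
  structure(list(rho = rho, L = L), class = "calibration_constants")
}

#' Default EEG oscillator specification
#'
#' Four band-limited oscillators ride on 1/f background noise. Effect deltas
#' (amplitude changes under treatment) are confined to designated channel
#' groups: slow bands (delta/theta) increase frontally during immersion, alpha
#' shows a broadly distributed evoked increase that habituates, beta a small
#' central one. Amplitudes are in microvolts.
#'
#' @param null zero all deltas and set h = 1.
#' @param channels montage channel names used by the renderer.
#' @return list keyed by band, each with `f` (center Hz), `base`, `ant`,
#'   `evoked`, `h`, `channels`; plus attribute `noise_scale`.
#' @export
default_eeg_spec <- function(null = FALSE,
                             channels = default_eeg_channels()) {
  z <- function(x) if (null) 0 else x
  h <- function(x) if (null) 1 else x
  frontal <- intersect(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"), channels)
  central <- intersect(c("C3", "Cz", "C4"), channels)
  spec <- list(
    delta = list(f = 2,   base = 4, ant = z(0),   evoked = z(2),
                 h = h(0.9),  channels = frontal),
    theta = list(f = 5.5, base = 3, ant = z(0),   evoked = z(1.5),
                 h = h(0.9),  channels = frontal),
    alpha = list(f = 10,  base = 5, ant = z(0.8), evoked = z(1.5),
                 h = h(0.8),  channels = channels),
    beta  = list(f = 22,  base = 2, ant = z(0.4), evoked = z(0.5),
                 h = h(0.85), channels = central)
  )
  attr(spec, "noise_scale") <- 1
  spec
}

#' Default 16-channel 10-20 style montage labels
#' @return character vector of channel names.
#' @export
default_eeg_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "C3", "Cz", "C4",
    "P3", "Pz", "P4", "O1", "Oz", "O2")
}

#' Default renderer noise levels
#'
#' Noise is white and additive; levels correspond to cleaned laboratory
#' recordings (ECG in mV with unit R amplitude; dZ/dt in Ohm/s against a
#' ~0.7 Ohm/s ejection peak).
#' @return named list of noise SDs.
#' @export
default_render_noise <- function() {
  list(ecg = 0.01, dzdt = 0.02, z0 = 0.005, bp = 0.5, pupil = 0.02)
}

# Add Gaussian bumps (amplitude `amp`, width `sd` seconds) at `times` into a
# sampled trace; truncated at 4 sd.
add_bumps <- function(x, fs, times, amp, sd) {
  n <- length(x)
  half <- ceiling(4 * sd * fs)
  for (i in seq_along(times)) {
    c0 <- round(times[i] * fs) + 1
    lo <- max(1, c0 - half); hi <- min(n, c0 + half)
    if (lo > hi) next
    idx <- lo:hi
    ts <- (idx - 1) / fs
    x[idx] <- x[idx] + amp[min(i, length(amp))] *
      exp(-(ts - times[i])^2 / (2 * sd^2))
  }
  x
}

# dZ/dt ejection waveform for one beat: abrupt slope-change onset at B (the
# detectable B point), peak of height A at B + 0.4 * (X - B), descent to zero,
# and a sharp incisura notch whose minimum falls exactly at X.
render_dzdt_beat <- function(x, fs, b, xp, A, notch_hw = 0.03,
                             notch_depth = 0.3) {
  n <- length(x)
  tp <- b + 0.4 * (xp - b)
  idx <- max(1, floor(b * fs) + 1):min(n, ceiling((xp + notch_hw) * fs) + 1)
  ts <- (idx - 1) / fs
  v <- numeric(length(ts))
  rise <- ts >= b & ts < tp
  v[rise] <- A * sin(pi / 2 * (ts[rise] - b) / (tp - b))
  fall_end <- xp - notch_hw
  fall <- ts >= tp & ts < fall_end
  v[fall] <- A * cos(pi / 2 * (ts[fall] - tp) / (fall_end - tp))
  ntc <- ts >= fall_end & ts <= xp + notch_hw
  v[ntc] <- v[ntc] - notch_depth * A * 0.5 *
    (1 - cos(2 * pi * (ts[ntc] - fall_end) / (2 * notch_hw)))
  x[idx] <- x[idx] + v
  x
}

#' Render one trial's raw signal set from a beat timeline
#'
#' Produces geometric stand-in waveforms with controllable landmarks: ECG with
#' Q/R/T waves, dZ/dt with a B-point slope-change onset at `q_time + PEP` and
#' an incisura minimum at `b_time + LVET`, amplitude scaled so the Kubicek
#' formula recovers the true stroke volume; baseline impedance carrying a
#' respiration sinusoid; continuous pressure pulses consistent with the MAP
#' profile; binocular pupil traces with blink dropouts; multichannel EEG as
#' 1/f noise plus band-limited oscillators.
#'
#' @param beats a `beat_truth` data.frame from [simulate_beat_timeline()].
#' @param profiles list of 1-Hz truth profiles (`map`, `pupil` used here).
#' @param protocol a `protocol_definition`.
#' @param condition,trial condition label and trial index (drive the EEG
#'   oscillator amplitudes).
#' @param fs,fs_pupil,fs_eeg sampling rates (Hz). Defaults are desk-scale
#'   analysis rates, not acquisition rates.
#' @param cal `calibration_constants` used to invert the Kubicek formula.
#' @param eeg_spec oscillator spec from [default_eeg_spec()].
#' @param noise named list of white-noise SDs (see [default_render_noise()]);
#'   set elements to 0 for noiseless rendering.
#' @param q_offset Q-to-R interval, seconds. The Q wave is rendered at
#'   `r_time - q_offset` and the B point at `q_time + PEP`, so PEP is the
#'   Q-to-B interval as defined for impedance cardiography.
#' @param resp_freq,resp_amp respiration sinusoid frequency (Hz) and
#'   amplitude (Ohm) on the baseline impedance.
#' @param z0_base baseline thoracic impedance, Ohm.
#' @param pulse_pressure rendered pulse pressure, mmHg.
#' @param blink_rate blink dropouts per minute in the pupil traces.
#' @param seed integer seed.
#' @return list of class `trial_signals` with channels `ecg`, `dzdt`, `z0`,
#'   `bp` (each `list(data, fs)`), `pupil` (`list(t, left, right, fs)`), `eeg`
#'   (`list(data, fs, channels)`), and a `truth` element holding the beat
#'   table with fiducial times.
#' @export
render_trial <- function(beats, profiles, protocol,
                         condition = "treatment", trial = 1,
                         fs = 250, fs_pupil = 500, fs_eeg = 250,
                         cal = default_calibration(),
                         eeg_spec = default_eeg_spec(),
                         noise = default_render_noise(),
                         q_offset = 0.04, resp_freq = 0.25, resp_amp = 0.2,
                         z0_base = 25, pulse_pressure = 40,
                         blink_rate = 2, seed = 1) {
  total <- protocol$total_duration
  grid <- time_grid(protocol)
  f_max <- max(vapply(eeg_spec, function(b) b$f, numeric(1)))
  if (fs_eeg < 2 * f_max)
    stop("fs_eeg below twice the highest rendered frequency (", f_max, " Hz)")
  if (fs < 2 * resp_freq || fs < 20)
    stop("fs below twice the highest rendered frequency")
  set.seed(seed)
  n <- round(total * fs)
  t_samp <- (seq_len(n) - 1) / fs

  r <- beats$r_time
  q <- r - q_offset
  b <- q + beats$pep_ms / 1000
  xx <- b + beats$lvet_ms / 1000
  if (any(b <= r))
    warning("some B points precede R (PEP <= q_offset); detection windows assume B after R")

  # ECG: Q dip, R spike, T wave
  ecg <- numeric(n)
  ecg <- add_bumps(ecg, fs, q, rep(-0.15, length(q)), 0.007)
  ecg <- add_bumps(ecg, fs, r, rep(1.0, length(r)), 0.008)
  ecg <- add_bumps(ecg, fs, r + 0.25, rep(0.25, length(r)), 0.045)
  if (noise$ecg > 0) ecg <- ecg + stats::rnorm(n, 0, noise$ecg)

  # baseline impedance with respiration
  resp_phase <- stats::runif(1, 0, 2 * pi)
  z0 <- z0_base + resp_amp * sin(2 * pi * resp_freq * t_samp + resp_phase)
  z0_at <- function(t) z0_base + resp_amp * sin(2 * pi * resp_freq * t + resp_phase)
  if (noise$z0 > 0) z0 <- z0 + stats::rnorm(n, 0, noise$z0)

  # dZ/dt with Kubicek-calibrated amplitude
  amp <- beats$sv_ml / (cal$rho * (cal$L / z0_at(b))^2 * (beats$lvet_ms / 1000))
  dzdt <- numeric(n)
  for (k in seq_along(r)) {
    if (xx[k] + 0.05 > total) next
    dzdt <- render_dzdt_beat(dzdt, fs, b[k], xx[k], amp[k])
  }
  if (noise$dzdt > 0) dzdt <- dzdt + stats::rnorm(n, 0, noise$dzdt)

  # continuous pressure: one pulse per beat, max = SBP, min = DBP
  map_at <- function(t) {
    p <- profiles$map
    if (is.null(p)) return(rep(80, length(t)))
    stats::approx(grid, p, xout = pmin(pmax(t, 0), max(grid)), rule = 2)$y
  }
  onset <- r + 0.15
  bp <- rep(map_at(0) - pulse_pressure / 3, n)
  for (k in seq_along(onset)) {
    e <- if (k < length(onset)) onset[k + 1] else total
    lo <- floor(onset[k] * fs) + 1; hi <- min(n, ceiling(e * fs))
    if (lo < 1 || lo + 1 > hi) next
    idx <- lo:hi
    u <- ((idx - 1) / fs - onset[k]) / (e - onset[k])
    m <- map_at(onset[k])
    dbp <- m - pulse_pressure / 3
    bp[idx] <- dbp + pulse_pressure * sin(pi * pmin(pmax(u, 0), 1))
  }
  if (noise$bp > 0) bp <- bp + stats::rnorm(n, 0, noise$bp)

  # binocular pupil with blink dropouts shared across eyes
  np <- round(total * fs_pupil)
  tp <- (seq_len(np) - 1) / fs_pupil
  pupil_prof <- stats::approx(grid, profiles$pupil %||% rep(3, length(grid)),
                              xout = pmin(tp, max(grid)), rule = 2)$y
  left <- pupil_prof + 0.1 + stats::rnorm(np, 0, noise$pupil)
  right <- pupil_prof - 0.1 + stats::rnorm(np, 0, noise$pupil)
  if (blink_rate > 0) {
    nb <- stats::rpois(1, blink_rate * total / 60)
    if (nb > 0) {
      bt <- stats::runif(nb, 0, total)
      bd <- stats::runif(nb, 0.2, 0.4)
      for (k in seq_len(nb)) {
        idx <- which(tp >= bt[k] & tp < bt[k] + bd[k])
        left[idx] <- NA; right[idx] <- NA
      }
    }
  }

  # EEG: 1/f background + band oscillators with per-epoch amplitude profiles
  channels <- unique(unlist(c(lapply(eeg_spec, function(bd) bd$channels),
                              list(default_eeg_channels()))))
  ne <- round(total * fs_eeg)
  te <- (seq_len(ne) - 1) / fs_eeg
  noise_scale <- attr(eeg_spec, "noise_scale") %||% 1
  eeg <- matrix(0, nrow = length(channels), ncol = ne,
                dimnames = list(channels, NULL))
  freqs <- (seq_len(ne) - 1) / ne * fs_eeg
  freqs <- pmin(freqs, fs_eeg - freqs)
  shape <- 1 / sqrt(pmax(freqs, 0.5))
  for (ch in seq_along(channels)) {
    w <- stats::rnorm(ne)
    bg <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / ne
    eeg[ch, ] <- noise_scale * 3 * bg / stats::sd(bg)
  }
  ramp2 <- function(t) pmin(pmax((t - epoch_interval(protocol, "immersion")["start"]) / 2, 0), 1)
  for (bd_name in names(eeg_spec)) {
    bd <- eeg_spec[[bd_name]]
    phase <- stats::runif(length(channels), 0, 2 * pi)
    for (ch_name in channels) {
      a <- rep(bd$base, ne)
      if (identical(condition, "treatment") && ch_name %in% bd$channels) {
        a <- a + bd$ant * bd$h^(trial - 1) * anticipatory_shape(protocol, te) +
          bd$evoked * bd$h^(trial - 1) * ramp2(te) *
            (te < epoch_interval(protocol, "immersion")["end"])
      }
      ci <- match(ch_name, channels)
      eeg[ci, ] <- eeg[ci, ] + a * sin(2 * pi * bd$f * te + phase[ci])
    }
  }

  truth <- data.frame(r_time = r, q_time = q, b_time = b, x_time = xx,
                      rr = beats$rr, pep_ms = beats$pep_ms,
                      lvet_ms = beats$lvet_ms, sv_ml = beats$sv_ml,
                      dzdt_amp = amp)
  structure(list(
    ecg = list(data = ecg, fs = fs),
    dzdt = list(data = dzdt, fs = fs),
    z0 = list(data = z0, fs = fs),
    bp = list(data = bp, fs = fs),
    pupil = list(t = tp, left = left, right = right, fs = fs_pupil),
    eeg = list(data = eeg, fs = fs_eeg, channels = channels),
    truth = truth, protocol = protocol,
    condition = condition, trial = trial
  ), class = "trial_signals")
}
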