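#' Effect specification for one simulated measure
#'
#' Each continuous measure is generated from a common additive structure:
#' a subject-specific baseline level, an anticipatory shift present during the
#' baseline and prep epochs of treatment trials, and an evoked shift present
#' during immersion of treatment trials (ramping in over `ramp` seconds after
#' `onset_lag`, decaying exponentially during recovery). Both shifts habituate
#' multiplicatively over trials: on trial t the shift is `delta * h^(t-1)`.
#'
#' @param measure measure name (e.g. "HR").
#' @param baseline_level population baseline, in measure units.
#' @param anticipatory_delta treatment shift during baseline/prep (units).
#' @param evoked_delta treatment shift during immersion (units).
#' @param h_anticipatory,h_evoked per-trial multiplicative habituation ratios
#'   in (0, 1]; 1 means no habituation.
#' @param onset_lag seconds after immersion onset before the evoked shift
#'   starts to ramp in.
#' @param ramp ramp-in duration of the evoked shift, seconds.
#' @param recovery_tau exponential decay constant of the evoked shift after
#'   the feet leave the water, seconds.
#' @param between_sd between-subject SD of the baseline level (units).
#' @param cond_sd SD of the subject-by-session offset (units); models day-to-
#'   day level differences between a subject's two sessions.
#' @param noise_sd within-trial measurement noise SD at 1 Hz (units).
#' @param units unit label.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(measure, baseline_level, anticipatory_delta = 0,
                        evoked_delta = 0, h_anticipatory = 1, h_evoked = 1,
                        onset_lag = 1, ramp = 5, recovery_tau = 10,
                        between_sd = 0, cond_sd = 0, noise_sd = 0,
                        units = "") {
  stopifnot(h_anticipatory > 0, h_anticipatory <= 1,
            h_evoked > 0, h_evoked <= 1,
            between_sd >= 0, cond_sd >= 0, noise_sd >= 0)
  structure(list(measure = measure, baseline_level = baseline_level,
                 anticipatory_delta = anticipatory_delta,
                 evoked_delta = evoked_delta,
                 h_anticipatory = h_anticipatory, h_evoked = h_evoked,
                 onset_lag = onset_lag, ramp = ramp,
                 recovery_tau = recovery_tau, between_sd = between_sd,
                 cond_sd = cond_sd, noise_sd = noise_sd, units = units),
            class = "effect_spec")
}

#' Default effect specifications
#'
#' Baseline levels follow the published resting means of the cold-pressor
#' cohort (HR 66 bpm, PEP 83 ms, LVET 288 ms, SV 37.6 mL, MAP 80 mmHg,
#' log HF 6.35); evoked magnitudes and the habituation ratio (HR +12 bpm,
#' h = 0.85) are the package's documented illustrative defaults, since the
#' source figures report effect windows rather than magnitudes.
#'
#' @param null if `TRUE`, all anticipatory/evoked deltas are zero and h = 1
#'   (the calibration configuration); noise and between-subject structure are
#'   retained.
#' @return named list of `effect_spec` objects, plus `pain` and `cortisol`
#'   scalar generator settings as attributes of the list elements
#'   `pain`/`cortisol`.
#' @export
default_effect_specs <- function(null = FALSE) {
  z <- function(x) if (null) 0 else x
  h <- function(x) if (null) 1 else x
  specs <- list(
    HR    = effect_spec("HR",    66,   z(3),   z(12),  h(0.85), h(0.85),
                        between_sd = 8,  cond_sd = 2.5, noise_sd = 2,
                        units = "bpm"),
    PEP   = effect_spec("PEP",   83,   z(-2),  z(-8),  h(0.85), h(0.85),
                        between_sd = 9,  cond_sd = 2,   noise_sd = 2,
                        units = "ms"),
    LVET  = effect_spec("LVET",  288,  z(-3),  z(-15), h(0.85), h(0.85),
                        between_sd = 20, cond_sd = 4,   noise_sd = 4,
                        units = "ms"),
    SV    = effect_spec("SV",    37.6, z(-1),  z(-4),  h(0.85), h(0.85),
                        between_sd = 8,  cond_sd = 1.5, noise_sd = 1.2,
                        units = "mL"),
    MAP   = effect_spec("MAP",   80,   z(4),   z(8),   h(0.9),  h(0.9),
                        between_sd = 9,  cond_sd = 2,   noise_sd = 1.5,
                        units = "mmHg"),
    HF    = effect_spec("HF",    6.35, z(-0.1), z(-0.8), h(0.9), h(0.9),
                        between_sd = 1,  cond_sd = 0.3, noise_sd = 0.25,
                        units = "log ms^2"),
    PUPIL = effect_spec("PUPIL", 3,    z(0.3), z(1),   h(0.9),  h(0.9),
                        between_sd = 0.5, cond_sd = 0.15, noise_sd = 0.1,
                        units = "a.u.")
  )
  attr(specs, "pain") <- list(evoked = z(60), h = h(0.85), sd = 10,
                              control_sd = if (null) 10 else 2)
  attr(specs, "cortisol") <- list(level = 0.25, decline = z(0.04),
                                  cond_offset = z(0.02), between_sd = 0.06,
                                  noise_sd = 0.02)
  attr(specs, "null") <- null
  specs
}

#' Null (no-effect) configuration
#' @return `default_effect_specs(null = TRUE)`.
#' @export
null_effect_specs <- function() default_effect_specs(null = TRUE)

# Time-course shape of the evoked effect: 0 before immersion onset + lag,
# linear ramp to 1, held through immersion, exponential decay in recovery.
evoked_shape <- function(spec, protocol, t) {
  imm <- epoch_interval(protocol, "immersion")
  on <- imm["start"] + spec$onset_lag
  s <- numeric(length(t))
  ramp <- pmax(spec$ramp, 1e-9)
  s <- pmin(pmax((t - on) / ramp, 0), 1)
  rec <- t >= imm["end"]
  s[rec] <- s[rec] * exp(-(t[rec] - imm["end"]) / spec$recovery_tau)
  s
}

# Anticipatory shape: 1 during baseline and prep, 0 from immersion onward.
anticipatory_shape <- function(protocol, t) {
  imm <- epoch_interval(protocol, "immersion")
  as.numeric(t < imm["start"])
}

#' Noise-free truth profile of one measure for one trial
#'
#' @param spec an `effect_spec`.
#' @param protocol a `protocol_definition`.
#' @param trial trial index 1-5.
#' @param condition `"treatment"` or `"control"`.
#' @param t times (seconds); defaults to the 1-Hz grid.
#' @param level_offset additive subject/session level offset (units).
#' @return numeric profile at `t`.
#' @export
truth_profile <- function(spec, protocol, trial, condition,
                          t = time_grid(protocol), level_offset = 0) {
  base <- spec$baseline_level + level_offset
  if (identical(condition, "treatment")) {
    ant <- spec$anticipatory_delta * spec$h_anticipatory^(trial - 1)
    evo <- spec$evoked_delta * spec$h_evoked^(trial - 1)
    base + ant * anticipatory_shape(protocol, t) +
      evo * evoked_shape(spec, protocol, t)
  } else {
    rep(base, length(t))
  }
}
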