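#' Extract all 1-Hz measures from one trial's raw signals
#'
#' The full beat-level pipeline: R-peak detection, fiducial location,
#' 15-s moving-ensemble averaging (PEP, LVET, ensemble dZ/dt peak),
#' Kubicek stroke volume, cardiac output, pressure measures and TPR,
#' trailing-window HF, respiration estimation and (optionally) respiration
#' correction of every cardiovascular series, pupil preprocessing -- each
#' resampled/aggregated onto the 1-Hz protocol grid.
#'
#' @param signals a `trial_signals` object (or an equivalent list).
#' @param protocol a `protocol_definition`; defaults to the one attached to
#'   `signals`.
#' @param cal `calibration_constants` for the stroke-volume formula.
#' @param respiration_correct residualize cardiovascular series on
#'   respiratory state (per the standard preprocessing); logical or a
#'   character vector of measures to correct.
#' @param window_s ensemble window, seconds.
#' @return named list of `continuous_measure`s: HR, PEP, LVET, SV, CO, MAP,
#'   SBP, DBP, TPR, HF, PUPIL; attribute `beat_table` holds the per-beat
#'   table, `flagged` whether R detection failed.
#' @export
extract_trial_measures <- function(signals,
                                   protocol = signals$protocol,
                                   cal = default_calibration(),
                                   respiration_correct = TRUE,
                                   window_s = 15) {
  fs <- signals$ecg$fs
  grid <- time_grid(protocol)
  nT <- n_grid(protocol)
  empty <- function(m, u) continuous_measure(rep(NA_real_, nT),
                                             rep(FALSE, nT), m, u)
  r_times <- detect_r_peaks(signals$ecg$data, fs)
  if (!length(r_times)) {
    out <- list(HR = empty("HR", "bpm"))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  bt <- locate_fiducials(signals$ecg$data, signals$dzdt$data, r_times, fs)
  bt <- beat_measures(bt, signals$dzdt$data, signals$z0$data, fs, cal)
  ens <- moving_ensemble(signals$ecg$data, signals$dzdt$data,
                         bt$r_time[bt$valid], fs, protocol,
                         window_s = window_s)

  hr <- resample_1hz(bt$r_time, bt$hr, protocol, "HR", "bpm")
  pep <- continuous_measure(ens$pep_ms, ens$mask, "PEP", "ms")
  lvet <- continuous_measure(ens$lvet_ms, ens$mask, "LVET", "ms")
  # per-second Z0 (window mean) for the ensemble stroke volume
  z0_sec <- vapply(grid, function(t0) {
    idx <- max(1, round((t0 - window_s / 2) * fs)):
      min(length(signals$z0$data), round((t0 + window_s / 2) * fs))
    mean(signals$z0$data[idx])
  }, numeric(1))
  sv_vals <- cal$rho * (cal$L / z0_sec)^2 * (ens$lvet_ms / 1000) *
    ens$max_dzdt
  sv <- continuous_measure(sv_vals, ens$mask & is.finite(sv_vals),
                           "SV", "mL")
  co_vals <- hr$values * sv$values / 1000
  co <- continuous_measure(co_vals, hr$mask & sv$mask, "CO", "L/min")
  pm <- pressure_measures(signals$bp$data, signals$bp$fs, protocol,
                          co_series = co)
  hf <- hf_timecourse(bt$r_time, protocol)

  resp <- estimate_respiration(signals$z0$data, fs, r_times = bt$r_time)
  out <- list(HR = hr, PEP = pep, LVET = lvet, SV = sv, CO = co,
              MAP = pm$map, SBP = pm$sbp, DBP = pm$dbp, TPR = pm$tpr,
              HF = hf)
  correct_set <- if (isTRUE(respiration_correct)) names(out)
                 else if (is.character(respiration_correct)) respiration_correct
                 else character(0)
  if (length(correct_set) && !is.null(resp$state) &&
      any(is.finite(resp$state$state))) {
    state_grid <- stats::approx(resp$state$r_time, resp$state$state,
                                xout = grid, rule = 1, ties = mean)$y
    for (m in intersect(correct_set, names(out))) {
      ok <- sum(is.finite(out[[m]]$values) & is.finite(state_grid))
      if (ok >= 10)
        out[[m]] <- respiration_correct(out[[m]], state_grid)
    }
  }
  if (!is.null(signals$pupil))
    out$PUPIL <- preprocess_pupil(signals$pupil, protocol)
  attr(out, "beat_table") <- bt
  attr(out, "flagged") <- FALSE
  out
}

#' Run the extraction pipeline over a rendered study
#'
#' Builds `measure_panel`s from the raw waveforms of every rendered trial.
#'
#' @param study a `study_simulation` with `render = TRUE`.
#' @param measures which measures to panel.
#' @param ... passed to [extract_trial_measures()].
#' @return named list of `measure_panel`s.
#' @export
process_study <- function(study, measures = c("HR", "PEP", "LVET", "SV",
                                              "CO", "MAP", "TPR", "HF",
                                              "PUPIL"), ...) {
  if (is.null(study$sessions)) stop("study was not rendered")
  subj <- names(study$sessions)
  conditions <- c("treatment", "control")
  nT <- n_grid(study$protocol)
  mk <- function() array(NA_real_, c(length(subj), 2, 5, nT),
                         dimnames = list(subj, conditions,
                                         paste0("T", 1:5), NULL))
  vals <- sapply(measures, function(m) mk(), simplify = FALSE)
  for (i in seq_along(subj)) {
    for (ci in 1:2) {
      sess <- study$sessions[[i]][[conditions[ci]]]
      for (tr in 1:5) {
        ex <- extract_trial_measures(sess$trials[[tr]], ...)
        for (m in measures) {
          if (!is.null(ex[[m]])) vals[[m]][i, ci, tr, ] <- ex[[m]]$values
        }
      }
    }
  }
  sapply(measures, function(m) measure_panel(vals[[m]], measure = m),
         simplify = FALSE)
}
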