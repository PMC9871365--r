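#' Simulate a complete repeated-exposure study
#'
#' Generates, for each subject, a treatment (cold water) and a control (warm
#' water) session of five trials each, with the statistical structure the
#' downstream analysis assumes: condition effects during immersion,
#' anticipatory effects during baseline/prep, multiplicative trial-wise
#' habituation, between-subject and session-level variability, and white
#' within-trial noise. Ground truth (noise-free profiles, generator
#' parameters, seeds) is returned alongside.
#'
#' Two generation depths are available. With `render = FALSE` (default) only
#' the 1-Hz measure panels are produced, directly from the truth profiles plus
#' measurement noise -- this is the fast path used for large calibration and
#' power simulations. With `render = TRUE` every trial's raw waveforms (ECG,
#' dZ/dt, Z0, pressure, pupil, EEG) are rendered as well, for exercising the
#' extraction pipeline.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param spec effect specifications from [default_effect_specs()].
#' @param protocol a `protocol_definition`.
#' @param seed master integer seed; identical seeds give identical studies.
#' @param render also render raw waveforms per trial (slow).
#' @param fs,fs_pupil,fs_eeg renderer sampling rates, Hz.
#' @param rr_jitter_sd white RR jitter SD (s) for the beat timeline.
#' @param cal calibration constants for the renderer.
#' @param eeg_spec EEG oscillator spec; defaults to
#'   `default_eeg_spec(null = attr(spec, "null"))`.
#' @param noise renderer noise levels ([default_render_noise()]).
#' @param blink_rate pupil blink dropouts per minute.
#' @return list of class `study_simulation`: `subjects` (data.frame with id,
#'   start_time, condition_order), `panels` (named list of `measure_panel`,
#'   including derived CO and TPR), `pain` (n x 2 x 5 array), `cortisol`
#'   (n x 2 x 3 array, samples pre-T1/pre-T3/post-T5), `truth` (noise-free
#'   profile arrays per measure and, when rendered, per-trial beat tables),
#'   `sessions` (when rendered), `spec`, `protocol`, `seed`.
#' @export
simulate_study <- function(n_subjects, spec = default_effect_specs(),
                           protocol = make_default_protocol(), seed = 1,
                           render = FALSE, fs = 250, fs_pupil = 500,
                           fs_eeg = 250, rr_jitter_sd = 0.005,
                           cal = default_calibration(), eeg_spec = NULL,
                           noise = default_render_noise(), blink_rate = 2) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (is.null(eeg_spec))
    eeg_spec <- default_eeg_spec(null = isTRUE(attr(spec, "null")))
  nT <- n_grid(protocol)
  measures <- names(spec)
  conditions <- c("treatment", "control")
  trials <- paste0("T", 1:5)
  subj_ids <- sprintf("s%02d", seq_len(n_subjects))

  set.seed(seed)
  subjects <- data.frame(
    id = subj_ids,
    start_time = rep(c("AM", "PM"), length.out = n_subjects),
    condition_order = rep(c("treatment_first", "control_first"),
                          length.out = n_subjects),
    stringsAsFactors = FALSE
  )

  dims <- c(n_subjects, 2, 5, nT)
  dn <- list(subj_ids, conditions, trials, NULL)
  values <- lapply(measures, function(m) array(NA_real_, dims, dimnames = dn))
  names(values) <- measures
  truth_prof <- lapply(measures, function(m) array(NA_real_, dims, dimnames = dn))
  names(truth_prof) <- measures

  # level offsets: subject baseline (shared across sessions) + session offset
  subj_off <- sapply(measures, function(m)
    stats::rnorm(n_subjects, 0, spec[[m]]$between_sd))
  sess_off <- array(stats::rnorm(n_subjects * 2 * length(measures)),
                    dim = c(n_subjects, 2, length(measures)),
                    dimnames = list(subj_ids, conditions, measures))
  for (m in measures)
    sess_off[, , m] <- sess_off[, , m] * spec[[m]]$cond_sd

  grid <- time_grid(protocol)
  for (i in seq_len(n_subjects)) {
    for (ci in 1:2) {
      for (tr in 1:5) {
        for (m in measures) {
          lvl <- subj_off[i, m] + sess_off[i, ci, m]
          prof <- truth_profile(spec[[m]], protocol, tr, conditions[ci],
                                t = grid, level_offset = lvl)
          truth_prof[[m]][i, ci, tr, ] <- prof
          values[[m]][i, ci, tr, ] <- prof +
            stats::rnorm(nT, 0, spec[[m]]$noise_sd)
        }
      }
    }
  }

  panels <- lapply(measures, function(m)
    measure_panel(values[[m]], measure = m, units = spec[[m]]$units))
  names(panels) <- measures
  # derived measures, consistent with the extraction-side formulas
  if (all(c("HR", "SV") %in% measures)) {
    co <- values$HR * values$SV / 1000
    panels$CO <- measure_panel(co, measure = "CO", units = "L/min")
    if ("MAP" %in% measures) {
      tpr <- 80 * values$MAP / co
      panels$TPR <- measure_panel(tpr, measure = "TPR", units = "dyn s cm^-5")
    }
  }

  # pain ratings: evoked, habituating under treatment; ~0 under control
  pcfg <- attr(spec, "pain")
  pain <- array(NA_real_, c(n_subjects, 2, 5),
                dimnames = list(subj_ids, conditions, trials))
  for (i in seq_len(n_subjects)) {
    for (tr in 1:5) {
      mu <- pcfg$evoked * pcfg$h^(tr - 1)
      pain[i, "treatment", tr] <-
        round(min(100, max(0, stats::rnorm(1, mu, pcfg$sd))))
      pain[i, "control", tr] <-
        round(min(100, max(0, stats::rnorm(1, 0, pcfg$control_sd))))
    }
  }

  # cortisol: session-wide declining trend + condition offset
  ccfg <- attr(spec, "cortisol")
  cortisol <- array(NA_real_, c(n_subjects, 2, 3),
                    dimnames = list(subj_ids, conditions,
                                    c("preT1", "preT3", "postT5")))
  cort_base <- ccfg$level + stats::rnorm(n_subjects, 0, ccfg$between_sd) +
    ifelse(subjects$start_time == "AM", 0.05, -0.02)
  for (i in seq_len(n_subjects)) {
    for (ci in 1:2) {
      off <- if (conditions[ci] == "treatment") ccfg$cond_offset else 0
      for (k in 1:3) {
        cortisol[i, ci, k] <- max(0.01, cort_base[i] - ccfg$decline * (k - 1) +
                                    off + stats::rnorm(1, 0, ccfg$noise_sd))
      }
    }
  }

  out <- list(subjects = subjects, panels = panels, pain = pain,
              cortisol = cortisol,
              truth = list(profiles = truth_prof, subj_off = subj_off,
                           sess_off = sess_off),
              spec = spec, protocol = protocol, seed = seed)

  if (render) {
    sessions <- vector("list", n_subjects)
    names(sessions) <- subj_ids
    beats_truth <- list()
    idx <- 0
    for (i in seq_len(n_subjects)) {
      sessions[[i]] <- list()
      for (ci in 1:2) {
        cond <- conditions[ci]
        trials_out <- vector("list", 5)
        for (tr in 1:5) {
          idx <- idx + 1
          profiles <- list(
            hr = truth_prof$HR[i, ci, tr, ],
            pep = truth_prof$PEP[i, ci, tr, ],
            lvet = truth_prof$LVET[i, ci, tr, ],
            sv = truth_prof$SV[i, ci, tr, ],
            hf = truth_prof$HF[i, ci, tr, ],
            map = truth_prof$MAP[i, ci, tr, ],
            pupil = truth_prof$PUPIL[i, ci, tr, ]
          )
          beats <- simulate_beat_timeline(profiles, protocol,
                                          rr_jitter_sd = rr_jitter_sd,
                                          seed = derive_seed(seed, idx))
          sig <- render_trial(beats, profiles, protocol, cond, tr,
                              fs = fs, fs_pupil = fs_pupil, fs_eeg = fs_eeg,
                              cal = cal, eeg_spec = eeg_spec, noise = noise,
                              blink_rate = blink_rate,
                              seed = derive_seed(seed, idx + 100000))
          trials_out[[tr]] <- sig
          beats_truth[[paste(subj_ids[i], cond, trials[tr], sep = ".")]] <-
            sig$truth
        }
        sessions[[i]][[cond]] <- list(
          subject_id = subj_ids[i], condition = cond,
          start_time = subjects$start_time[i], trials = trials_out,
          pain = pain[i, ci, ], cortisol = cortisol[i, ci, ]
        )
      }
    }
    out$sessions <- sessions
    out$truth$beats <- beats_truth
  }
  class(out) <- "study_simulation"
  out
}

#' @export
print.study_simulation <- function(x, ...) {
  cat(sprintf("study_simulation: %d subjects x 2 conditions x 5 trials, seed %d\n",
              nrow(x$subjects), x$seed))
  cat("  panels:", paste(names(x$panels), collapse = ", "), "\n")
  cat("  rendered signals:", if (is.null(x$sessions)) "no" else "yes", "\n")
  invisible(x)
}

#' Write a session's channels to per-channel CSV files
#'
#' One file per channel named `<subject>_<condition>_T<trial>_<channel>.csv`
#' with columns `time_s,value` (EEG: one column per channel; pupil: left and
#' right columns with missing samples empty).
#'
#' @param session one element of `study_simulation$sessions[[i]][[cond]]`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_session_csv <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tr in seq_along(session$trials)) {
    sig <- session$trials[[tr]]
    stub <- sprintf("%s_%s_T%d", session$subject_id, session$condition, tr)
    for (ch in c("ecg", "dzdt", "z0", "bp")) {
      d <- sig[[ch]]
      p <- file.path(dir, sprintf("%s_%s.csv", stub, ch))
      utils::write.csv(data.frame(time_s = (seq_along(d$data) - 1) / d$fs,
                                  value = d$data), p, row.names = FALSE)
      paths <- c(paths, p)
    }
    p <- file.path(dir, sprintf("%s_pupil.csv", stub))
    utils::write.csv(data.frame(time_s = sig$pupil$t, left = sig$pupil$left,
                                right = sig$pupil$right), p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, sprintf("%s_eeg.csv", stub))
    eegdf <- as.data.frame(t(sig$eeg$data))
    names(eegdf) <- sig$eeg$channels
    eegdf <- cbind(time_s = (seq_len(ncol(sig$eeg$data)) - 1) / sig$eeg$fs,
                   eegdf)
    utils::write.csv(eegdf, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
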