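#' Event-related spectral perturbation (ERSP) grid
#'
#' Short-time spectral decomposition with Hann-tapered 1-s windows hopped at
#' 1 s (1-Hz frequency and temporal resolution), frequencies 1-30 Hz, with
#' powers additionally averaged over a 4-bin moving frequency neighborhood
#' (the spectral-smoothing reading of the source toolbox's "4 Hz moving
#' window"). The dB variant divides each channel x frequency row by its mean
#' over the baseline seconds (grid times 1-40) of the same trial:
#' `10 * log10(power / baseline_mean)`.
#'
#' @param data channels x samples matrix (microvolts) or a `trial_signals`
#'   object (its `eeg` channel is used).
#' @param fs sampling rate, Hz (integer, >= 60).
#' @param protocol a `protocol_definition`.
#' @param freqs frequencies, Hz (default 1:30).
#' @param smooth_bins width of the frequency moving average (default 4).
#' @param baseline_times grid seconds defining the dB baseline (default 1:40).
#' @return object of class `ersp_grid`: list with `raw` and `db` arrays
#'   `[channel, frequency, time]`, `freqs`, `channels`, `protocol`.
#' @export
compute_ersp <- function(data, fs = NULL, protocol = make_default_protocol(),
                         freqs = 1:30, smooth_bins = 4,
                         baseline_times = 1:40) {
  if (inherits(data, "trial_signals")) {
    fs <- data$eeg$fs
    protocol <- data$protocol
    data <- data$eeg$data
  }
  if (is.null(fs)) stop("fs required")
  if (fs < 2 * max(freqs)) stop("fs must be at least twice the top frequency")
  if (abs(fs - round(fs)) > 1e-9) stop("fs must be an integer rate")
  fs <- round(fs)
  nT <- n_grid(protocol)
  nch <- nrow(data)
  chn <- rownames(data) %||% paste0("ch", seq_len(nch))
  w <- hann_taper(fs)
  wsum2 <- sum(w)^2 / 2   # amplitude normalization: sinusoid amp A -> A^2/2
  raw <- array(NA_real_, c(nch, length(freqs), nT),
               dimnames = list(chn, freqs, NULL))
  bins <- freqs + 1  # 1-Hz bin spacing with a 1-s window
  for (tt in seq_len(nT)) {
    i0 <- (tt - 1) * fs
    if (i0 + fs > ncol(data)) break
    seg <- data[, (i0 + 1):(i0 + fs), drop = FALSE]
    seg <- sweep(seg, 1, rowMeans(seg))
    X <- stats::mvfft(t(sweep(seg, 2, w, "*")))
    raw[, , tt] <- t(Mod(X[bins, , drop = FALSE])^2 / wsum2)
  }
  if (smooth_bins > 1) {
    lo <- floor((smooth_bins - 1) / 2); hi <- smooth_bins - 1 - lo
    sm <- raw
    for (f in seq_along(freqs)) {
      sel <- max(1, f - lo):min(length(freqs), f + hi)
      sm[, f, ] <- apply(raw[, sel, , drop = FALSE], c(1, 3), mean)
    }
    raw <- sm
  }
  base_idx <- baseline_times + 1  # grid second s lives at index s + 1
  base_mean <- apply(raw[, , base_idx, drop = FALSE], c(1, 2), mean,
                     na.rm = TRUE)
  db <- 10 * log10(sweep(raw, c(1, 2), pmax(base_mean, 1e-30), "/"))
  structure(list(raw = raw, db = db, freqs = freqs, channels = chn,
                 protocol = protocol), class = "ersp_grid")
}

#' Canonical frequency bands and trial periods
#'
#' Bands: delta 1-3, theta 4-7, alpha 8-14, beta 15-30 Hz. Periods (grid
#' seconds, inclusive): baseline 1-40, early 65-94, mid 95-124, late 125-154,
#' recovery 155-190.
#' @return named list of integer vectors.
#' @export
eeg_bands <- function() {
  list(delta = 1:3, theta = 4:7, alpha = 8:14, beta = 15:30)
}

#' @rdname eeg_bands
#' @export
eeg_periods <- function() {
  list(baseline = 1:40, early = 65:94, mid = 95:124, late = 125:154,
       recovery = 155:190)
}

#' Reduce an ERSP grid to a band x period panel
#'
#' Arithmetic mean over band frequencies, then over period seconds. The
#' baseline period is summarized from raw log power (`10*log10(power)`, no
#' self-division); post-baseline periods use the baseline-corrected dB grid.
#'
#' @param ersp an `ersp_grid`.
#' @param bands named list of frequency vectors (default [eeg_bands()]).
#' @param periods named list of grid-second vectors (default [eeg_periods()]).
#' @return data.frame `channel, band, period, value` (dB).
#' @export
reduce_band_period <- function(ersp, bands = eeg_bands(),
                               periods = eeg_periods()) {
  out <- expand.grid(channel = ersp$channels, band = names(bands),
                     period = names(periods), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$value <- NA_real_
  for (r in seq_len(nrow(out))) {
    fsel <- match(bands[[out$band[r]]], ersp$freqs)
    tsel <- periods[[out$period[r]]] + 1
    ci <- match(out$channel[r], ersp$channels)
    if (out$period[r] == "baseline") {
      v <- 10 * log10(pmax(ersp$raw[ci, fsel, tsel], 1e-30))
    } else {
      v <- ersp$db[ci, fsel, tsel]
    }
    out$value[r] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Band x period panel for a rendered study
#'
#' Runs [compute_ersp()] and [reduce_band_period()] on every rendered trial
#' of a simulated study.
#'
#' @param study a `study_simulation` with `sessions` (i.e. `render = TRUE`).
#' @param ... passed to [compute_ersp()].
#' @return tidy data.frame `subject, condition, trial, channel, band,
#'   period, value`.
#' @export
eeg_band_panel <- function(study, ...) {
  if (is.null(study$sessions)) stop("study was not rendered")
  rows <- list()
  for (sid in names(study$sessions)) {
    for (cond in names(study$sessions[[sid]])) {
      sess <- study$sessions[[sid]][[cond]]
      for (tr in seq_along(sess$trials)) {
        ersp <- compute_ersp(sess$trials[[tr]], ...)
        red <- reduce_band_period(ersp)
        red$subject <- sid; red$condition <- cond
        red$trial <- paste0("T", tr)
        rows[[length(rows) + 1]] <- red
      }
    }
  }
  do.call(rbind, rows)[, c("subject", "condition", "trial", "channel",
                           "band", "period", "value")]
}
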