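#' Estimate respiration from the baseline impedance signal
#'
#' Band-passes Z0 to the respiratory range (0.1-0.4 Hz), forms the analytic
#' signal, and returns instantaneous phase and magnitude plus the
#' "respiratory state" -- the z-scored product of phase and magnitude sampled
#' at each R time -- used as the covariate for respiration correction.
#'
#' @param z0 baseline impedance trace (Ohm) at rate `fs`.
#' @param fs sampling rate, Hz.
#' @param r_times R times (seconds) at which to sample the state.
#' @param band respiratory band, Hz.
#' @return list with `signal` (band-passed trace), `phase`, `magnitude`
#'   (per sample), and, when `r_times` given, a data.frame `state` with
#'   `r_time, phase, magnitude, state`. When Z0 is degenerate (constant) the
#'   state is NA with a warning.
#' @export
estimate_respiration <- function(z0, fs, r_times = NULL,
                                 band = c(0.1, 0.4)) {
  if (length(z0) < 60 * fs) stop("z0 must span at least 60 s")
  if (stats::sd(z0) < 1e-12) {
    warning("degenerate (constant) z0: respiration state undefined")
    resp <- rep(0, length(z0))
    st <- if (is.null(r_times)) NULL else
      data.frame(r_time = r_times, phase = NA_real_, magnitude = NA_real_,
                 state = NA_real_)
    return(list(signal = resp, phase = rep(NA_real_, length(z0)),
                magnitude = rep(0, length(z0)), state = st))
  }
  resp <- fft_bandpass(z0, fs, band[1], band[2])
  an <- analytic_signal(resp)
  phase <- Arg(an)
  magnitude <- Mod(an)
  out <- list(signal = resp, phase = phase, magnitude = magnitude)
  if (!is.null(r_times)) {
    idx <- pmin(pmax(round(r_times * fs) + 1, 1), length(z0))
    prod <- phase[idx] * magnitude[idx]
    s <- stats::sd(prod)
    state <- if (is.finite(s) && s > 0) (prod - mean(prod)) / s
             else rep(NA_real_, length(prod))
    out$state <- data.frame(r_time = r_times, phase = phase[idx],
                            magnitude = magnitude[idx], state = state)
  }
  out
}

#' Residualize a series on respiratory state
#'
#' Ordinary least squares of the series on the state (with intercept),
#' per subject and measure; the subject's mean level is added back so units
#' are preserved. Points with missing series or state values pass through
#' unchanged in the residual's mask.
#'
#' @param series numeric series (or `continuous_measure`).
#' @param state aligned respiratory state values (unitless).
#' @param min_points minimum complete pairs required (default 10).
#' @return object of the same kind as `series`, respiration-corrected.
#'   If the state is constant the input is returned with a warning.
#' @export
respiration_correct <- function(series, state, min_points = 10) {
  is_cm <- inherits(series, "continuous_measure")
  y <- if (is_cm) series$values else as.numeric(series)
  if (length(y) != length(state))
    stop("series and state must be aligned")
  ok <- is.finite(y) & is.finite(state)
  if (sum(ok) < min_points)
    stop("need at least ", min_points, " complete points")
  if (stats::sd(state[ok]) < 1e-12) {
    warning("constant respiratory state: series returned unchanged")
    return(series)
  }
  fit <- stats::lm.fit(cbind(1, state[ok]), y[ok])
  out <- y
  out[ok] <- fit$residuals + mean(y[ok])
  if (is_cm) continuous_measure(out, series$mask, series$measure,
                                series$units)
  else out
}
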