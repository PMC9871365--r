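#' Preprocess a binocular pupil trace to the 1-Hz grid
#'
#' Per sample, the mean of the available eyes is taken (one missing eye falls
#' back to the other); gaps up to `gap_interp_max` seconds are bridged by
#' linear interpolation; values are averaged into 1-s bins on the protocol
#' grid; bins with more than `missing_max` missing samples are masked.
#' An optional centered 5-s moving average is for visualization only -- the
#' statistics path refuses smoothed input.
#'
#' @param trace data.frame with `t` (seconds), `left`, `right` (a.u., NA =
#'   missing), e.g. `trial_signals$pupil` coerced via `as.data.frame`.
#' @param protocol a `protocol_definition`.
#' @param smooth apply the 5-s visualization smoother.
#' @param smooth_s smoother width, seconds.
#' @param gap_interp_max longest gap bridged by interpolation, seconds.
#' @param missing_max per-bin missing fraction above which the bin is masked.
#' @return a `continuous_measure` (`PUPIL`) with attributes `smoothed` and
#'   `missing_frac` (overall missing fraction before interpolation).
#' @export
preprocess_pupil <- function(trace, protocol, smooth = FALSE, smooth_s = 5,
                             gap_interp_max = 1, missing_max = 0.5) {
  if (is.list(trace) && !is.data.frame(trace))
    trace <- data.frame(t = trace$t, left = trace$left, right = trace$right)
  both <- rowMeans(cbind(trace$left, trace$right), na.rm = TRUE)
  both[is.nan(both)] <- NA
  missing_frac <- mean(is.na(both))
  n <- length(both)
  fs <- 1 / stats::median(diff(trace$t))
  if (any(is.na(both)) && !all(is.na(both))) {
    filled <- stats::approx(trace$t[!is.na(both)], both[!is.na(both)],
                            xout = trace$t, rule = 1)$y
    # only bridge short gaps
    r <- rle(is.na(both))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      if (r$lengths[j] / fs <= gap_interp_max)
        both[starts[j]:ends[j]] <- filled[starts[j]:ends[j]]
    }
  }
  grid <- time_grid(protocol)
  bin <- findInterval(trace$t, c(grid, protocol$total_duration),
                      rightmost.closed = FALSE)
  vals <- rep(NA_real_, length(grid))
  mask <- rep(FALSE, length(grid))
  for (g in seq_along(grid)) {
    w <- both[bin == g]
    if (!length(w)) next
    miss <- mean(is.na(w))
    if (miss <= missing_max && any(!is.na(w))) {
      vals[g] <- mean(w, na.rm = TRUE)
      mask[g] <- TRUE
    }
  }
  if (smooth) vals <- moving_average(vals, smooth_s)
  out <- continuous_measure(vals, mask, "PUPIL", "a.u.")
  attr(out, "smoothed") <- smooth
  attr(out, "missing_frac") <- missing_frac
  out
}

#' Reject subjects with failed pupil trials
#'
#' A subject is excluded when any trial in either condition has a missing
#' fraction at or above `threshold` (default 1: a fully failed detection).
#'
#' @param missing_frac named structure of per-trial missing fractions: either
#'   a 3-d array `[subject, condition, trial]` or a data.frame with columns
#'   `subject, condition, trial, missing_frac`.
#' @param threshold per-trial missing fraction triggering exclusion.
#' @return list with `retained`, `excluded` (subject ids) and `report`
#'   (data.frame of offending trials).
#' @export
reject_pupil_subjects <- function(missing_frac, threshold = 1.0) {
  if (is.array(missing_frac)) {
    dn <- dimnames(missing_frac)
    df <- expand.grid(subject = dn[[1]], condition = dn[[2]],
                      trial = dn[[3]], stringsAsFactors = FALSE)
    df$missing_frac <- as.vector(missing_frac)
  } else df <- missing_frac
  bad <- df[df$missing_frac >= threshold, , drop = FALSE]
  subjects <- unique(df$subject)
  excluded <- unique(bad$subject)
  list(retained = setdiff(subjects, excluded), excluded = excluded,
       report = bad)
}

#' Min-max normalize a panel to [0, 1] per subject
#'
#' Scaling is computed per subject across all of that subject's trials and
#' conditions jointly (so condition differences are preserved); the subject
#' minimum maps to 0 and the maximum to 1. Subjects with constant data map
#' to 0.5 with a warning.
#'
#' @param panel a `measure_panel`.
#' @return the normalized `measure_panel` (units become "0-1").
#' @export
normalize_01 <- function(panel) {
  v <- panel$values
  for (i in seq_len(dim(v)[1])) {
    x <- v[i, , , ]
    rng <- range(x, na.rm = TRUE)
    if (!all(is.finite(rng))) next
    if (rng[2] - rng[1] < 1e-12) {
      warning("constant data for subject ", dimnames(v)[[1]][i],
              ": normalized to 0.5")
      v[i, , , ][!is.na(x)] <- 0.5
    } else {
      v[i, , , ] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  measure_panel(v, panel$mask, panel$measure, units = "0-1")
}
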