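#' Per-beat cardiovascular measures
#'
#' Augments a beat table with the derived hemodynamic quantities: heart rate
#' (60/RR), stroke volume via the Kubicek impedance formula
#' `SV = rho * (L/Z0)^2 * LVET_s * max(dZ/dt)`, and cardiac output
#' `CO = HR * SV / 1000` (L/min). `max(dZ/dt)` is taken between B and X of
#' each beat; `Z0` is the mean baseline impedance over the beat.
#'
#' @param beat_table a `beat_table` from [locate_fiducials()].
#' @param dzdt,z0 traces at rate `fs`.
#' @param fs sampling rate, Hz.
#' @param cal `calibration_constants`.
#' @return the beat table with added `z0_ohm, max_dzdt, sv_ml, co_lmin`;
#'   beats with non-positive Z0 are marked invalid.
#' @export
beat_measures <- function(beat_table, dzdt, z0, fs,
                          cal = default_calibration()) {
  nb <- nrow(beat_table)
  n <- length(dzdt)
  z0_ohm <- max_dz <- sv <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    if (!isTRUE(beat_table$valid[k])) next
    bi <- round(beat_table$b_time[k] * fs) + 1
    xi <- round(beat_table$x_time[k] * fs) + 1
    if (bi < 1 || xi > n || xi <= bi) next
    max_dz[k] <- max(dzdt[bi:xi])
    qi <- max(1, round(beat_table$q_time[k] * fs) + 1)
    z0_ohm[k] <- mean(z0[qi:xi])
    if (!is.finite(z0_ohm[k]) || z0_ohm[k] <= 0) {
      beat_table$valid[k] <- FALSE
      next
    }
    sv[k] <- cal$rho * (cal$L / z0_ohm[k])^2 *
      (beat_table$lvet_ms[k] / 1000) * max_dz[k]
  }
  beat_table$z0_ohm <- z0_ohm
  beat_table$max_dzdt <- max_dz
  beat_table$sv_ml <- sv
  beat_table$co_lmin <- beat_table$hr * sv / 1000
  beat_table
}

#' Beat-level blood-pressure measures and TPR
#'
#' Segments the continuous pressure trace into pulses (adaptive peak
#' detection with a refractory constraint), takes per-pulse systolic maxima
#' and the diastolic minimum between successive peaks, and derives
#' `MAP = DBP + (SBP - DBP)/3` and, given a 1-Hz cardiac-output series,
#' `TPR = 80 * MAP / CO` in dyn s cm^-5.
#'
#' @param bp pressure trace, mmHg, at rate `fs`.
#' @param fs sampling rate, Hz.
#' @param protocol a `protocol_definition`.
#' @param co_series optional 1-Hz CO series (length = grid) for TPR.
#' @param refractory minimum pulse separation, seconds.
#' @return list with `beats` (data.frame `t, sbp, dbp, map, valid`) and
#'   1-Hz `continuous_measure`s `sbp, dbp, map` and `tpr` (if CO given).
#' @export
pressure_measures <- function(bp, fs, protocol, co_series = NULL,
                              refractory = 0.3) {
  n <- length(bp)
  x <- bp - stats::median(bp)
  thr <- 0.35 * stats::quantile(x, 0.999, names = FALSE)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  keep <- integer(0)
  gap <- refractory * fs
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < gap) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  if (length(keep) < 3)
    stop("no identifiable pulses in pressure trace")
  np <- length(keep) - 1
  tmid <- sbp <- dbp <- rep(NA_real_, np)
  for (k in seq_len(np)) {
    seg <- keep[k]:keep[k + 1]
    sbp[k] <- bp[keep[k]]
    dbp[k] <- min(bp[seg])
    tmid[k] <- (keep[k] - 1) / fs
  }
  valid <- sbp > dbp
  map <- dbp + (sbp - dbp) / 3
  beats <- data.frame(t = tmid, sbp = sbp, dbp = dbp, map = map,
                      valid = valid)
  res <- list(beats = beats,
              sbp = resample_1hz(tmid[valid], sbp[valid], protocol,
                                 measure = "SBP", units = "mmHg"),
              dbp = resample_1hz(tmid[valid], dbp[valid], protocol,
                                 measure = "DBP", units = "mmHg"),
              map = resample_1hz(tmid[valid], map[valid], protocol,
                                 measure = "MAP", units = "mmHg"))
  if (!is.null(co_series)) {
    co <- if (inherits(co_series, "continuous_measure")) co_series$values
          else co_series
    tpr <- 80 * res$map$values / co
    res$tpr <- continuous_measure(tpr, res$map$mask & is.finite(tpr),
                                  "TPR", "dyn s cm^-5")
  }
  res
}

#' 1-Hz continuous measure container
#'
#' @param values numeric vector on the protocol grid.
#' @param mask logical validity per point.
#' @param measure,units labels.
#' @return object of class `continuous_measure`.
#' @export
continuous_measure <- function(values, mask = NULL, measure = "", units = "") {
  if (is.null(mask)) mask <- is.finite(values)
  values[!mask] <- NA_real_
  structure(list(values = as.numeric(values), mask = as.logical(mask),
                 measure = measure, units = units),
            class = "continuous_measure")
}

#' @export
print.continuous_measure <- function(x, ...) {
  cat(sprintf("continuous_measure '%s' [%s]: %d points, %d masked\n",
              x$measure, x$units, length(x$values), sum(!x$mask)))
  invisible(x)
}

#' Resample an irregular beat-level series onto the 1-Hz trial grid
#'
#' Linear interpolation onto integer seconds; grid points outside the
#' observed time span are masked (no extrapolation).
#'
#' @param times sample times, seconds.
#' @param values sample values.
#' @param protocol a `protocol_definition`.
#' @param measure,units labels.
#' @return a `continuous_measure` of length `protocol$total_duration`.
#' @export
resample_1hz <- function(times, values, protocol, measure = "", units = "") {
  grid <- time_grid(protocol)
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 2) {
    return(continuous_measure(rep(NA_real_, length(grid)),
                              rep(FALSE, length(grid)), measure, units))
  }
  o <- order(times)
  times <- times[o]; values <- values[o]
  y <- stats::approx(times, values, xout = grid, rule = 1, ties = mean)$y
  continuous_measure(y, is.finite(y), measure, units)
}
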