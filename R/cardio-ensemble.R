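#' Moving-ensemble averaging of beat waveforms
#'
#' For each 1-Hz grid point t, all valid beats whose R falls in the centered
#' window `[t - w/2, t + w/2)` are aligned on R, the ECG and dZ/dt segments
#' are averaged, and the fiducials (Q, B, X) are re-extracted from the
#' averaged waveforms. This gives continuous, denoised PEP/LVET estimates and
#' an ensemble dZ/dt peak for the stroke-volume formula. Grid points with
#' fewer than 2 contributing beats are masked.
#'
#' @param ecg,dzdt aligned traces at rate `fs`.
#' @param r_times R times of usable beats, seconds.
#' @param fs sampling rate, Hz.
#' @param protocol a `protocol_definition`.
#' @param window_s ensemble window width, seconds (default 15, centered).
#' @param seg segment around R to average, seconds `c(before, after)`.
#' @param ... passed to [locate_fiducials()] (windows, smoothing).
#' @return data.frame with one row per grid point: `t, n_beats, pep_ms,
#'   lvet_ms, max_dzdt, hr, mask` (`mask = TRUE` means usable).
#' @export
moving_ensemble <- function(ecg, dzdt, r_times, fs, protocol, window_s = 15,
                            seg = c(0.15, 0.65), ...) {
  nT <- n_grid(protocol)
  grid <- time_grid(protocol)
  n <- length(ecg)
  pre <- round(seg[1] * fs); post <- round(seg[2] * fs)
  seg_len <- pre + post + 1
  ri <- round(r_times * fs) + 1
  ok <- ri - pre >= 1 & ri + post <= n
  ri <- ri[ok]; r_use <- r_times[ok]
  if (length(ri) < 2) {
    return(data.frame(t = grid, n_beats = 0L, pep_ms = NA_real_,
                      lvet_ms = NA_real_, max_dzdt = NA_real_,
                      hr = NA_real_, mask = FALSE))
  }
  offs <- -pre:post
  ecg_seg <- t(vapply(ri, function(i) ecg[i + offs], numeric(seg_len)))
  dz_seg <- t(vapply(ri, function(i) dzdt[i + offs], numeric(seg_len)))
  half <- window_s / 2
  out <- data.frame(t = grid, n_beats = 0L, pep_ms = NA_real_,
                    lvet_ms = NA_real_, max_dzdt = NA_real_, hr = NA_real_,
                    mask = FALSE)
  r_in_seg <- pre / fs  # R sits at sample pre+1 of each segment
  for (g in seq_len(nT)) {
    t0 <- grid[g]
    sel <- which(r_use >= t0 - half & r_use < t0 + half)
    out$n_beats[g] <- length(sel)
    if (length(sel) < 2) next
    avg_ecg <- colMeans(ecg_seg[sel, , drop = FALSE])
    avg_dz <- colMeans(dz_seg[sel, , drop = FALSE])
    ft <- locate_fiducials(avg_ecg, avg_dz, r_in_seg, fs, ...)
    rrw <- diff(r_use[sel])
    out$hr[g] <- 60 / mean(rrw)
    if (isTRUE(ft$valid[1])) {
      out$pep_ms[g] <- ft$pep_ms[1]
      out$lvet_ms[g] <- ft$lvet_ms[1]
      bi <- round(ft$b_time[1] * fs) + 1
      xi <- round(ft$x_time[1] * fs) + 1
      out$max_dzdt[g] <- max(avg_dz[bi:xi])
      out$mask[g] <- TRUE
    }
  }
  out
}
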