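# Paper-style outputs: per-trial mean +/- SEM time courses with stacked
# significance bars, and summary tables. Every plotted number is also
# emitted as CSV so figures are reproducible from text.

trial_colors <- function() {
  c(T1 = "#D62728", T2 = "#FF7F0E", T3 = "#E6C700", T4 = "#2CA02C",
    T5 = "#1F77B4")  # red / orange / yellow / green / blue
}

effect_bar_colors <- function() {
  c(condition = "#4B0082", trial = "#B39DDB", interaction = "#555555")
}

#' Per-trial mean and SEM traces of a panel
#'
#' @param panel a `measure_panel`.
#' @return data.frame `condition, trial, t, mean, sem, n`.
#' @export
panel_traces <- function(panel) {
  d <- dim(panel$values)
  dn <- dimnames(panel$values)
  rows <- list()
  for (ci in seq_len(d[2])) for (tr in seq_len(d[3])) {
    m <- panel$values[, ci, tr, , drop = FALSE]
    dim(m) <- c(d[1], d[4])
    n_ok <- colSums(is.finite(m))
    mu <- colMeans(m, na.rm = TRUE)
    sem <- apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
    rows[[paste(ci, tr)]] <- data.frame(
      condition = dn[[2]][ci], trial = dn[[3]][tr],
      t = seq_len(d[4]) - 1L, mean = mu, sem = sem, n = n_ok)
  }
  do.call(rbind, rows)
}

# Contiguous TRUE runs of a flag track -> intervals data.frame.
track_intervals <- function(flags) {
  x <- flags; x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(t_start = starts[keep] - 1L, t_end = ends[keep] - 1L)
}

#' Time-course figure with significance bars
#'
#' Two stacked panels (treatment, control) of per-trial mean traces, ANOVA
#' effect bars between them, interaction-gated pairwise bars at each panel
#' base, and shading over out-of-scope epochs. All plotted quantities are
#' returned (and optionally written) as CSV tables.
#'
#' @param panel a `measure_panel` (same processing stage as used for
#'   `tracks`).
#' @param tracks a `significance_tracks` from [pointwise_framework()].
#' @param protocol a `protocol_definition`.
#' @param file optional PNG path.
#' @param csv optional path stub; writes `<stub>_traces.csv` and
#'   `<stub>_bars.csv`.
#' @return invisibly, list with `traces` and `bars` data.frames.
#' @export
timecourse_figure <- function(panel, tracks, protocol = make_default_protocol(),
                              file = NULL, csv = NULL) {
  nT <- dim(panel$values)[4]
  if (length(tracks$tracks[[1]]) != nT)
    stop("panel and tracks have mismatched lengths")
  traces <- panel_traces(panel)
  bars <- list()
  for (e in names(tracks$tracks)) {
    iv <- track_intervals(tracks$tracks[[e]])
    if (nrow(iv)) bars[[e]] <- cbind(layer = "anova", effect = e,
                                     condition = NA, iv)
  }
  for (cd in names(tracks$contrast_tracks)) {
    for (cp in names(tracks$contrast_tracks[[cd]])) {
      iv <- track_intervals(tracks$contrast_tracks[[cd]][[cp]])
      if (nrow(iv)) bars[[paste(cd, cp)]] <- cbind(layer = "pairwise",
                                                   effect = cp,
                                                   condition = cd, iv)
    }
  }
  bars <- if (length(bars)) do.call(rbind, bars) else
    data.frame(layer = character(0), effect = character(0),
               condition = character(0), t_start = integer(0),
               t_end = integer(0))
  if (!is.null(csv)) {
    utils::write.csv(traces, paste0(csv, "_traces.csv"), row.names = FALSE)
    utils::write.csv(bars, paste0(csv, "_bars.csv"), row.names = FALSE)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 1000, height = 700, res = 110)
    on.exit(grDevices::dev.off())
    draw_timecourse(traces, bars, tracks, protocol, panel)
  }
  invisible(list(traces = traces, bars = bars))
}

draw_timecourse <- function(traces, bars, tracks, protocol, panel) {
  cols <- trial_colors()
  conditions <- unique(traces$condition)
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  ylim <- range(traces$mean + traces$sem, traces$mean - traces$sem,
                na.rm = TRUE)
  shade <- setdiff(time_grid(protocol), tracks$scope)
  for (cd in conditions) {
    graphics::plot(NULL, xlim = c(0, protocol$total_duration), ylim = ylim,
                   xlab = "time (s)", ylab = panel$measure, main = cd)
    if (length(shade))
      graphics::rect(min(shade), ylim[1], max(shade) + 1, ylim[2],
                     col = grDevices::adjustcolor("gray", 0.35), border = NA)
    for (ep in names(protocol$epochs))
      graphics::abline(v = protocol$epochs[[ep]]["start"], lty = 3,
                       col = "gray40")
    for (tr in names(cols)) {
      sub <- traces[traces$condition == cd & traces$trial == tr, ]
      if (!nrow(sub)) next
      graphics::lines(sub$t, sub$mean, col = cols[tr], lwd = 1.5)
    }
    sub_b <- bars[bars$layer == "pairwise" & bars$condition %in% cd, ,
                  drop = FALSE]
    if (nrow(sub_b)) {
      y0 <- ylim[1] + 0.02 * diff(ylim)
      for (j in seq_len(nrow(sub_b)))
        graphics::segments(sub_b$t_start[j], y0, sub_b$t_end[j] + 1, y0,
                           lwd = 3, col = "black")
    }
    if (cd == conditions[1]) {
      ecol <- effect_bar_colors()
      yb <- ylim[2]
      sub_a <- bars[bars$layer == "anova", , drop = FALSE]
      for (j in seq_len(nrow(sub_a))) {
        off <- match(sub_a$effect[j], names(ecol)) * 0.03 * diff(ylim)
        graphics::segments(sub_a$t_start[j], yb - off,
                           sub_a$t_end[j] + 1, yb - off, lwd = 3,
                           col = ecol[sub_a$effect[j]])
      }
      graphics::legend("topleft", legend = names(cols), col = cols, lwd = 2,
                       bty = "n", cex = 0.7, ncol = 5)
    }
  }
}

#' Baseline summary table
#'
#' Per-measure mean (SD) across subjects of the final-15-s baseline mean in
#' the first trial of the control condition -- the conventional resting
#' description of the sample.
#'
#' @param panels named list of `measure_panel`s.
#' @param protocol a `protocol_definition`.
#' @param window_s baseline window, seconds.
#' @return data.frame `measure, mean, sd, n, units`.
#' @export
summary_tables <- function(panels, protocol = make_default_protocol(),
                           window_s = 15) {
  iv <- epoch_interval(protocol, "baseline")
  idx <- which(time_grid(protocol) >= iv["end"] - window_s &
                 time_grid(protocol) < iv["end"])
  rows <- lapply(names(panels), function(m) {
    p <- panels[[m]]
    per_subj <- apply(p$values[, "control", "T1", idx, drop = FALSE], 1,
                      mean, na.rm = TRUE)
    data.frame(measure = m, mean = mean(per_subj, na.rm = TRUE),
               sd = stats::sd(per_subj, na.rm = TRUE),
               n = sum(is.finite(per_subj)), units = p$units,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
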