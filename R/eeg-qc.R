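# Idealized 10-20 electrode positions on the unit sphere. Inclination is the
# angle from the vertex (Cz), azimuth is measured from the right ear toward
# the nose (+y = anterior, +x = right). These are the standard schematic
# positions, adequate for neighbor weighting and spherical-spline work.
eeg_1020_angles <- function() {
  a <- rbind(
    Cz  = c(0,    0),
    Fz  = c(45,  90),  Pz  = c(45, -90),
    C3  = c(45, 180),  C4  = c(45,   0),
    F3  = c(60, 129),  F4  = c(60,  51),
    P3  = c(60, -129), P4  = c(60, -51),
    Fpz = c(90,  90),  Oz  = c(90, -90),
    Fp1 = c(90, 108),  Fp2 = c(90,  72),
    O1  = c(90, -108), O2  = c(90, -72),
    F7  = c(90, 144),  F8  = c(90,  36),
    T7  = c(90, 180),  T8  = c(90,   0),
    P7  = c(90, -144), P8  = c(90, -36)
  )
  colnames(a) <- c("incl", "azim")
  a
}

#' Standard schematic 10-20 montage
#'
#' @param channels channel names to include (must be standard 10-20 labels).
#' @return data.frame `name, x, y, z` on the unit sphere.
#' @export
default_montage <- function(channels = default_eeg_channels()) {
  a <- eeg_1020_angles()
  missing <- setdiff(channels, rownames(a))
  if (length(missing))
    stop("no schematic position for: ", paste(missing, collapse = ", "))
  incl <- a[channels, "incl"] * pi / 180
  azim <- a[channels, "azim"] * pi / 180
  data.frame(name = channels,
             x = sin(incl) * cos(azim),
             y = sin(incl) * sin(azim),
             z = cos(incl), stringsAsFactors = FALSE)
}

#' Detect abnormal EEG channels
#'
#' A channel is flagged when (a) it flatlines -- any run of at least
#' `flat_s` seconds with absolute first differences below `flat_floor`;
#' (b) its SD exceeds `sd_factor` times the median channel SD; or (c) it
#' fails to correlate at `r > corr_thresh` with a reconstruction of itself
#' from the other channels (inverse-square-distance weighted average).
#'
#' @param data channels x samples matrix (rownames = channel names), microvolts.
#' @param fs sampling rate, Hz.
#' @param montage data.frame from [default_montage()] covering the channels.
#' @param flat_s flatline duration threshold, seconds.
#' @param flat_floor absolute-derivative floor, microvolts per sample.
#' @param sd_factor population-SD multiple for rule (b).
#' @param corr_thresh reconstruction-correlation threshold for rule (c).
#' @return character vector of bad channel names (with `rules` attribute).
#' @export
detect_bad_channels <- function(data, fs, montage = NULL, flat_s = 5,
                                flat_floor = 1e-4, sd_factor = 4,
                                corr_thresh = 0.85) {
  nch <- nrow(data)
  if (nch < 8) stop("need at least 8 channels")
  chn <- rownames(data) %||% as.character(seq_len(nch))
  if (is.null(montage)) montage <- default_montage(chn)
  bad <- character(0); why <- character(0)
  # (a) flatline
  for (i in seq_len(nch)) {
    r <- rle(abs(diff(data[i, ])) < flat_floor)
    if (any(r$values & r$lengths >= flat_s * fs)) {
      bad <- c(bad, chn[i]); why <- c(why, "flatline")
    }
  }
  # (b) amplitude outlier
  sds <- apply(data, 1, stats::sd)
  hit <- sds > sd_factor * stats::median(sds)
  bad <- c(bad, chn[hit]); why <- c(why, rep("amplitude", sum(hit)))
  # (c) reconstruction correlation
  pos <- as.matrix(montage[match(chn, montage$name), c("x", "y", "z")])
  for (i in seq_len(nch)) {
    d2 <- rowSums(sweep(pos[-i, , drop = FALSE], 2, pos[i, ])^2)
    w <- 1 / pmax(d2, 1e-6)
    rec <- crossprod(data[-i, , drop = FALSE], w / sum(w))
    r <- suppressWarnings(stats::cor(data[i, ], rec[, 1]))
    if (!is.finite(r) || r <= corr_thresh) {
      bad <- c(bad, chn[i]); why <- c(why, "correlation")
    }
  }
  ord <- !duplicated(bad)
  out <- bad[ord]
  attr(out, "rules") <- why[ord]
  out
}

# Perrin-style spherical spline basis: g(cos angle) truncated at `lmax`
# Legendre terms with smoothing order m.
spline_g <- function(x, m = 4, lmax = 20) {
  # Legendre recurrence, accumulated sum; x may be a matrix
  p_prev <- array(1, dim = dim(as.matrix(x)))
  p_cur <- as.matrix(x)
  acc <- 3 / (2^m) * p_cur        # l = 1 term: (2l+1)/(l(l+1))^m
  for (l in 2:lmax) {
    p_next <- ((2 * l - 1) * as.matrix(x) * p_cur - (l - 1) * p_prev) / l
    acc <- acc + (2 * l + 1) / (l * (l + 1))^m * p_next
    p_prev <- p_cur; p_cur <- p_next
  }
  acc / (4 * pi)
}

#' Average-reference and spherical-spline interpolation
#'
#' Subtracts the mean of the good channels from every channel, then replaces
#' each bad channel by a spherical-spline interpolation (Perrin smoothing
#' order 4) from the good channels' positions.
#'
#' @param data channels x samples matrix (rownames = channel names).
#' @param bad character vector of bad channel names.
#' @param montage data.frame from [default_montage()].
#' @param max_bad_frac recordings with more bad channels than this fraction
#'   are rejected with an error.
#' @return the re-referenced, interpolated matrix (same shape).
#' @export
rereference_interpolate <- function(data, bad = character(0),
                                    montage = NULL, max_bad_frac = 0.5) {
  chn <- rownames(data)
  if (is.null(chn)) stop("data must have channel rownames")
  if (is.null(montage)) montage <- default_montage(chn)
  good <- setdiff(chn, bad)
  if (!length(good)) stop("no good channels")
  if (length(bad) / length(chn) > max_bad_frac)
    stop("recording rejected: more than ", 100 * max_bad_frac,
         "% bad channels")
  ref <- colMeans(data[good, , drop = FALSE])
  out <- sweep(data, 2, ref)
  if (length(bad)) {
    pos <- as.matrix(montage[match(chn, montage$name), c("x", "y", "z")])
    rownames(pos) <- chn
    cosgg <- tcrossprod(pos[good, , drop = FALSE])
    cosbg <- tcrossprod(pos[bad, , drop = FALSE], pos[good, , drop = FALSE])
    Ggg <- spline_g(pmin(pmax(cosgg, -1), 1))
    Gbg <- spline_g(pmin(pmax(cosbg, -1), 1))
    ng <- length(good)
    A <- rbind(cbind(Ggg, 1), c(rep(1, ng), 0))
    rhs <- rbind(out[good, , drop = FALSE], 0)
    sol <- solve(A, rhs)
    out[bad, ] <- Gbg %*% sol[seq_len(ng), , drop = FALSE] +
      matrix(sol[ng + 1, ], nrow = length(bad), ncol = ncol(out),
             byrow = TRUE)
  }
  out
}

#' Zero-phase high-pass and line-noise notch
#'
#' Convenience preprocessing exercised on real recordings: 1-Hz high-pass to
#' remove drifts and a 60-Hz notch. Implemented as zero-phase FFT filters.
#'
#' @param data channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param highpass high-pass cutoff, Hz (NULL to skip).
#' @param notch line frequency, Hz (NULL to skip; skipped automatically when
#'   `fs < 2 * notch`).
#' @return filtered matrix.
#' @export
eeg_prefilter <- function(data, fs, highpass = 1, notch = 60) {
  for (i in seq_len(nrow(data))) {
    x <- data[i, ]
    if (!is.null(highpass)) x <- fft_highpass(x, fs, highpass)
    if (!is.null(notch) && fs >= 2 * notch) x <- fft_notch(x, fs, notch)
    data[i, ] <- x
  }
  data
}
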