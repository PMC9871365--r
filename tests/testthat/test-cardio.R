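p <- make_default_protocol()

test_that("R-peak detection recovers every beat and is polarity robust", {
  sig <- rendered_trial("noiseless", noise = noiseless())
  tr <- sig$truth
  r <- detect_r_peaks(sig$ecg$data, sig$ecg$fs)
  expect_equal(length(r), nrow(tr))
  expect_lt(max(abs(r - tr$r_time)), 1.01 / sig$ecg$fs)
  r_neg <- detect_r_peaks(-sig$ecg$data, sig$ecg$fs)
  expect_equal(r_neg, r)
  flat <- detect_r_peaks(rep(0.3, 250 * 40), 250)
  expect_length(flat, 0)
  expect_true(attr(flat, "flagged"))
  expect_error(detect_r_peaks(rnorm(100), 250), "shorter")
  expect_error(detect_r_peaks(rnorm(10000), 50), "fs")
})

test_that("fiducials are recovered within one sample on noiseless data", {
  sig <- rendered_trial("noiseless", noise = noiseless())
  tr <- sig$truth
  fs <- sig$ecg$fs
  r <- detect_r_peaks(sig$ecg$data, fs)
  ft <- locate_fiducials(sig$ecg$data, sig$dzdt$data, r, fs)
  ok <- which(ft$valid)
  expect_gt(length(ok), nrow(tr) - 3)  # only trace-edge beats may drop
  idx <- match_truth(ft$r_time[ok], tr)
  expect_lte(max(abs(ft$pep_ms[ok] - tr$pep_ms[idx])), 1000 / fs + 1e-9)
  expect_lte(max(abs(ft$lvet_ms[ok] - tr$lvet_ms[idx])), 1000 / fs + 1e-9)
  expect_true(all(ft$q_time[ok] < ft$b_time[ok]))
  expect_true(all(ft$b_time[ok] < ft$x_time[ok]))
})

test_that("beats with truncated search windows are invalid", {
  sig <- rendered_trial("noiseless", noise = noiseless())
  # append a fake R time just before the end of the trace
  r_edge <- (length(sig$ecg$data) - 2) / sig$ecg$fs
  ft <- locate_fiducials(sig$ecg$data, sig$dzdt$data,
                         c(10.0, r_edge), sig$ecg$fs)
  expect_false(ft$valid[2])
})

test_that("ensemble averaging matches sliding-window expectations", {
  fs <- 250
  prof <- flat_profiles()
  beats <- simulate_beat_timeline(prof, p, seed = 21)
  # alternate PEP 70/90 ms across beats
  beats$pep_ms <- ifelse(seq_len(nrow(beats)) %% 2 == 0, 70, 90)
  sig <- render_trial(beats, prof, p, noise = noiseless(), blink_rate = 0,
                      seed = 22)
  ens <- moving_ensemble(sig$ecg$data, sig$dzdt$data, sig$truth$r_time,
                         fs, p)
  mid <- ens$mask & ens$t > 20 & ens$t < 180
  expect_true(any(mid))
  expect_equal(mean(ens$pep_ms[mid]), 80, tolerance = 3)
  # identical beats reproduce the single-beat fiducials
  sig2 <- rendered_trial("noiseless", noise = noiseless())
  ens2 <- moving_ensemble(sig2$ecg$data, sig2$dzdt$data, sig2$truth$r_time,
                          fs, p)
  ok <- ens2$mask & ens2$t > 20 & ens2$t < 180
  expect_lt(max(abs(ens2$pep_ms[ok] - 80)), 1000 / fs + 1e-9)
  expect_lt(max(abs(ens2$lvet_ms[ok] - 290)), 1000 / fs + 1e-9)
  # abrupt step: ensemble is intermediate and monotone across the step
  beats3 <- simulate_beat_timeline(prof, p, seed = 23)
  beats3$pep_ms <- ifelse(beats3$r_time < 100, 70, 90)
  sig3 <- render_trial(beats3, prof, p, noise = noiseless(), blink_rate = 0,
                       seed = 24)
  ens3 <- moving_ensemble(sig3$ecg$data, sig3$dzdt$data, sig3$truth$r_time,
                          fs, p)
  ramp <- ens3$pep_ms[ens3$t >= 92 & ens3$t <= 108]
  expect_true(all(diff(ramp[!is.na(ramp)]) >= -1000 / fs))
  expect_lt(ens3$pep_ms[ens3$t == 80], 75)
  expect_gt(ens3$pep_ms[ens3$t == 120], 85)
})

test_that("Kubicek stroke volume and cardiac output identities hold", {
  sig <- rendered_trial("noiseless", noise = noiseless())
  fs <- sig$ecg$fs
  r <- detect_r_peaks(sig$ecg$data, fs)
  ft <- locate_fiducials(sig$ecg$data, sig$dzdt$data, r, fs)
  bm <- beat_measures(ft, sig$dzdt$data, sig$z0$data, fs)
  ok <- which(bm$valid & is.finite(bm$co_lmin))
  expect_equal(bm$co_lmin[ok], bm$hr[ok] * bm$sv_ml[ok] / 1000)
  idx <- match_truth(bm$r_time[ok], sig$truth)
  expect_lt(median(abs(bm$sv_ml[ok] - sig$truth$sv_ml[idx])), 1)
  # doubling max dZ/dt doubles SV
  bm2 <- beat_measures(ft, 2 * sig$dzdt$data, sig$z0$data, fs)
  expect_equal(bm2$sv_ml[ok] / bm$sv_ml[ok], rep(2, length(ok)),
               tolerance = 1e-6)
})

test_that("pressure measures follow the MAP and TPR formulas", {
  expect_equal(60 + (120 - 60) / 3, 80)  # MAP formula sanity
  sig <- rendered_trial("noiseless", noise = noiseless())
  co_flat <- continuous_measure(rep(2, 195), measure = "CO")
  pm <- pressure_measures(sig$bp$data, sig$bp$fs, p, co_series = co_flat)
  mid <- pm$map$mask & time_grid(p) > 10 & time_grid(p) < 190
  expect_equal(mean(pm$map$values[mid]), 80, tolerance = 1)
  expect_equal(pm$tpr$values[mid], 80 * pm$map$values[mid] / 2,
               tolerance = 1e-9)
  expect_equal(mean(pm$tpr$values[mid]), 3200, tolerance = 50)
  expect_true(all(pm$beats$dbp < pm$beats$map & pm$beats$map < pm$beats$sbp,
                  na.rm = TRUE))
})

test_that("respiration estimation recovers phase and magnitude", {
  fs <- 250
  t <- (0:(200 * fs - 1)) / fs
  z0 <- 25 + 0.2 * sin(2 * pi * 0.25 * t)
  resp <- estimate_respiration(z0, fs, r_times = seq(40, 160, by = 1))
  ph <- resp$phase[round(seq(50, 100, by = 4) * fs)]
  wrapped <- ((diff(ph) + pi) %% (2 * pi)) - pi   # 2*pi advance per 4 s
  expect_lt(max(abs(wrapped)), 0.1)
  st <- resp$state$state
  expect_equal(mean(st), 0, tolerance = 1e-9)
  expect_equal(stats::sd(st), 1, tolerance = 1e-9)
  resp2 <- estimate_respiration(25 + 0.4 * sin(2 * pi * 0.25 * t), fs,
                                r_times = seq(40, 160, by = 1))
  mid <- round(seq(60, 140) * fs)
  expect_equal(mean(resp2$magnitude[mid]) / mean(resp$magnitude[mid]), 2,
               tolerance = 0.05)
  expect_warning(estimate_respiration(rep(25, 200 * fs), fs,
                                      r_times = c(50, 60)), "degenerate")
})

test_that("respiration correction removes linear leakage exactly", {
  set.seed(4)
  state <- as.vector(scale(rnorm(100)))   # z-scored, like respiratory state
  series <- 2 * state + 5
  expect_equal(respiration_correct(series, state), rep(5, 100),
               tolerance = 1e-9)
  noise <- rnorm(100)
  leaky <- noise + 1.7 * state
  corr <- respiration_correct(leaky, state)
  expect_lt(abs(stats::cor(corr, state)), 1e-9)
  expect_warning(out <- respiration_correct(series, rep(1, 100)),
                 "constant")
  expect_identical(out, series)
})

test_that("1-Hz resampling honors the grid contract", {
  y <- resample_1hz(c(0, 194), c(0, 194), p)
  expect_length(y$values, 195)
  expect_equal(y$values, 0:194)  # linear ramp reproduced exactly
  ident <- resample_1hz(0:194, sin(0:194), p)
  expect_equal(ident$values, sin(0:194))
  few <- resample_1hz(c(10), c(1), p)
  expect_true(all(!few$mask))
  part <- resample_1hz(c(50, 100), c(1, 2), p)
  expect_false(any(part$mask[1:49]))   # no extrapolation
  expect_true(all(part$mask[51:100]))
})
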