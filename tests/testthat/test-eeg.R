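p <- make_default_protocol()

clean_montage_data <- function(fs = 250, dur = 60, seed = 41) {
  set.seed(seed)
  chn <- default_eeg_channels()
  n <- fs * dur
  t <- (0:(n - 1)) / fs
  common <- 5 * sin(2 * pi * 10 * t) + 3 * sin(2 * pi * 5.5 * t) +
    4 * sin(2 * pi * 2 * t)
  d <- matrix(0, length(chn), n, dimnames = list(chn, NULL))
  for (i in seq_along(chn))
    d[i, ] <- common * runif(1, 0.8, 1.2) + rnorm(n, 0, 1.5)
  d
}

test_that("bad-channel rules fire on constructed defects only", {
  d <- clean_montage_data()
  expect_length(detect_bad_channels(d, 250), 0)
  # (a) flatline for 6 s
  d1 <- d; d1["P3", 1001:(1000 + 6 * 250)] <- 0.77
  bad1 <- detect_bad_channels(d1, 250)
  expect_true("P3" %in% bad1)
  # (b) amplitude scaled x10
  d2 <- d; d2["F4", ] <- d2["F4", ] * 10
  expect_true("F4" %in% detect_bad_channels(d2, 250))
  sds <- apply(d2, 1, sd)            # direct population-SD oracle
  expect_true(sds["F4"] > 4 * median(sds))
  # (c) uncorrelated channel
  d3 <- d; d3["Oz", ] <- rnorm(ncol(d), 0, 5)
  expect_true("Oz" %in% detect_bad_channels(d3, 250))
  # determinism
  expect_identical(detect_bad_channels(d3, 250),
                   detect_bad_channels(d3, 250))
  expect_error(detect_bad_channels(d[1:4, ], 250), "8 channels")
})

test_that("average reference and spherical interpolation behave", {
  d <- clean_montage_data()
  out <- rereference_interpolate(d, bad = character(0))
  expect_lt(max(abs(colMeans(out))), 1e-9)
  # bad channel amid a uniform field is restored to the field
  du <- matrix(2.5, nrow(d), ncol(d), dimnames = dimnames(d))
  du["Cz", ] <- 99
  fixed <- rereference_interpolate(du, bad = "Cz")
  # after average referencing the field is 0 everywhere; Cz interpolates to 0
  expect_lt(max(abs(fixed["Cz", ] - mean(fixed[rownames(d) != "Cz", 1]))),
            1e-6)
  # leave-one-out on a smooth spatial gradient
  mont <- default_montage()
  grad <- outer(mont$y + 0.5 * mont$z, rep(1, 100))
  rownames(grad) <- mont$name
  est <- rereference_interpolate(grad, bad = "C3", montage = mont)
  truth <- rereference_interpolate(grad, bad = character(0), montage = mont)
  expect_lt(mean(abs(est["C3", ] - truth["C3", ])), 0.1)
  expect_error(rereference_interpolate(d, bad = rownames(d)[1:12]),
               "rejected")
})

test_that("ERSP concentrates power and self-normalizes", {
  fs <- 250
  n <- 195 * fs
  x <- matrix(3 * sin(2 * pi * 10 * (0:(n - 1)) / fs), 1,
              dimnames = list("Cz", NULL))
  er <- compute_ersp(x, fs, p, smooth_bins = 1)
  pw <- rowMeans(er$raw[1, , 1:195])
  inband <- pw["10"]
  outband <- mean(pw[setdiff(as.character(1:30), c("9", "10", "11"))])
  expect_gt(10 * log10(inband / outband), 20)
  expect_equal(unname(inband), 9 / 2, tolerance = 0.01)  # amp 3 -> 4.5
  # stationary signal: dB variant ~ 0 everywhere
  expect_lt(max(abs(er$db[1, "10", 41:195])), 0.01)
  # amplitude doubled during immersion only: ~ +6 dB there, ~0 elsewhere
  x2 <- x
  imm <- (65 * fs + 1):(155 * fs)
  x2[1, imm] <- 2 * x2[1, imm]
  er2 <- compute_ersp(x2, fs, p, smooth_bins = 1)
  expect_equal(mean(er2$db[1, "10", 67:154]), 10 * log10(4),
               tolerance = 0.2)
  expect_lt(max(abs(er2$db[1, "10", c(2:40, 170:195)])), 0.5)
})

test_that("band/period reduction uses the published definitions", {
  bands <- eeg_bands()
  expect_length(bands$alpha, 7)        # 8-14 Hz inclusive
  expect_equal(bands$delta, 1:3)
  expect_equal(bands$beta, 15:30)
  periods <- eeg_periods()
  expect_length(periods$early, 30)     # 65-94 s
  expect_equal(range(periods$recovery), c(155, 190))
  # constant grid reduces to the constant (in raw-log dB for baseline)
  er <- list(raw = array(4, c(2, 30, 195),
                         dimnames = list(c("Cz", "Pz"), 1:30, NULL)),
             db = array(1.5, c(2, 30, 195),
                        dimnames = list(c("Cz", "Pz"), 1:30, NULL)),
             freqs = 1:30, channels = c("Cz", "Pz"))
  class(er) <- "ersp_grid"
  red <- reduce_band_period(er)
  expect_equal(unique(red$value[red$period != "baseline"]), 1.5)
  expect_equal(unique(red$value[red$period == "baseline"]),
               10 * log10(4), tolerance = 1e-9)
})

test_that("prefilter removes drift and line noise", {
  fs <- 250
  t <- (0:(fs * 20 - 1)) / fs
  x <- matrix(0.5 * sin(2 * pi * 0.1 * t) + sin(2 * pi * 10 * t) +
                2 * sin(2 * pi * 60 * t), 1, dimnames = list("Cz", NULL))
  y <- eeg_prefilter(x, fs)
  pw <- function(sig, f) {
    X <- abs(fft(sig[1, ]))^2
    X[round(f * length(t) / fs) + 1]
  }
  expect_lt(pw(y, 0.1) / pw(x, 0.1), 0.01)
  expect_lt(pw(y, 60) / pw(x, 60), 1e-6)
  expect_gt(pw(y, 10) / pw(x, 10), 0.95)
})
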