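p <- make_default_protocol()

test_that("beat timeline follows the HR profile", {
  prof <- flat_profiles(hr = 60, hf = -Inf)
  prof$hf <- NULL
  bt <- simulate_beat_timeline(prof, p, seed = 1)
  expect_true(all(abs(bt$rr[-1] - 1) < 1e-9))  # constant HR=60, no noise

  # step 60 -> 90 at immersion: RR ratio across epochs ~ 60/90
  prof2 <- flat_profiles(hr = 60)
  prof2$hf <- NULL
  prof2$hr[66:155] <- 90
  bt2 <- simulate_beat_timeline(prof2, p, seed = 1)
  rr_base <- bt2$rr[bt2$r_time < 60 & !is.na(bt2$rr)]
  rr_imm <- bt2$rr[bt2$r_time > 70 & bt2$r_time < 150]
  expect_equal(mean(rr_imm) / mean(rr_base), 60 / 90, tolerance = 0.03)
  expect_error(simulate_beat_timeline(list(hr = rep(-5, 195)), p),
               "positive")
})

test_that("beat timeline and study generation are deterministic", {
  prof <- flat_profiles()
  b1 <- simulate_beat_timeline(prof, p, rr_jitter_sd = 0.01, seed = 7)
  b2 <- simulate_beat_timeline(prof, p, rr_jitter_sd = 0.01, seed = 7)
  expect_identical(b1, b2)
  s1 <- simulate_study(3, seed = 9)
  s2 <- simulate_study(3, seed = 9)
  expect_identical(s1$panels$HR$values, s2$panels$HR$values)
  expect_identical(s1$pain, s2$pain)
})

test_that("rendered landmarks sit where the truth says", {
  sig <- rendered_trial("noiseless", noise = noiseless())
  tr <- sig$truth
  fs <- sig$dzdt$fs
  # B point: slope-change onset at q_time + PEP; check rendered second
  # difference peaks within one sample of truth for a few beats
  d2 <- stressmux:::second_diff(sig$dzdt$data, h = 3)
  for (k in c(10, 50, 100)) {
    ri <- round(tr$r_time[k] * fs) + 1
    pk <- ri + which.max(sig$dzdt$data[(ri + 1):(ri + 80)])
    bi <- (ri + 1):(pk - 1)
    b_est <- (bi[which.max(d2[bi])] - 1) / fs
    expect_lt(abs(b_est - tr$b_time[k]), 1.5 / fs)
  }
  # pupil with blink rate 0 has no missing samples
  expect_false(anyNA(sig$pupil$left))
  expect_false(anyNA(sig$pupil$right))
})

test_that("doubling an oscillator amplitude quadruples its band power", {
  prof <- flat_profiles()
  spec1 <- default_eeg_spec(null = TRUE)
  spec2 <- default_eeg_spec(null = TRUE)
  spec2$alpha$base <- 2 * spec1$alpha$base
  b <- simulate_beat_timeline(prof, p, seed = 3)
  s1 <- render_trial(b, prof, p, eeg_spec = spec1, blink_rate = 0, seed = 4)
  s2 <- render_trial(b, prof, p, eeg_spec = spec2, blink_rate = 0, seed = 4)
  pow10 <- function(sig) {
    x <- sig$eeg$data["Cz", ]
    sp <- stats::spec.pgram(stats::ts(x, frequency = sig$eeg$fs),
                            taper = 0, plot = FALSE, span = 5)
    mean(sp$spec[abs(sp$freq - 10) < 0.3])
  }
  expect_equal(pow10(s2) / pow10(s1), 4, tolerance = 0.25)
})

test_that("study bookkeeping and habituation structure are correct", {
  st <- simulate_study(8, seed = 2)
  expect_equal(dim(st$panels$HR$values), c(8, 2, 5, 195))
  expect_equal(dim(st$truth$profiles$HR), c(8, 2, 5, 195))
  expect_equal(dim(st$pain), c(8, 2, 5))
  expect_true(all(st$pain >= 0 & st$pain <= 100))
  expect_true(all(st$cortisol > 0))
  expect_setequal(unique(st$subjects$start_time), c("AM", "PM"))
  expect_setequal(unique(st$subjects$condition_order),
                  c("treatment_first", "control_first"))
  # T1 vs T5 true evoked delta ratio = h^4 during immersion
  spec <- st$spec$HR
  tp <- st$truth$profiles$HR
  d1 <- tp[1, "treatment", "T1", 120] - tp[1, "control", "T1", 120]
  d5 <- tp[1, "treatment", "T5", 120] - tp[1, "control", "T5", 120]
  # session offsets differ between conditions; compare within treatment
  # against trial-1 evoked size instead
  e1 <- tp[1, "treatment", "T1", 120] - tp[1, "treatment", "T1", 30]
  e5 <- tp[1, "treatment", "T5", 120] - tp[1, "treatment", "T5", 30]
  ant1 <- spec$anticipatory_delta * spec$h_anticipatory^0
  ant5 <- spec$anticipatory_delta * spec$h_anticipatory^4
  expect_equal((e5 + ant5) / (e1 + ant1), spec$h_evoked^4, tolerance = 1e-8)
})

test_that("null configuration removes all deltas", {
  sp <- null_effect_specs()
  for (m in names(sp)) {
    expect_equal(sp[[m]]$anticipatory_delta, 0)
    expect_equal(sp[[m]]$evoked_delta, 0)
    expect_equal(sp[[m]]$h_evoked, 1)
  }
  st <- simulate_study(4, sp, seed = 5)
  tp <- st$truth$profiles$HR
  # truth profiles are flat within any subject x condition x trial
  expect_equal(stats::sd(tp[2, "treatment", "T3", ]), 0)
})

test_that("session CSV round-trip preserves channel data", {
  st <- simulate_study(2, seed = 12, render = TRUE, fs = 100, fs_eeg = 100,
                       fs_pupil = 100)
  dir <- tempfile(); dir.create(dir)
  write_session_csv(st$sessions[[1]][["control"]], dir)
  f <- file.path(dir, "s01_control_T1_ecg.csv")
  expect_true(file.exists(f))
  df <- read.csv(f)
  expect_equal(df$value, st$sessions[[1]][["control"]]$trials[[1]]$ecg$data)
  unlink(dir, recursive = TRUE)
})
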