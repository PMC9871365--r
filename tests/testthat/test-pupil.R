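p <- make_default_protocol()

mk_trace <- function(left, right, fs = 100) {
  n <- 195 * fs
  data.frame(t = (0:(n - 1)) / fs,
             left = rep_len(left, n), right = rep_len(right, n))
}

test_that("binocular averaging and fallback to one eye", {
  out <- preprocess_pupil(mk_trace(3, 3), p)
  expect_length(out$values, 195)
  expect_equal(out$values, rep(3, 195))
  one_eye <- mk_trace(NA_real_, 4.2)
  out2 <- preprocess_pupil(one_eye, p)
  expect_equal(out2$values, rep(4.2, 195))
})

test_that("smoothing a step yields a 5-s ramp (visualization only)", {
  fs <- 100
  tr <- mk_trace(2, 2, fs)
  step_idx <- tr$t >= 100
  tr$left[step_idx] <- 5; tr$right[step_idx] <- 5
  sm <- preprocess_pupil(tr, p, smooth = TRUE)
  raw <- preprocess_pupil(tr, p)
  # oracle: centered 5-s moving average of the unsmoothed series
  expect_equal(sm$values, moving_average(raw$values, 5), tolerance = 1e-9)
  ramp <- which(sm$values > 2 + 1e-6 & sm$values < 5 - 1e-6)
  expect_lte(length(ramp), 5)
  expect_gte(length(ramp), 3)
  expect_true(isTRUE(attr(sm, "smoothed")))
})

test_that("gaps are bridged only up to the interpolation limit", {
  fs <- 100
  tr <- mk_trace(3, 3, fs)
  short_gap <- tr$t >= 50 & tr$t < 50.5       # 0.5 s: bridged
  long_gap <- tr$t >= 80 & tr$t < 83          # 3 s: stays missing
  tr$left[short_gap | long_gap] <- NA
  tr$right[short_gap | long_gap] <- NA
  out <- preprocess_pupil(tr, p)
  expect_true(out$mask[51])
  expect_false(all(out$mask[81:83]))
})

test_that("subject rejection respects the per-trial threshold", {
  mf <- array(0, c(3, 2, 5),
              dimnames = list(c("s1", "s2", "s3"),
                              c("treatment", "control"), paste0("T", 1:5)))
  mf["s2", "control", 4] <- 1        # one fully failed trial
  res <- reject_pupil_subjects(mf)
  expect_equal(res$excluded, "s2")
  expect_setequal(res$retained, c("s1", "s3"))
  res_all <- reject_pupil_subjects(array(0, c(3, 2, 5),
                                         dimnames = dimnames(mf)))
  expect_length(res_all$excluded, 0)
  mf["s3", "treatment", 1] <- 0.6
  res_thr <- reject_pupil_subjects(mf, threshold = 0.5)
  expect_setequal(res_thr$excluded, c("s2", "s3"))
})

test_that("0-1 normalization is per subject, order preserving, idempotent", {
  v <- array(NA_real_, c(2, 2, 5, 195),
             dimnames = list(c("a", "b"), c("treatment", "control"),
                             paste0("T", 1:5), NULL))
  v["a", , , ] <- seq(2, 6, length.out = 2 * 5 * 195)
  v["b", , , ] <- seq(-10, 30, length.out = 2 * 5 * 195)
  pan <- measure_panel(v, measure = "PUPIL")
  nm <- normalize_01(pan)
  for (s in c("a", "b")) {
    rng <- range(nm$values[s, , , ])
    expect_equal(rng, c(0, 1))
  }
  # value 4 for subject a (range 2..6) maps to 0.5
  idx <- which.min(abs(v["a", , , ] - 4))
  expect_equal(as.vector(nm$values["a", , , ])[idx], 0.5, tolerance = 1e-3)
  # monotone transform preserves ordering
  o1 <- order(v["a", 1, 1, ]); o2 <- order(nm$values["a", 1, 1, ])
  expect_equal(o1, o2)
  # idempotent
  nm2 <- normalize_01(nm)
  expect_equal(nm2$values, nm$values, tolerance = 1e-12)
  # constant data warns and maps to 0.5
  vc <- v; vc["a", , , ] <- 7
  expect_warning(nc <- normalize_01(measure_panel(vc)), "constant")
  expect_true(all(nc$values["a", , , ] == 0.5))
})

test_that("statistics path refuses smoothed panels", {
  st <- simulate_study(4, null_effect_specs(), seed = 31)
  pan <- st$panels$PUPIL
  attr(pan, "smoothed") <- TRUE
  expect_error(pointwise_framework(pan, p, n_perm = 100), "smoothed")
})
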