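p <- make_default_protocol()

test_that("pain analysis finds the generated habituating treatment effect", {
  st <- simulate_study(16, default_effect_specs(), seed = 71)
  res <- scalar_condition_trial(st$pain, n_perm = 500, seed = 2)
  a <- res$anova
  expect_true(a$flagged[a$effect == "condition"])
  expect_true(a$flagged[a$effect == "interaction"])
  expect_false(is.null(res$contrasts))
  tc <- res$contrasts[res$contrasts$condition == "treatment", ]
  expect_true(tc$flagged[tc$pair == "T1vT5"])
  expect_true(tc$flagged[tc$pair == "T3vT5"])
})

test_that("degenerate-variance conditions are skipped in contrasts", {
  y <- array(0, c(6, 2, 5),
             dimnames = list(paste0("s", 1:6),
                             c("treatment", "control"), paste0("T", 1:5)))
  set.seed(3)
  y[, 1, ] <- rnorm(30, 50, 5) * rep(0.85^(0:4), each = 6)
  res <- scalar_condition_trial(y, n_perm = 300, seed = 4)
  if (!is.null(res$contrasts))
    expect_false(any(res$contrasts$condition == "control"))
})

test_that("cortisol mixed ANOVA flags the declining trend only", {
  st <- simulate_study(12, default_effect_specs(), seed = 72)
  res <- cortisol_mixed_anova(st$cortisol, st$subjects$start_time,
                              n_perm = 300, seed = 5)
  expect_true(res$flagged[res$effect == "sample"])
  expect_false(res$flagged[res$effect == "condition:sample"])
})

test_that("EEG electrode analysis localizes an injected interaction", {
  set.seed(73)
  chn <- default_eeg_channels()
  target <- c("Fp1", "Fp2", "F3", "F4", "Fz", "F7")
  rows <- list()
  for (s in paste0("s", 1:10)) for (cond in c("treatment", "control"))
    for (tr in 1:5) for (ch in chn) {
      base <- rnorm(1, 0, 0.4)
      eff <- if (cond == "treatment" && ch %in% target)
        3 * 0.6^(tr - 1) else 0
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, condition = cond, trial = paste0("T", tr),
        channel = ch, band = "alpha", period = "early",
        value = base + eff)
    }
  band_df <- do.call(rbind, rows)
  res <- eeg_scalar_analysis(band_df, n_perm = 300, seed = 6)
  el <- res$electrode
  inter <- el[el$effect == "interaction", ]
  hit <- inter$channel[inter$flagged]
  expect_gte(length(intersect(hit, target)), 5)
  expect_lte(length(setdiff(hit, target)), 2)
  expect_false(is.null(res$followup))
  expect_true(any(res$followup$flagged[res$followup$pair == "T1vT5"]))
})

test_that("scalar_analyses bundles all study-level results", {
  st <- simulate_study(8, default_effect_specs(), seed = 74)
  res <- scalar_analyses(st, n_perm = 200, seed = 7)
  expect_named(res, c("pain", "pupil", "cortisol"), ignore.order = TRUE)
  expect_s3_class(res$pain$anova, "data.frame")
  expect_s3_class(res$cortisol, "data.frame")
  # pupil condition effect present at the generator defaults
  pa <- res$pupil$anova
  expect_true(pa$flagged[pa$effect == "condition"])
})
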