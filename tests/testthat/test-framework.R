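p <- make_default_protocol()

test_that("baseline correction subtracts the final-15-s baseline mean", {
  st <- simulate_study(4, null_effect_specs(), seed = 51)
  pan <- st$panels$HR
  # flat trial: corrected values have near-zero baseline-window mean
  cor <- baseline_correct(pan, p)
  for (i in 1:2) {
    w <- cor$values[i, 1, 1, 26:40]
    expect_equal(mean(w), 0, tolerance = 1e-9)
  }
  # step of +10 at immersion: corrected = 0 before, +10 after
  v <- array(5, c(3, 2, 5, 195),
             dimnames = list(paste0("s", 1:3), c("treatment", "control"),
                             paste0("T", 1:5), NULL))
  v[, , , 66:195] <- 15
  stepc <- baseline_correct(measure_panel(v), p)
  expect_equal(unique(as.vector(stepc$values[, , , 1:65])), 0)
  expect_equal(unique(as.vector(stepc$values[, , , 66:195])), 10)
  # generator with known evoked delta, no noise: corrected immersion = delta
  spec <- default_effect_specs()
  prof <- truth_profile(spec$HR, p, trial = 1, condition = "treatment")
  v2 <- array(rep(prof, each = 3 * 2 * 5), c(3, 2, 5, 195),
              dimnames = dimnames(v))
  c2 <- baseline_correct(measure_panel(v2), p)
  expect_equal(c2$values[1, 1, 1, 121],
               spec$HR$evoked_delta - spec$HR$anticipatory_delta,
               tolerance = 1e-9)
  # fully masked baseline window masks the trial
  v3 <- v; v3[1, 1, 2, 26:40] <- NA
  c3 <- baseline_correct(measure_panel(v3), p)
  expect_true(all(!c3$mask[1, 1, 2, ]))
  expect_true(all(c3$mask[1, 1, 1, ]))
})

test_that("pointwise framework scope, gating and determinism", {
  st <- simulate_study(8, default_effect_specs(), seed = 52)
  tr <- pointwise_framework(st$panels$HR, p, "corrected", n_perm = 200,
                            seed = 3)
  # scope: corrected analysis covers 65 s onward only
  expect_true(all(is.na(tr$tracks$condition[1:65])))
  expect_true(all(!is.na(tr$tracks$condition[66:195])))
  raw <- pointwise_framework(st$panels$HR, p, "raw", n_perm = 200, seed = 3)
  expect_true(all(!is.na(raw$tracks$condition[1:65])))
  expect_true(all(is.na(raw$tracks$condition[66:195])))
  # gating law: pairwise flags only where the interaction flag is set
  for (cd in names(tr$contrast_tracks)) {
    for (cp in names(tr$contrast_tracks[[cd]])) {
      flags <- tr$contrast_tracks[[cd]][[cp]]
      expect_true(all(tr$tracks$interaction[which(flags)] %in% TRUE))
    }
  }
  # determinism
  tr2 <- pointwise_framework(st$panels$HR, p, "corrected", n_perm = 200,
                             seed = 3)
  expect_identical(tr$results, tr2$results)
})

test_that("masked subjects drop listwise; over-masked timepoints drop", {
  st <- simulate_study(4, null_effect_specs(), seed = 53)
  pan <- st$panels$HR
  pan$values[1, 1, 1, 100] <- NA; pan$mask[1, 1, 1, 100] <- FALSE
  pan$values[1:2, 1, 1, 101] <- NA; pan$mask[1:2, 1, 1, 101] <- FALSE
  tr <- pointwise_framework(pan, p, "corrected", n_perm = 100, seed = 4,
                            effects = "condition", gated = FALSE)
  # grid t=99 (index 100): 1 of 4 subjects masked (25%) -> analyzed on n=3
  expect_false(is.na(tr$tracks$condition[100]))
  # grid t=100 (index 101): 2 of 4 masked (50% > 25%) -> excluded
  expect_true(is.na(tr$tracks$condition[101]))
})

test_that("contiguity filter clears short runs only", {
  flags <- c(NA, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  out <- stressmux:::clear_short_runs(flags, min_run = 2)
  expect_identical(out, c(NA, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("baseline-shift ANOVA distinguishes shared from differential shifts", {
  nsub <- 8
  dn <- list(paste0("s", 1:nsub), c("treatment", "control"),
             paste0("T", 1:5), NULL)
  mk <- function(shift_treat, shift_ctrl) {
    set.seed(60)
    v <- array(rnorm(nsub * 2 * 5 * 195, 50, 1.5), c(nsub, 2, 5, 195),
               dimnames = dn)
    v[, 1, , 66:155] <- v[, 1, , 66:155] + shift_treat
    v[, 2, , 66:155] <- v[, 2, , 66:155] + shift_ctrl
    measure_panel(v)
  }
  rng <- 80:95  # sub-range for test runtime
  # equal shift in both conditions: baseline main effect, not baseline:condition
  eq <- baseline_shift_anova(mk(8, 8), p, n_perm = 200, seed = 6,
                             range_s = rng)
  b_rate <- mean(eq$tracks$baseline[rng + 1], na.rm = TRUE)
  bc_rate <- mean(eq$tracks[["baseline:condition"]][rng + 1], na.rm = TRUE)
  expect_gt(b_rate, 0.9)
  expect_lt(bc_rate, 0.3)
  # treatment-only shift: baseline:condition flagged
  tr_only <- baseline_shift_anova(mk(8, 0), p, n_perm = 200, seed = 6,
                                  range_s = rng)
  expect_gt(mean(tr_only$tracks[["baseline:condition"]][rng + 1],
                 na.rm = TRUE), 0.9)
  # no shift at all: baseline effect at chance-ish rate
  none <- baseline_shift_anova(mk(0, 0), p, n_perm = 200, seed = 6,
                               range_s = rng)
  expect_lt(mean(none$tracks$baseline[rng + 1], na.rm = TRUE), 0.3)
})
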