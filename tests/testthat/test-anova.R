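test_that("rm_anova_2way matches the brute-force oracle on random tables", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    y <- array(rnorm(n * 2 * 5, sd = runif(1, 0.5, 3)), c(n, 2, 5))
    fit <- rm_anova_2way(y)
    ref <- oracle_2way(y)
    expect_lt(max(abs(fit$F - ref) / pmax(abs(ref), 1e-12)), 1e-10)
    expect_true(all(fit$eta_p_sq >= 0 & fit$eta_p_sq <= 1))
  }
})

test_that("rm_anova_2way matches aov and handles degenerate inputs", {
  set.seed(5)
  n <- 6
  y <- array(rnorm(n * 2 * 5), c(n, 2, 5))
  df <- data.frame(y = as.vector(y), s = factor(rep(1:n, 10)),
                   c = factor(rep(rep(1:2, each = n), 5)),
                   t = factor(rep(1:5, each = 2 * n)))
  a <- summary(aov(y ~ c * t + Error(s / (c * t)), data = df))
  expect_equal(rm_anova_2way(y)$F,
               c(a[["Error: s:c"]][[1]]["c", "F value"],
                 a[["Error: s:t"]][[1]]["t", "F value"],
                 a[["Error: s:c:t"]][[1]]["c:t", "F value"]),
               tolerance = 1e-10)
  # all identical -> all F = 0
  expect_equal(rm_anova_2way(array(2, c(4, 2, 5)))$F, c(0, 0, 0))
  # pure condition shift, no noise: F_condition = Inf flag, F_trial = 0
  y0 <- array(0, c(4, 2, 5)); y0[, 1, ] <- 1
  fit0 <- rm_anova_2way(y0)
  expect_equal(fit0$F, c(Inf, 0, 0))
  expect_error(rm_anova_2way(array(0, c(2, 2, 5))), "3 subjects")
})

test_that("three-way and split-plot decompositions match aov", {
  set.seed(6)
  n <- 5
  y3 <- array(rnorm(n * 2 * 2 * 5), c(n, 2, 2, 5))
  fit3 <- rm_anova_3way(y3)
  df3 <- data.frame(y = as.vector(y3), s = factor(rep(1:n, 20)),
                    b = factor(rep(rep(1:2, each = n), 10)),
                    c = factor(rep(rep(1:2, each = 2 * n), 5)),
                    t = factor(rep(1:5, each = 4 * n)))
  a3 <- summary(aov(y ~ b * c * t + Error(s / (b * c * t)), data = df3))
  ref <- c(a3[["Error: s:b"]][[1]]["b", "F value"],
           a3[["Error: s:c"]][[1]]["c", "F value"],
           a3[["Error: s:t"]][[1]]["t", "F value"],
           a3[["Error: s:b:c"]][[1]]["b:c", "F value"],
           a3[["Error: s:b:t"]][[1]]["b:t", "F value"],
           a3[["Error: s:c:t"]][[1]]["c:t", "F value"],
           a3[["Error: s:b:c:t"]][[1]]["b:c:t", "F value"])
  ord <- c("baseline", "condition", "trial", "baseline:condition",
           "baseline:trial", "condition:trial",
           "baseline:condition:trial")
  expect_equal(fit3$F[match(ord, fit3$effect)], ref, tolerance = 1e-10)

  grp <- rep(c("AM", "PM"), length.out = 8)
  ys <- array(rnorm(8 * 2 * 3), c(8, 2, 3))
  fs <- anova_split_plot(ys, grp)
  dfs <- data.frame(y = as.vector(ys), s = factor(rep(1:8, 6)),
                    g = factor(rep(grp, 6)),
                    c = factor(rep(rep(1:2, each = 8), 3)),
                    smp = factor(rep(1:3, each = 16)))
  asp <- summary(aov(y ~ g * c * smp + Error(s / (c * smp)), data = dfs))
  refs <- c(asp[["Error: s"]][[1]]["g", "F value"],
            asp[["Error: s:c"]][[1]]["c", "F value"],
            asp[["Error: s:c"]][[1]]["g:c", "F value"],
            asp[["Error: s:smp"]][[1]]["smp", "F value"],
            asp[["Error: s:smp"]][[1]]["g:smp", "F value"],
            asp[["Error: s:c:smp"]][[1]]["c:smp", "F value"],
            asp[["Error: s:c:smp"]][[1]]["g:c:smp", "F value"])
  expect_equal(fs$F, refs, tolerance = 1e-10)
})

test_that("vectorized sign-flip F formulas reproduce the observed F", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    y <- array(rnorm(n * 2 * 5), c(n, 2, 5))
    S1 <- matrix(1, 1, n)
    fit <- rm_anova_2way(y)
    expect_equal(stressmux:::perm_F_condition(y, S1),
                 fit$F[fit$effect == "condition"], tolerance = 1e-10)
    expect_equal(stressmux:::perm_F_interaction(y, S1),
                 fit$F[fit$effect == "interaction"], tolerance = 1e-10)
  }
  # 3-way closed forms
  y3 <- array(rnorm(6 * 2 * 2 * 5), c(6, 2, 2, 5))
  fit3 <- rm_anova_3way(y3)
  Q5 <- stressmux:::ortho_contrasts(5)
  S1 <- matrix(1, 1, 6)
  for (e in c("baseline", "condition", "baseline:condition",
              "condition:trial", "baseline:trial",
              "baseline:condition:trial")) {
    expect_equal(stressmux:::baseline3_null(y3, e, S1, 1, Q5),
                 fit3$F[fit3$effect == e], tolerance = 1e-10,
                 label = e)
  }
})
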