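#' Baseline-correct a measure panel
#'
#' Subtracts, per subject x condition x trial, the mean over the final
#' `window_s` seconds of the baseline epoch (grid times `[40 - window_s, 40)`
#' under the default protocol) from every timepoint of that trial. Trials
#' whose baseline window is fully masked become fully masked.
#'
#' @param panel a `measure_panel`.
#' @param protocol a `protocol_definition`.
#' @param window_s baseline window, seconds (default 15).
#' @return the corrected `measure_panel`.
#' @export
baseline_correct <- function(panel, protocol = make_default_protocol(),
                             window_s = 15) {
  iv <- epoch_interval(protocol, "baseline")
  if (iv["end"] - iv["start"] < window_s)
    stop("baseline epoch shorter than window_s")
  idx <- which(time_grid(protocol) >= iv["end"] - window_s &
                 time_grid(protocol) < iv["end"])
  v <- panel$values
  m <- panel$mask
  d <- dim(v)
  for (i in seq_len(d[1])) for (ci in seq_len(d[2])) for (tr in seq_len(d[3])) {
    w <- v[i, ci, tr, idx]
    if (all(is.na(w))) {
      m[i, ci, tr, ] <- FALSE
      v[i, ci, tr, ] <- NA_real_
    } else {
      v[i, ci, tr, ] <- v[i, ci, tr, ] - mean(w, na.rm = TRUE)
    }
  }
  out <- measure_panel(v, m, panel$measure, panel$units)
  attr(out, "baseline_corrected") <- TRUE
  out
}

#' Pointwise permutation ANOVA framework
#'
#' At every in-scope timepoint, runs the condition x trial repeated-measures
#' ANOVA with permutation-null p-values and, where the interaction is
#' significant, within-condition interaction-gated paired contrasts T1 vs T5
#' (whole-session habituation), T1 vs T3 (early) and T3 vs T5 (late) with
#' sign-flip permutation p-values. The raw analysis covers pre-immersion
#' timepoints (0-64 s: anticipatory effects); the baseline-corrected analysis
#' covers immersion and recovery (65 s onward: evoked effects) after
#' subtracting each trial's final-15-s baseline mean.
#'
#' @param panel a `measure_panel` (unsmoothed; smoothed input is refused).
#' @param protocol a `protocol_definition`.
#' @param analysis `"corrected"` (baseline-corrected, 65 s onward) or
#'   `"raw"` (0-64 s). Correction is applied internally for `"corrected"`
#'   unless the panel is already flagged as corrected.
#' @param n_perm permutation iterations per timepoint and effect.
#' @param alpha significance threshold on `p_null`.
#' @param seed master seed; per-timepoint streams are derived from it.
#' @param effects subset of `c("condition", "trial", "interaction")` to
#'   test (trial-label permutations dominate runtime; large calibration runs
#'   can restrict to `"condition"`).
#' @param gated compute interaction-gated pairwise contrasts.
#' @param max_masked_frac timepoints where more than this fraction of
#'   subjects is masked are excluded from the tracks.
#' @param min_run optional contiguity filter: flagged runs shorter than this
#'   many seconds are cleared (0 = off, the default).
#' @return object of class `significance_tracks`: list with `results` (long
#'   data.frame: `t, effect, condition, stat, df1, df2, eta_p_sq, p_null,
#'   flagged`), `tracks` (named logical vectors over the grid; NA out of
#'   scope), `contrast_tracks` (per condition), plus run metadata.
#' @export
pointwise_framework <- function(panel, protocol = make_default_protocol(),
                                analysis = c("corrected", "raw"),
                                n_perm = 1000, alpha = 0.05, seed = 1,
                                effects = c("condition", "trial",
                                            "interaction"),
                                gated = TRUE, max_masked_frac = 0.25,
                                min_run = 0) {
  analysis <- match.arg(analysis)
  if (isTRUE(attr(panel, "smoothed")))
    stop("smoothed panels must not enter the statistics path")
  if (analysis == "corrected" && !isTRUE(attr(panel, "baseline_corrected")))
    panel <- baseline_correct(panel, protocol)
  nT <- dim(panel$values)[4]
  grid <- time_grid(protocol)
  imm_start <- epoch_interval(protocol, "immersion")["start"]
  scope <- if (analysis == "raw") which(grid < imm_start)
           else which(grid >= imm_start)
  n_subj <- dim(panel$values)[1]
  conditions <- dimnames(panel$values)[[2]]
  contrast_pairs <- list(T1vT5 = c(1, 5), T1vT3 = c(1, 3), T3vT5 = c(3, 5))

  tracks <- list()
  for (e in effects) tracks[[e]] <- rep(NA, nT)
  contrast_tracks <- list()
  for (cd in conditions) {
    contrast_tracks[[cd]] <- list()
    for (cp in names(contrast_pairs)) contrast_tracks[[cd]][[cp]] <- rep(NA, nT)
  }
  rows <- vector("list", length(scope))

  for (k in seq_along(scope)) {
    g <- scope[k]
    cells <- panel_cells_at(panel, g)
    y <- cells$y
    if ((n_subj - dim(y)[1]) / n_subj > max_masked_frac) next
    if (dim(y)[1] < 3) next
    n <- dim(y)[1]
    fit <- rm_anova_2way(y)
    set.seed(derive_seed(seed, g))
    S <- perm_signs(n_perm, n)
    res_t <- list()
    for (e in effects) {
      obs <- fit$F[fit$effect == e]
      null <- switch(e,
        condition = perm_F_condition(y, S),
        interaction = perm_F_interaction(y, S),
        trial = perm_F_trial(y, n_perm))
      p <- p_ge(null, obs)
      flag <- p < alpha
      tracks[[e]][g] <- flag
      res_t[[e]] <- data.frame(t = grid[g], effect = e, condition = NA,
                               stat = obs, df1 = fit$df1[fit$effect == e],
                               df2 = fit$df2[fit$effect == e],
                               eta_p_sq = fit$eta_p_sq[fit$effect == e],
                               p_null = p, flagged = flag,
                               stringsAsFactors = FALSE)
    }
    if (gated && "interaction" %in% effects &&
        isTRUE(tracks$interaction[g])) {
      for (ci in seq_along(conditions)) {
        for (cp in names(contrast_pairs)) {
          pr <- contrast_pairs[[cp]]
          d <- y[, ci, pr[1]] - y[, ci, pr[2]]
          tobs <- paired_t_stat(d)
          q <- S %*% d
          mean_p <- q / n
          var_p <- (sum(d^2) - q^2 / n) / (n - 1)
          tnull <- ifelse(var_p <= 1e-300, ifelse(mean_p != 0, Inf, 0),
                          mean_p / sqrt(var_p / n))
          p <- p_ge(abs(tnull), abs(tobs))
          flag <- p < alpha
          contrast_tracks[[conditions[ci]]][[cp]][g] <- flag
          res_t[[paste(conditions[ci], cp)]] <- data.frame(
            t = grid[g], effect = cp, condition = conditions[ci],
            stat = tobs, df1 = n - 1, df2 = NA, eta_p_sq = NA,
            p_null = p, flagged = flag, stringsAsFactors = FALSE)
        }
      }
    }
    rows[[k]] <- do.call(rbind, res_t)
  }
  # gating law: a contrast flag requires the interaction flag at the same t
  if ("interaction" %in% effects) {
    for (cd in names(contrast_tracks)) {
      for (cp in names(contrast_tracks[[cd]])) {
        ct <- contrast_tracks[[cd]][[cp]]
        ct[!is.na(ct) & ct &
             (is.na(tracks$interaction) | !tracks$interaction)] <- FALSE
        contrast_tracks[[cd]][[cp]] <- ct
      }
    }
  }
  if (min_run > 0) {
    tracks <- lapply(tracks, clear_short_runs, min_run = min_run)
    contrast_tracks <- lapply(contrast_tracks, function(l)
      lapply(l, clear_short_runs, min_run = min_run))
  }
  structure(list(results = do.call(rbind, rows[!vapply(rows, is.null,
                                                       logical(1))]),
                 tracks = tracks, contrast_tracks = contrast_tracks,
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 analysis = analysis, scope = grid[scope],
                 measure = panel$measure),
            class = "significance_tracks")
}

clear_short_runs <- function(flags, min_run) {
  x <- flags
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (j in which(r$values & r$lengths < min_run))
    flags[starts[j]:ends[j]] <- FALSE
  flags
}

#' @export
print.significance_tracks <- function(x, ...) {
  cat(sprintf("significance_tracks (%s analysis, measure '%s'): %d timepoints in scope\n",
              x$analysis, x$measure %||% "", length(x$scope)))
  for (e in names(x$tracks)) {
    tr <- x$tracks[[e]]
    cat(sprintf("  %-12s flagged %d / %d\n", e, sum(tr, na.rm = TRUE),
                sum(!is.na(tr))))
  }
  invisible(x)
}

#' Three-way baseline-shift ANOVA over immersion timepoints
#'
#' Tests whether the signal departs from its own pre-exposure baseline: at
#' each timepoint t in `range_s`, a 2 (baseline: pre-exposure mean over the
#' final 15 s of baseline vs a trailing 15-s moving average over [t, t+15))
#' x 2 (condition) x 5 (trial) within-subject ANOVA is computed on the raw
#' panel, with permutation nulls per effect (condition-bearing effects swap
#' condition labels; baseline-bearing effects swap the pre/during pairing;
#' the trial main effect permutes trial labels).
#'
#' @param panel a raw (uncorrected) `measure_panel`.
#' @param protocol a `protocol_definition`.
#' @param n_perm,alpha,seed as in [pointwise_framework()].
#' @param range_s grid seconds analyzed (default 65:140).
#' @param window_s averaging window, seconds.
#' @return list with `results` (long data.frame over t x 7 effects) and
#'   `tracks` (list of 7 logical grid vectors).
#' @export
baseline_shift_anova <- function(panel, protocol = make_default_protocol(),
                                 n_perm = 1000, alpha = 0.05, seed = 1,
                                 range_s = 65:140, window_s = 15) {
  iv <- epoch_interval(protocol, "baseline")
  grid <- time_grid(protocol)
  pre_idx <- which(grid >= iv["end"] - window_s & grid < iv["end"])
  v <- panel$values
  d <- dim(v)
  nT <- d[4]
  pre <- apply(v[, , , pre_idx, drop = FALSE], 1:3, mean)
  effects <- c("baseline", "condition", "trial", "baseline:condition",
               "baseline:trial", "condition:trial",
               "baseline:condition:trial")
  tracks <- sapply(effects, function(e) rep(NA, nT), simplify = FALSE)
  rows <- list()
  Q5 <- ortho_contrasts(5)
  for (t0 in range_s) {
    win <- which(grid >= t0 & grid < t0 + window_s)
    during <- apply(v[, , , win, drop = FALSE], 1:3, mean)
    complete <- apply(is.finite(pre) & is.finite(during), 1, all)
    if (sum(complete) < 3) next
    y <- array(NA_real_, c(sum(complete), 2, 2, 5))
    y[, 1, , ] <- pre[complete, , ]
    y[, 2, , ] <- during[complete, , ]
    n <- dim(y)[1]
    fit <- rm_anova_3way(y, factor_names = c("baseline", "condition",
                                             "trial"))
    set.seed(derive_seed(seed, t0))
    S <- perm_signs(n_perm, n)
    for (e in effects) {
      obs <- fit$F[fit$effect == e]
      null <- baseline3_null(y, e, S, n_perm, Q5)
      p <- p_ge(null, obs)
      tracks[[e]][t0 + 1] <- p < alpha
      rows[[length(rows) + 1]] <- data.frame(
        t = t0, effect = e, stat = obs, df1 = fit$df1[fit$effect == e],
        df2 = fit$df2[fit$effect == e],
        eta_p_sq = fit$eta_p_sq[fit$effect == e], p_null = p,
        flagged = p < alpha, stringsAsFactors = FALSE)
    }
  }
  list(results = do.call(rbind, rows), tracks = tracks, alpha = alpha,
       n_perm = n_perm, seed = seed, range_s = range_s)
}

# Null F draws for one effect of the 2x2x5 design. Condition-bearing effects
# reduce to sign flips of the condition-difference array; baseline-bearing
# effects (without condition) to sign flips of the baseline-difference array;
# the trial main effect permutes trial labels within subject x baseline x
# condition.
baseline3_null <- function(y, effect, S, n_perm, Q5) {
  n <- dim(y)[1]
  has <- function(f) grepl(f, effect, fixed = TRUE)
  if (has("condition")) {
    D <- y[, , 1, ] - y[, , 2, ]          # n x 2(baseline) x 5
    U <- switch(effect,
      "condition" = rowMeans(matrix(D, n)),
      "baseline:condition" = (D[, 1, ] - D[, 2, ]) |> rowMeans(),
      "condition:trial" = {
        Dm <- (D[, 1, ] + D[, 2, ]) / 2
        (Dm - rowMeans(Dm)) %*% Q5
      },
      "baseline:condition:trial" = {
        Dd <- D[, 1, ] - D[, 2, ]
        (Dd - rowMeans(Dd)) %*% Q5
      })
    signflip_F(U, S)
  } else if (has("baseline")) {
    B <- y[, 1, , ] - y[, 2, , ]          # n x 2(condition) x 5
    U <- switch(effect,
      "baseline" = rowMeans(matrix(B, n)),
      "baseline:trial" = {
        Bm <- (B[, 1, ] + B[, 2, ]) / 2
        (Bm - rowMeans(Bm)) %*% Q5
      })
    signflip_F(U, S)
  } else {
    # trial main effect: permute trial labels within subject x B x C
    out <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      yp <- y
      for (i in seq_len(n)) for (b1 in 1:2) for (c1 in 1:2)
        yp[i, b1, c1, ] <- yp[i, b1, c1, sample.int(5)]
      st <- apply(yp, c(1, 4), mean)       # n x 5
      tt <- colMeans(st); si <- rowMeans(st); g <- mean(st)
      ss_t <- n * 4 * sum((tt - g)^2)
      resid <- st - outer(si, tt, "+") + g
      ss_err <- 4 * sum(resid^2)
      out[p] <- if (ss_err <= 1e-300) { if (ss_t > 0) Inf else 0 } else
        (ss_t / 4) / (ss_err / (4 * (n - 1)))
    }
    out
  }
}
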