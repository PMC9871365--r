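#' Condition x trial analysis of one scalar per trial
#'
#' The same framework as a single timepoint of [pointwise_framework()]:
#' two-way repeated-measures ANOVA with permutation nulls, then
#' interaction-gated pairwise trial contrasts per condition. Contrasts are
#' skipped for a condition whose difference variance is essentially zero
#' (e.g. floor-level control pain ratings).
#'
#' @param y numeric array `n x 2 x 5` (subjects x condition x trial).
#' @param n_perm,alpha,seed as in [pointwise_framework()].
#' @param gated compute pairwise contrasts when the interaction is flagged.
#' @return list with `anova` (data.frame incl. `p_null`, `flagged`) and
#'   `contrasts` (data.frame per condition x pair, possibly empty).
#' @export
scalar_condition_trial <- function(y, n_perm = 1000, alpha = 0.05, seed = 1,
                                   gated = TRUE) {
  n <- dim(y)[1]
  fit <- rm_anova_2way(y)
  set.seed(derive_seed(seed, 0))
  S <- perm_signs(n_perm, n)
  fit$p_null <- NA_real_
  for (e in fit$effect) {
    null <- switch(e,
      condition = perm_F_condition(y, S),
      interaction = perm_F_interaction(y, S),
      trial = perm_F_trial(y, n_perm))
    fit$p_null[fit$effect == e] <- p_ge(null, fit$F[fit$effect == e])
  }
  fit$flagged <- fit$p_null < alpha
  contrasts <- NULL
  if (gated && fit$flagged[fit$effect == "interaction"]) {
    pairs <- list(T1vT5 = c(1, 5), T1vT3 = c(1, 3), T3vT5 = c(3, 5))
    rows <- list()
    conditions <- dimnames(y)[[2]] %||% c("treatment", "control")
    for (ci in seq_along(conditions)) {
      for (cp in names(pairs)) {
        d <- y[, ci, pairs[[cp]][1]] - y[, ci, pairs[[cp]][2]]
        if (stats::var(d) < 1e-9) next  # degenerate (e.g. control floor)
        pr <- permutation_p(paired_t_stat(d), d, "paired_t", n_perm,
                            derive_seed(seed, 10 + ci))
        rows[[paste(ci, cp)]] <- data.frame(
          condition = conditions[ci], pair = cp, t = paired_t_stat(d),
          df = length(d) - 1, p_null = pr$p_null,
          flagged = pr$p_null < alpha, stringsAsFactors = FALSE)
      }
    }
    contrasts <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  list(anova = fit, contrasts = contrasts)
}

#' Electrode-wise EEG band x period analysis
#'
#' For each band x period, a condition x trial permutation ANOVA per
#' electrode; where any electrodes show a significant interaction, values are
#' averaged across those contributing electrodes and interaction-gated
#' pairwise contrasts are computed on the average.
#'
#' @param band_df tidy data.frame from [eeg_band_panel()] (`subject,
#'   condition, trial, channel, band, period, value`).
#' @param n_perm,alpha,seed as elsewhere.
#' @param effects ANOVA effects to test per electrode.
#' @return list with `electrode` (per-channel ANOVA long data.frame) and
#'   `followup` (per band x period contrasts on contributing electrodes).
#' @export
eeg_scalar_analysis <- function(band_df, n_perm = 500, alpha = 0.05,
                                seed = 1,
                                effects = c("condition", "trial",
                                            "interaction")) {
  to_array <- function(df) {
    subjects <- sort(unique(df$subject))
    trials <- paste0("T", 1:5)
    y <- array(NA_real_, c(length(subjects), 2, 5),
               dimnames = list(subjects, c("treatment", "control"), trials))
    idx <- cbind(match(df$subject, subjects),
                 match(df$condition, c("treatment", "control")),
                 match(df$trial, trials))
    y[idx] <- df$value
    y
  }
  rows <- list(); follow <- list()
  combos <- unique(band_df[, c("band", "period")])
  for (r in seq_len(nrow(combos))) {
    bnd <- combos$band[r]; per <- combos$period[r]
    sub <- band_df[band_df$band == bnd & band_df$period == per, ]
    contributing <- character(0)
    for (ch in unique(sub$channel)) {
      y <- to_array(sub[sub$channel == ch, ])
      if (any(is.na(y))) next
      res <- scalar_condition_trial(y, n_perm, alpha,
                                    derive_seed(seed, r * 100 +
                                                  match(ch, unique(sub$channel))),
                                    gated = FALSE)
      a <- res$anova
      a$band <- bnd; a$period <- per; a$channel <- ch
      rows[[paste(bnd, per, ch)]] <- a
      if (a$flagged[a$effect == "interaction"]) contributing <- c(contributing, ch)
    }
    if (length(contributing)) {
      avg <- stats::aggregate(value ~ subject + condition + trial,
                              data = sub[sub$channel %in% contributing, ],
                              FUN = mean)
      res <- scalar_condition_trial(to_array(avg), n_perm, alpha,
                                    derive_seed(seed, r), gated = TRUE)
      if (!is.null(res$contrasts)) {
        res$contrasts$band <- bnd; res$contrasts$period <- per
        res$contrasts$n_electrodes <- length(contributing)
        follow[[paste(bnd, per)]] <- res$contrasts
      }
    }
  }
  list(electrode = if (length(rows)) do.call(rbind, rows) else NULL,
       followup = if (length(follow)) do.call(rbind, follow) else NULL)
}

#' Mixed-design permutation ANOVA for cortisol
#'
#' 2 (condition, within) x 3 (sample: pre-T1, pre-T3, post-T5, within) with
#' session start time (AM/PM) as the between-participants factor. Permutation
#' nulls shuffle the factor under test: group labels across subjects for
#' between effects, condition labels within subjects for condition-bearing
#' effects, sample labels within subject x condition for sample effects.
#'
#' @param y numeric array `n x 2 x 3`.
#' @param group length-n between-subject factor (e.g. `"AM"`/`"PM"`).
#' @param n_perm,alpha,seed as elsewhere.
#' @return data.frame of all 7 effects with `p_null` and `flagged`.
#' @export
cortisol_mixed_anova <- function(y, group, n_perm = 1000, alpha = 0.05,
                                 seed = 1) {
  fit <- anova_split_plot(y, group)
  n <- dim(y)[1]
  set.seed(derive_seed(seed, 0))
  nulls <- matrix(NA_real_, n_perm, nrow(fit),
                  dimnames = list(NULL, fit$effect))
  for (p in seq_len(n_perm)) {
    yg <- y[sample.int(n), , , drop = FALSE]        # group shuffle
    yc <- y
    flip <- stats::runif(n) < 0.5
    yc[flip, , ] <- yc[flip, c(2, 1), , drop = FALSE]  # condition swap
    ys <- y
    for (i in seq_len(n)) for (ci in 1:2)
      ys[i, ci, ] <- ys[i, ci, sample.int(3)]       # sample permute
    fg <- anova_split_plot(yg, group)
    fc <- anova_split_plot(yc, group)
    fs <- anova_split_plot(ys, group)
    nulls[p, "group"] <- fg$F[fg$effect == "group"]
    for (e in c("condition", "group:condition", "condition:sample",
                "group:condition:sample"))
      nulls[p, e] <- fc$F[fc$effect == e]
    for (e in c("sample", "group:sample"))
      nulls[p, e] <- fs$F[fs$effect == e]
  }
  fit$p_null <- vapply(seq_len(nrow(fit)), function(j)
    p_ge(nulls[, fit$effect[j]], fit$F[j]), numeric(1))
  fit$flagged <- fit$p_null < alpha
  fit
}

#' Scalar analyses of a simulated study
#'
#' Runs the pain rating ANOVA, the immersion-averaged pupil analysis
#' (0-1 normalized), optionally the EEG band x period electrode analysis, and
#' the cortisol mixed ANOVA.
#'
#' @param study a `study_simulation`.
#' @param n_perm,alpha,seed as elsewhere.
#' @param eeg_band_df optional tidy band panel (from [eeg_band_panel()]);
#'   skipped when NULL.
#' @param pupil_window grid seconds averaged for the pupil analysis
#'   (default 66:155, the immersion period).
#' @return list with elements `pain`, `pupil`, `eeg` (or NULL), `cortisol`.
#' @export
scalar_analyses <- function(study, n_perm = 1000, alpha = 0.05, seed = 1,
                            eeg_band_df = NULL, pupil_window = 66:155) {
  out <- list()
  out$pain <- scalar_condition_trial(study$pain, n_perm, alpha,
                                     derive_seed(seed, 1))
  if (!is.null(study$panels$PUPIL)) {
    pn <- normalize_01(study$panels$PUPIL)
    idx <- pupil_window + 1
    yp <- apply(pn$values[, , , idx, drop = FALSE], 1:3, mean, na.rm = TRUE)
    out$pupil <- scalar_condition_trial(yp, n_perm, alpha,
                                        derive_seed(seed, 2))
  }
  if (!is.null(eeg_band_df))
    out$eeg <- eeg_scalar_analysis(eeg_band_df, min(n_perm, 500), alpha,
                                   derive_seed(seed, 3))
  out$cortisol <- cortisol_mixed_anova(study$cortisol,
                                       study$subjects$start_time,
                                       n_perm, alpha, derive_seed(seed, 4))
  out
}
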