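# Permutation-null machinery. The scheme follows the factor under test:
# condition and interaction effects swap each subject's condition labels with
# probability 1/2 (a within-subject shuffle of the full trial set); trial
# effects permute trial labels within subject x condition; paired t contrasts
# flip each subject's difference sign. p_null counts null statistics >= the
# observed one, divided by the number of iterations (the observed value is
# not added to the null set), so p_null >= 1/(n_perm+1) effectively and a
# value below every draw reports 0.

# Tolerant >= used when counting null draws at least as extreme as the
# observed statistic: permutation schemes can regenerate the observed value
# exactly (e.g. the identity sign pattern), and it must count as a tie
# regardless of floating-point round-off in the two computation routes.
p_ge <- function(null, obs) {
  mean(null >= obs - 1e-9 * max(1, abs(obs)))
}

# Random sign matrix (n_perm x n), entries in {-1, +1}.
perm_signs <- function(n_perm, n) {
  matrix(sign(stats::runif(n_perm * n) - 0.5), n_perm, n)
}

# All 2^n sign patterns (for exhaustive paired tests at small n).
all_signs <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
}

# Core sign-flip F statistic for within-subject contrast matrices.
# U: n x q matrix of per-subject contrast scores whose null distribution is
# generated by per-subject sign flips; S: n_perm x n sign matrix. Returns the
# F of the effect spanned by U's columns against its subject interaction:
# F = n (n-1) W / (sum(U^2) - n W), with W the per-permutation sum of squared
# contrast means. Requires U's columns to be an orthonormal contrast basis
# (any common scaling cancels; different per-column scalings do not).
signflip_F <- function(U, S) {
  U <- as.matrix(U)
  n <- nrow(U)
  M <- (S %*% U) / n
  W <- rowSums(M^2)
  SU <- sum(U^2)
  den <- SU - n * W
  ifelse(den <= 1e-300, ifelse(W > 0, Inf, 0), n * (n - 1) * W / den)
}

# Orthonormal contrast basis for a k-level factor (Helmert, orthonormalized).
ortho_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))
}

# Condition-effect F under condition-label swaps: U = subject condition
# differences averaged over trials. y: n x 2 x b.
perm_F_condition <- function(y, S) {
  D <- y[, 1, ] - y[, 2, ]
  signflip_F(rowMeans(D), S)
}

# Interaction F under condition-label swaps: U = trial-contrast scores of the
# subject condition-difference profiles.
perm_F_interaction <- function(y, S) {
  D <- y[, 1, ] - y[, 2, ]
  b <- ncol(D)
  G <- D - rowMeans(D)
  signflip_F(G %*% ortho_contrasts(b), S)
}

# Trial-effect F under within-subject-x-condition trial-label permutation.
perm_F_trial <- function(y, n_perm) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  out <- numeric(n_perm)
  ym <- matrix(aperm(y, c(3, 1, 2)), b)   # b x (n*a) columns: subj x cond
  ncols <- n * a
  for (p in seq_len(n_perm)) {
    yp <- ym
    for (j in seq_len(ncols)) yp[, j] <- yp[sample.int(b), j]
    st <- yp[, seq_len(n)]
    if (a > 1) for (ci in 2:a) st <- st + yp[, (ci - 1) * n + seq_len(n)]
    st <- st / a                                          # b x n subj means
    tt <- rowMeans(st)
    si <- colMeans(st)
    g <- mean(tt)
    ss_t <- n * a * sum((tt - g)^2)
    resid <- st - outer(tt, si, "+") + g
    ss_err <- a * sum(resid^2)
    out[p] <- if (ss_err <= 1e-300) { if (ss_t > 0) Inf else 0 } else
      (ss_t / (b - 1)) / (ss_err / ((b - 1) * (n - 1)))
  }
  out
}

#' Permutation p-value for a repeated-measures effect or paired contrast
#'
#' @param observed observed statistic (F, or t for `effect = "paired_t"`).
#' @param data for ANOVA effects, the `n x 2 x b` cell array; for
#'   `"paired_t"`, the vector of per-subject differences.
#' @param effect one of `"condition"`, `"trial"`, `"interaction"`,
#'   `"paired_t"`.
#' @param n_perm permutation iterations (warns below 100).
#' @param seed integer seed.
#' @param exhaustive for `"paired_t"`, enumerate all `2^n` sign patterns
#'   instead of sampling.
#' @param sided `"two"` (default) or `"one"`: sidedness of the paired t
#'   comparison (F effects are inherently one-sided).
#' @return list with `p_null`, `n_perm` (effective), `null` (statistics).
#' @export
permutation_p <- function(observed, data, effect, n_perm = 1000, seed = 1,
                          exhaustive = FALSE, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (n_perm < 100 && !exhaustive)
    warning("n_perm < 100 gives a coarse null")
  set.seed(seed)
  if (effect == "paired_t") {
    d <- as.numeric(data)
    n <- length(d)
    S <- if (exhaustive) all_signs(n) else perm_signs(n_perm, n)
    q <- as.numeric(S %*% d)
    mean_p <- q / n
    var_p <- (sum(d^2) - q^2 / n) / (n - 1)
    tstat <- ifelse(var_p <= 1e-300, ifelse(mean_p != 0, Inf, 0),
                    mean_p / sqrt(var_p / n))
    null <- if (sided == "two") abs(tstat) else tstat
    obs <- if (sided == "two") abs(observed) else observed
  } else {
    y <- data
    stopifnot(length(dim(y)) == 3)
    n <- dim(y)[1]
    null <- switch(effect,
      condition = perm_F_condition(y, perm_signs(n_perm, n)),
      interaction = perm_F_interaction(y, perm_signs(n_perm, n)),
      trial = perm_F_trial(y, n_perm),
      stop("unknown effect: ", effect))
    obs <- observed
  }
  list(p_null = p_ge(null, obs), n_perm = length(null), null = null)
}

# Observed paired t statistic.
paired_t_stat <- function(d) {
  n <- length(d)
  v <- stats::var(d)
  if (v <= 1e-300) return(if (mean(d) != 0) Inf else 0)
  mean(d) / sqrt(v / n)
}
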