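# Classical fully-within-subject ANOVA decompositions, computed from marginal
# means. Subjects index dimension 1; each within effect is tested against its
# own interaction with subjects.

# Expand a marginal-mean array over `keep` dims back to the full shape.
expand_marginal <- function(m, keep, dims) {
  if (!length(keep)) return(array(m, dims))
  oth <- setdiff(seq_along(dims), keep)
  a <- array(m, dim = c(dims[keep], dims[oth]))
  aperm(a, order(c(keep, oth)))
}

# Effect array (full shape) for the factor subset `A` via Moebius inversion
# over marginal means; sum of its squares is the effect SS.
effect_ss <- function(y, A) {
  dims <- dim(y)
  subsets <- list(integer(0))
  for (f in A) subsets <- c(subsets, lapply(subsets, c, f))
  e <- array(0, dims)
  for (B in subsets) {
    sgn <- (-1)^(length(A) - length(B))
    m <- if (length(B)) apply(y, sort(B), mean) else mean(y)
    e <- e + sgn * expand_marginal(m, sort(B), dims)
  }
  sum(e^2)
}

anova_f_row <- function(effect, ss, ss_err, df1, df2) {
  f <- if (ss_err <= 1e-300) { if (ss > 1e-300) Inf else 0 } else
    (ss / df1) / (ss_err / df2)
  data.frame(effect = effect, F = f, df1 = df1, df2 = df2, ss = ss,
             ss_error = ss_err,
             eta_p_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
             stringsAsFactors = FALSE)
}

#' Two-way repeated-measures ANOVA (condition x trial)
#'
#' Classical within-subject decomposition of an `n x a x b` cell array
#' (subjects x conditions x trials): each effect is tested against its own
#' subject-by-effect error term, with partial eta squared
#' `SS_effect / (SS_effect + SS_error)`. Degenerate zero-error cases yield
#' `F = Inf` (non-zero effect) or `F = 0`.
#'
#' @param y numeric array `n x a x b` with complete cells.
#' @return data.frame with rows `condition`, `trial`, `interaction` and
#'   columns `effect, F, df1, df2, ss, ss_error, eta_p_sq`.
#' @export
rm_anova_2way <- function(y) {
  stopifnot(length(dim(y)) == 3)
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (n < 3) stop("need at least 3 subjects")
  if (a == 2) {
    # direct matrix computation (hot path of the pointwise framework)
    A <- y[, 1, , drop = FALSE]; dim(A) <- c(n, b)
    B <- y[, 2, , drop = FALSE]; dim(B) <- c(n, b)
    SC <- cbind(rowMeans(A), rowMeans(B))
    ST <- (A + B) / 2
    Cm <- colMeans(SC); Tm <- colMeans(ST)
    S <- rowMeans(SC); g <- mean(Cm)
    CT <- rbind(colMeans(A), colMeans(B))
    ss_C <- b * n * sum((Cm - g)^2)
    ss_SC <- b * sum((SC - S - rep(Cm, each = n) + g)^2)
    ss_T <- a * n * sum((Tm - g)^2)
    ss_ST <- a * sum((ST - S - rep(Tm, each = n) + g)^2)
    ctr <- CT - outer(Cm, Tm, "+") + g
    ss_CT <- n * sum(ctr^2)
    Tmn <- matrix(Tm, n, b, byrow = TRUE)
    R1 <- A - SC[, 1] - ST - matrix(CT[1, ], n, b, byrow = TRUE) +
      S + Cm[1] + Tmn - g
    R2 <- B - SC[, 2] - ST - matrix(CT[2, ], n, b, byrow = TRUE) +
      S + Cm[2] + Tmn - g
    ss_SCT <- sum(R1^2) + sum(R2^2)
    return(rbind(
      anova_f_row("condition", ss_C, ss_SC, a - 1, (a - 1) * (n - 1)),
      anova_f_row("trial", ss_T, ss_ST, b - 1, (b - 1) * (n - 1)),
      anova_f_row("interaction", ss_CT, ss_SCT,
                  (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1))))
  }
  rbind(
    anova_f_row("condition", effect_ss(y, 2), effect_ss(y, c(1, 2)),
                a - 1, (a - 1) * (n - 1)),
    anova_f_row("trial", effect_ss(y, 3), effect_ss(y, c(1, 3)),
                b - 1, (b - 1) * (n - 1)),
    anova_f_row("interaction", effect_ss(y, c(2, 3)),
                effect_ss(y, c(1, 2, 3)),
                (a - 1) * (b - 1), (a - 1) * (b - 1) * (n - 1))
  )
}

#' Three-way repeated-measures ANOVA
#'
#' Fully-within decomposition of an `n x l2 x l3 x l4` array; all 7 main and
#' interaction effects, each against its subject interaction.
#'
#' @param y numeric array `n x l2 x l3 x l4`; factor names taken from
#'   `names(dimnames(y))[2:4]` or `factor_names`.
#' @param factor_names labels for the three within factors.
#' @return data.frame as in [rm_anova_2way()], one row per effect
#'   (e.g. `"baseline"`, `"baseline:condition"`, ...).
#' @export
rm_anova_3way <- function(y, factor_names = c("baseline", "condition",
                                              "trial")) {
  stopifnot(length(dim(y)) == 4)
  n <- dim(y)[1]
  if (n < 3) stop("need at least 3 subjects")
  dims <- dim(y)
  rows <- list()
  for (k in 1:3) {
    combs <- utils::combn(2:4, k)
    for (j in seq_len(ncol(combs))) {
      A <- combs[, j]
      df1 <- prod(dims[A] - 1)
      rows[[length(rows) + 1]] <- anova_f_row(
        paste(factor_names[A - 1], collapse = ":"),
        effect_ss(y, A), effect_ss(y, c(1, A)), df1, df1 * (n - 1))
    }
  }
  do.call(rbind, rows)
}

#' Mixed (split-plot) ANOVA for the cortisol design
#'
#' One between-subject factor (e.g. session start time AM/PM) and two within
#' factors (condition x sample). Between effect tested against subjects
#' within groups; within effects and their group interactions against the
#' corresponding within-subject error pooled over groups.
#'
#' @param y numeric array `n x a x b` (subjects x condition x sample).
#' @param group factor/character of length n (between-subject groups).
#' @return data.frame of effects `group, condition, group:condition, sample,
#'   group:sample, condition:sample, group:condition:sample` with F, dfs and
#'   partial eta squared.
#' @export
anova_split_plot <- function(y, group) {
  stopifnot(length(dim(y)) == 3, dim(y)[1] == length(group))
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  group <- as.factor(group)
  G <- nlevels(group)
  if (n - G < 1) stop("need more subjects than groups")
  gm <- mean(y)
  m_i <- apply(y, 1, mean)                  # subject means
  m_g <- as.numeric(tapply(m_i, group, mean))
  n_g <- tabulate(group, nbins = G)
  gi <- as.integer(group)
  # per-group cell/margin means
  y_ic <- apply(y, c(1, 2), mean)           # n x a
  y_is <- apply(y, c(1, 3), mean)           # n x b
  y_c <- colMeans(y_ic)                     # a
  y_s <- colMeans(y_is)                     # b
  y_cs <- apply(y, c(2, 3), mean)           # a x b
  y_gc <- apply(y_ic, 2, function(v) tapply(v, group, mean))   # G x a
  y_gs <- apply(y_is, 2, function(v) tapply(v, group, mean))   # G x b
  y_gcs <- array(NA_real_, c(G, a, b))
  for (g in seq_len(G))
    y_gcs[g, , ] <- apply(y[gi == g, , , drop = FALSE], c(2, 3), mean)
  if (G == 1) { y_gc <- matrix(y_gc, 1); y_gs <- matrix(y_gs, 1) }

  ss_G <- a * b * sum(n_g * (m_g - gm)^2)
  ss_SG <- a * b * sum((m_i - m_g[gi])^2)

  ss_C <- n * b * sum((y_c - gm)^2)
  ss_GC <- b * sum(n_g * (y_gc - outer(m_g, y_c, "+") + gm)^2)
  err_C <- y_ic - m_i - y_gc[gi, , drop = FALSE] + m_g[gi]
  ss_eC <- b * sum(err_C^2)

  ss_S <- n * a * sum((y_s - gm)^2)
  ss_GS <- a * sum(n_g * (y_gs - outer(m_g, y_s, "+") + gm)^2)
  err_S <- y_is - m_i - y_gs[gi, , drop = FALSE] + m_g[gi]
  ss_eS <- a * sum(err_S^2)

  cs_int <- y_cs - outer(y_c, y_s, "+") + gm
  ss_CS <- n * sum(cs_int^2)
  ss_GCS <- 0
  for (g in seq_len(G)) {
    g_int <- y_gcs[g, , ] - outer(y_gc[g, ], y_gs[g, ], "+") + m_g[g]
    ss_GCS <- ss_GCS + n_g[g] * sum((g_int - cs_int)^2)
  }
  ss_eCS <- 0
  for (i in seq_len(n)) {
    i_int <- y[i, , ] - outer(y_ic[i, ], y_is[i, ], "+") + m_i[i]
    g_int <- y_gcs[gi[i], , ] - outer(y_gc[gi[i], ], y_gs[gi[i], ], "+") +
      m_g[gi[i]]
    ss_eCS <- ss_eCS + sum((i_int - g_int)^2)
  }

  rbind(
    anova_f_row("group", ss_G, ss_SG, G - 1, n - G),
    anova_f_row("condition", ss_C, ss_eC, a - 1, (a - 1) * (n - G)),
    anova_f_row("group:condition", ss_GC, ss_eC, (a - 1) * (G - 1),
                (a - 1) * (n - G)),
    anova_f_row("sample", ss_S, ss_eS, b - 1, (b - 1) * (n - G)),
    anova_f_row("group:sample", ss_GS, ss_eS, (b - 1) * (G - 1),
                (b - 1) * (n - G)),
    anova_f_row("condition:sample", ss_CS, ss_eCS, (a - 1) * (b - 1),
                (a - 1) * (b - 1) * (n - G)),
    anova_f_row("group:condition:sample", ss_GCS, ss_eCS,
                (a - 1) * (b - 1) * (G - 1), (a - 1) * (b - 1) * (n - G))
  )
}
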