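# Repeated-measures statistical battery.
#
# Fully within-subject designs with one observation per subject x cell:
# two-way (game x target height) and one-way (simple effects) ANOVA. Each
# effect is tested against its own subject-by-effect interaction error term.
# Sphericity is screened per effect with Mauchly's test on orthonormal
# contrast scores; when violated (p < .05 by default) both degrees of
# freedom are multiplied by the Greenhouse-Geisser epsilon
#   eps = tr(S)^2 / (d * tr(S^2)),
# where S is the covariance of the d orthonormal contrast scores. Effect
# sizes are partial eta-squared, SS_effect / (SS_effect + SS_error), with
# > 0.25 read as moderate and > 0.64 as strong. Post hoc comparisons use
# uncorrected paired t-tests (least significant differences).

# (k-1) x k matrix of orthonormal contrasts, each orthogonal to the mean.
orthonormal_contrasts <- function(k) {
  t(qr.Q(qr(stats::contr.helmert(k))))
}

mauchly_gg <- function(Z) {
  d <- ncol(Z)
  n <- nrow(Z)
  S <- cov(Z)
  eps <- sum(diag(S))^2 / (d * sum(S * S))
  if (d == 1L) {
    return(list(epsilon = 1, W = 1, mauchly_p = NA_real_))
  }
  W <- det(S) / (sum(diag(S)) / d)^d
  if (!is.finite(W) || W <= 0) {
    return(list(epsilon = eps, W = W, mauchly_p = NA_real_))
  }
  # chi-square approximation with the standard second-order correction term
  nn <- n - 1
  f <- d * (d + 1) / 2 - 1
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nn)
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
    (288 * d^2 * nn^2 * rho^2)
  stat <- -nn * rho * log(W)
  pr1 <- pchisq(stat, f, lower.tail = FALSE)
  pr2 <- pchisq(stat, f + 4, lower.tail = FALSE)
  p <- pr1 + w2 * (pr2 - pr1)
  list(epsilon = eps, W = W, mauchly_p = min(max(p, 0), 1))
}

effect_row <- function(effect, ss_eff, df_eff, ss_err, df_err, Z,
                       sphericity_alpha) {
  ms_eff <- ss_eff / df_eff
  ms_err <- ss_err / df_err
  F <- if (ms_err > 0) ms_eff / ms_err else 0
  sph <- mauchly_gg(Z)
  corrected <- !is.na(sph$mauchly_p) && sph$mauchly_p < sphericity_alpha
  df1 <- df_eff
  df2 <- df_err
  if (corrected) {
    df1 <- sph$epsilon * df_eff
    df2 <- sph$epsilon * df_err
  }
  tibble::tibble(
    effect = effect, F = F, df1 = df1, df2 = df2,
    p = pf(F, df1, df2, lower.tail = FALSE),
    partial_eta_sq = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0,
    epsilon_gg = sph$epsilon, mauchly_p = sph$mauchly_p,
    corrected = corrected,
    ss_effect = ss_eff, ss_error = ss_err,
    df1_uncorrected = df_eff, df2_uncorrected = df_err)
}

# Core decomposition. Y is n x (a*b) (or n x a when b is NULL), columns
# ordered with the first factor slow and the second fast.
rm_anova_core <- function(Y, a, b = NULL, names_ab = c("A", "B"),
                          sphericity_alpha = 0.05) {
  n <- nrow(Y)
  if (n < 2) abort_reachvr("need at least 2 subjects", "reachvr_insufficient_data_error")
  m <- mean(Y)
  m_s <- rowMeans(Y)

  if (is.null(b)) {
    m_j <- colMeans(Y)
    ss_a <- n * sum((m_j - m)^2)
    resid <- sweep(sweep(Y, 1, m_s), 2, m_j) + m
    ss_as <- sum(resid^2)
    Z <- Y %*% t(orthonormal_contrasts(a))
    return(effect_row(names_ab[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1), Z,
                      sphericity_alpha))
  }

  K_A <- kronecker(diag(a), matrix(1 / b, b, 1))      # (ab) x a, col order j slow
  K_B <- kronecker(matrix(1 / a, a, 1), diag(b))
  M_A <- Y %*% K_A                                    # subject x A marginal means
  M_B <- Y %*% K_B
  m_j <- colMeans(M_A)
  m_k <- colMeans(M_B)
  m_jk <- colMeans(Y)                                 # length ab

  ss_a <- n * b * sum((m_j - m)^2)
  ss_b <- n * a * sum((m_k - m)^2)
  ss_as <- b * sum((sweep(sweep(M_A, 1, m_s), 2, m_j) + m)^2)
  ss_bs <- a * sum((sweep(sweep(M_B, 1, m_s), 2, m_k) + m)^2)
  mj_full <- rep(m_j, each = b)
  mk_full <- rep(m_k, times = a)
  ss_ab <- n * sum((m_jk - mj_full - mk_full + m)^2)
  resid <- Y -
    M_A[, rep(seq_len(a), each = b), drop = FALSE] -
    M_B[, rep(seq_len(b), times = a), drop = FALSE] -
    matrix(m_jk, n, a * b, byrow = TRUE) +
    matrix(m_s, n, a * b) +
    matrix(mj_full + mk_full - m, n, a * b, byrow = TRUE)
  ss_abs <- sum(resid^2)

  C_a <- orthonormal_contrasts(a)
  C_b <- orthonormal_contrasts(b)
  Z_a <- Y %*% t(kronecker(C_a, matrix(1 / b, 1, b)))
  Z_b <- Y %*% t(kronecker(matrix(1 / a, 1, a), C_b))
  Z_ab <- Y %*% t(kronecker(C_a, C_b))

  dplyr::bind_rows(
    effect_row(names_ab[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1), Z_a, sphericity_alpha),
    effect_row(names_ab[2], ss_b, b - 1, ss_bs, (b - 1) * (n - 1), Z_b, sphericity_alpha),
    effect_row(paste0(names_ab[1], ":", names_ab[2]), ss_ab, (a - 1) * (b - 1),
               ss_abs, (a - 1) * (b - 1) * (n - 1), Z_ab, sphericity_alpha))
}

factor_levels <- function(x) {
  if (is.factor(x)) return(levels(x))
  u <- unique(x)
  if (is.character(x) && all(u %in% GAMES)) return(intersect(GAMES, u))
  sort(u)
}

# Pivot a long table to the n x (a*b) matrix the core expects.
cells_matrix <- function(data, outcome, subject, within) {
  vals <- data[[outcome]]
  subj <- data[[subject]]
  levs <- lapply(within, function(w) factor_levels(data[[w]]))
  key <- do.call(interaction, c(lapply(seq_along(within), function(i) {
    factor(data[[within[i]]], levels = levs[[i]])
  }), list(lex.order = TRUE, drop = FALSE)))
  subj_f <- factor(subj)
  counts <- table(subj_f, key)
  if (any(counts != 1L)) {
    bad <- sum(counts == 0L)
    abort_reachvr(sprintf(
      "incomplete or duplicated design: need exactly one observation per subject x cell (%d empty, %d duplicated cells)",
      bad, sum(counts > 1L)), "reachvr_design_error")
  }
  if (anyNA(vals)) abort_reachvr("outcome contains missing values", "reachvr_design_error")
  Y <- matrix(NA_real_, nlevels(subj_f), nlevels(key),
              dimnames = list(levels(subj_f), levels(key)))
  Y[cbind(as.integer(subj_f), as.integer(key))] <- vals
  list(Y = Y, levels = levs)
}

#' Repeated-measures ANOVA (1 or 2 within-subject factors)
#'
#' Fits a fully within-subject ANOVA on a long table with one observation
#' per subject and cell, testing each effect against its subject-by-effect
#' interaction. Mauchly's sphericity test is run per effect; when it rejects
#' (at `sphericity_alpha`), Greenhouse-Geisser-corrected degrees of freedom
#' are used for the reported F test. Partial eta-squared accompanies every
#' effect.
#'
#' @param data Long data frame (e.g. the cohort table from
#'   [aggregate_trials()]).
#' @param outcome Outcome column (unquoted).
#' @param subject Subject identifier column (unquoted).
#' @param within One or two within-subject factor columns (unquoted, e.g.
#'   `c(game, theta_deg)`).
#' @param sphericity_alpha Mauchly p-value below which the
#'   Greenhouse-Geisser correction is applied (default 0.05).
#'
#' @return An object of class `reachvr_rm_anova`; use [tidy()] for the
#'   per-effect table (`effect`, `F`, `df1`, `df2`, `p`, `partial_eta_sq`,
#'   `epsilon_gg`, `mauchly_p`, `corrected`, sums of squares and
#'   uncorrected dfs) and [glance()] for a one-row fit summary.
#' @examples
#' tab <- tidyr::expand_grid(participant = paste0("P", 1:6),
#'                           game = c("reachality", "fishality", "dodgeality"),
#'                           theta_deg = c(15, 30, 45, 60))
#' tab$y <- rnorm(nrow(tab)) + tab$theta_deg / 20
#' fit <- rm_anova(tab, y, participant, c(game, theta_deg))
#' tidy(fit)
#' @export
rm_anova <- function(data, outcome, subject, within, sphericity_alpha = 0.05) {
  out_nm <- tidyselect::eval_select(rlang::enquo(outcome), data)
  sub_nm <- tidyselect::eval_select(rlang::enquo(subject), data)
  w_nm <- tidyselect::eval_select(rlang::enquo(within), data)
  if (length(out_nm) != 1L || length(sub_nm) != 1L || !length(w_nm) %in% 1:2) {
    abort_validation("need one outcome, one subject column and 1-2 within factors")
  }
  cm <- cells_matrix(data, names(out_nm), names(sub_nm), names(w_nm))
  ks <- lengths(cm$levels)
  tab <- if (length(ks) == 1L) {
    rm_anova_core(cm$Y, ks[1], NULL, names(w_nm), sphericity_alpha)
  } else {
    rm_anova_core(cm$Y, ks[1], ks[2], names(w_nm), sphericity_alpha)
  }
  structure(list(table = tab, n = nrow(cm$Y), outcome = names(out_nm),
                 within = names(w_nm), levels = cm$levels,
                 sphericity_alpha = sphericity_alpha),
            class = "reachvr_rm_anova")
}

#' @export
print.reachvr_rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on `%s` (n = %d subjects)\n", x$outcome, x$n))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-22s F(%.1f, %.1f) = %.3f, p %s, eta^2p = %.3f%s\n",
                r$effect, r$df1, r$df2, r$F,
                ifelse(r$p < 0.001, "< .001", sprintf("= %.3f", r$p)),
                r$partial_eta_sq,
                ifelse(r$corrected, " [GG-corrected]", "")))
  }
  invisible(x)
}

#' @rdname rm_anova
#' @param x A `reachvr_rm_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.reachvr_rm_anova <- function(x, ...) x$table

#' @rdname rm_anova
#' @exportS3Method generics::glance
glance.reachvr_rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n, outcome = x$outcome,
                 n_effects = nrow(x$table),
                 any_corrected = any(x$table$corrected),
                 min_p = min(x$table$p))
}

#' Partial eta-squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`, algebraically identical to
#' `SS_effect / (SS_effect + SS_error)` for the matching ANOVA effect, so a
#' published F with its degrees of freedom determines the effect size.
#'
#' @param f F statistic (`>= 0`).
#' @param df1,df2 Numerator and denominator degrees of freedom (possibly
#'   epsilon-corrected, `> 0`). Vectorised.
#' @return Partial eta-squared in `[0, 1]`.
#' @examples
#' eta_sq_from_f(17.002, 2, 48)  # 0.415
#' @export
eta_sq_from_f <- function(f, df1, df2) {
  if (any(f < 0) || any(df1 <= 0) || any(df2 <= 0)) {
    abort_validation("need f >= 0 and positive degrees of freedom")
  }
  f * df1 / (f * df1 + df2)
}

#' Classify a partial eta-squared effect size
#'
#' Values above 0.64 are strong, above 0.25 moderate, otherwise small
#' (strict inequalities).
#'
#' @param partial_eta_sq Value(s) in `[0, 1]`.
#' @return Character vector: `"small"`, `"moderate"` or `"strong"`.
#' @export
classify_effect_size <- function(partial_eta_sq) {
  if (any(partial_eta_sq < 0 | partial_eta_sq > 1)) {
    abort_validation("partial eta-squared must lie in [0, 1]")
  }
  dplyr::case_when(partial_eta_sq > 0.64 ~ "strong",
                   partial_eta_sq > 0.25 ~ "moderate",
                   TRUE ~ "small")
}

#' Shapiro-Wilk normality test
#'
#' Royston-algorithm W and p (delegating to [stats::shapiro.test()]) for
#' sample sizes 3 to 5000.
#'
#' @param x Numeric sample. A degenerate constant sample (zero range) has no
#'   defined W and yields `NA`s.
#' @return One-row tibble with `W`, `p_value`, `n`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort_validation("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (diff(range(x)) == 0) {
    return(tibble::tibble(W = NA_real_, p_value = NA_real_, n = length(x)))
  }
  sw <- stats::shapiro.test(x)
  tibble::tibble(W = unname(sw$statistic), p_value = sw$p.value, n = length(x))
}

#' Normality screen per design cell
#'
#' Runs [shapiro_wilk()] on each (game, height) cell of a cohort table
#' across participants, as done before fitting the ANOVA models.
#'
#' @inheritParams rm_anova
#' @return Tibble with one row per cell: factor levels, `W`, `p_value`, `n`.
#' @export
normality_screen <- function(data, outcome, within) {
  out_nm <- names(tidyselect::eval_select(rlang::enquo(outcome), data))
  w_nm <- names(tidyselect::eval_select(rlang::enquo(within), data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(w_nm))) |>
    dplyr::summarise(shapiro_wilk(.data[[out_nm]]), .groups = "drop")
}

#' LSD post hoc pairwise comparisons
#'
#' All pairwise paired t-tests between levels of one within-subject factor
#' (subject means collapsed over any other factor), with uncorrected
#' p-values — the least-significant-differences method.
#'
#' @inheritParams rm_anova
#' @param factor Factor column (unquoted) whose levels are compared.
#' @return Tibble: `level_1`, `level_2`, `mean_diff` (level_1 - level_2),
#'   `t`, `df`, `p_value`.
#' @export
lsd_posthoc <- function(data, outcome, subject, factor) {
  out_nm <- names(tidyselect::eval_select(rlang::enquo(outcome), data))
  sub_nm <- names(tidyselect::eval_select(rlang::enquo(subject), data))
  fac_nm <- names(tidyselect::eval_select(rlang::enquo(factor), data))
  levs <- factor_levels(data[[fac_nm]])
  wide <- data |>
    dplyr::group_by(.data[[sub_nm]], .data[[fac_nm]]) |>
    dplyr::summarise(value = mean(.data[[out_nm]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(fac_nm), values_from = "value")
  purrr::map_dfr(utils::combn(as.character(levs), 2, simplify = FALSE), function(pr) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    n <- length(d)
    se <- sd(d) / sqrt(n)
    tstat <- if (se > 0) mean(d) / se else 0
    p <- if (se > 0) 2 * pt(abs(tstat), n - 1, lower.tail = FALSE) else 1
    tibble::tibble(level_1 = pr[1], level_2 = pr[2], mean_diff = mean(d),
                   t = tstat, df = n - 1, p_value = p)
  })
}

#' Simple effects of one factor at each level of the other
#'
#' Follows up a significant interaction: a one-way repeated-measures ANOVA
#' of `within` (e.g. game) at every level of `by` (e.g. target height), each
#' with its own error term and its own LSD pairwise comparisons.
#'
#' @inheritParams rm_anova
#' @param within Factor compared within each stratum (unquoted).
#' @param by Stratifying factor (unquoted).
#' @return Tibble of per-stratum ANOVA rows (column named after `by`) with a
#'   `posthoc` list-column of LSD tables.
#' @export
simple_effects <- function(data, outcome, subject, within, by,
                           sphericity_alpha = 0.05) {
  out_q <- rlang::enquo(outcome)
  sub_q <- rlang::enquo(subject)
  w_q <- rlang::enquo(within)
  by_nm <- names(tidyselect::eval_select(rlang::enquo(by), data))
  levs <- factor_levels(data[[by_nm]])
  purrr::map_dfr(levs, function(lv) {
    sub_tab <- data[data[[by_nm]] == lv, , drop = FALSE]
    fit <- rm_anova(sub_tab, !!out_q, !!sub_q, !!w_q, sphericity_alpha)
    row <- fit$table
    row[[by_nm]] <- lv
    row$posthoc <- list(lsd_posthoc(sub_tab, !!out_q, !!sub_q, !!w_q))
    dplyr::relocate(row, dplyr::all_of(by_nm))
  })
}
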