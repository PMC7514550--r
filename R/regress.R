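#' Per-feature linear age regression with distributional screening
#'
#' For every feature column: ordinary least squares of
#' `feature = a0 + a1 * age`, with R^2 and coefficient p-values; then the
#' decade-group screens -- Shapiro-Wilk normality (on the group-model
#' residuals) and Brown-Forsythe equal variance (Levene on median centres).
#' When normality passes, group differences are tested with one-way ANOVA
#' and pairwise t comparisons; when it fails, with Kruskal-Wallis and Dunn's
#' rank-based pairwise test. Pairwise p-values are multiplicity-adjusted.
#'
#' @param cohort an `hrv_cohort` of raw (non-normalized) features with
#'   `age_years` and `decade` columns.
#' @param adjust p-value adjustment method for pairwise comparisons
#'   (default `"holm"`; any [stats::p.adjust.methods] value).
#' @param alpha significance level for reporting pairs and screens.
#' @return tibble with one row per feature: `a0`, `a1`, `r_squared`,
#'   `p_a0`, `p_a1`, `normality_p`, `normality_pass`, `equal_variance_p`,
#'   `equal_variance_pass`, `group_test` (`"anova"`/`"kruskal"`),
#'   `group_p`, `sig_pairs` (e.g. `"20vs80,30vs80"`), `degenerate`.
#' @export
age_regression <- function(cohort, adjust = "holm", alpha = 0.05) {
  if (isTRUE(attr(cohort, "normalized"))) {
    rlang::warn("age regression expects raw features; cohort is z-scored")
  }
  cols <- cohort_feature_cols(cohort)
  dplyr::bind_rows(lapply(cols, function(f) {
    d <- cohort[!is.na(cohort[[f]]) & !is.na(cohort$age_years), ]
    v <- d[[f]]; age <- d$age_years; g <- factor(d$decade)
    if (length(v) < 3 || stats::sd(v) == 0) {
      return(tibble::tibble(
        feature = f, a0 = if (length(v)) mean(v) else NA_real_, a1 = 0,
        r_squared = 0, p_a0 = NA_real_, p_a1 = NA_real_,
        normality_p = NA_real_, normality_pass = NA,
        equal_variance_p = NA_real_, equal_variance_pass = NA,
        group_test = NA_character_, group_p = NA_real_,
        sig_pairs = NA_character_, degenerate = TRUE))
    }
    fit <- stats::lm(v ~ age)
    sm <- summary(fit)
    norm_p <- tryCatch(
      stats::shapiro.test(stats::residuals(stats::aov(v ~ g)))$p.value,
      error = function(e) NA_real_)
    bf_p <- tryCatch(
      car::leveneTest(v ~ g, center = "median")[1, "Pr(>F)"],
      error = function(e) NA_real_)
    norm_pass <- !is.na(norm_p) && norm_p >= alpha
    if (norm_pass) {
      gp <- summary(stats::aov(v ~ g))[[1]][1, "Pr(>F)"]
      pw <- stats::pairwise.t.test(v, g, p.adjust.method = adjust)$p.value
      test <- "anova"
    } else {
      gp <- stats::kruskal.test(v, g)$p.value
      dn <- dunn_pairwise(v, g, adjust = adjust)
      pw <- matrix(NA_real_, nlevels(g) - 1, nlevels(g) - 1,
                   dimnames = list(levels(g)[-1], levels(g)[-nlevels(g)]))
      for (j in seq_len(nrow(dn))) pw[dn$g2[j], dn$g1[j]] <- dn$p[j]
      test <- "kruskal"
    }
    sig <- which(pw < alpha, arr.ind = TRUE)
    pairs <- if (nrow(sig)) {
      paste(sprintf("%svs%s", colnames(pw)[sig[, 2]], rownames(pw)[sig[, 1]]),
            collapse = ",")
    } else NA_character_
    tibble::tibble(
      feature = f,
      a0 = sm$coefficients[1, 1], a1 = sm$coefficients[2, 1],
      r_squared = sm$r.squared,
      p_a0 = sm$coefficients[1, 4], p_a1 = sm$coefficients[2, 4],
      normality_p = norm_p, normality_pass = norm_pass,
      equal_variance_p = bf_p,
      equal_variance_pass = !is.na(bf_p) && bf_p >= alpha,
      group_test = test, group_p = gp, sig_pairs = pairs,
      degenerate = FALSE)
  }))
}

#' Dunn's rank-based pairwise comparison
#'
#' Tie-corrected z tests on mean ranks for all group pairs, the standard
#' follow-up to a Kruskal-Wallis test.
#'
#' @param value numeric vector.
#' @param group grouping factor.
#' @param adjust p-value adjustment method.
#' @return tibble `g1`, `g2`, `z`, `p` (adjusted).
#' @export
dunn_pairwise <- function(value, group, adjust = "holm") {
  g <- factor(group)
  N <- length(value)
  r <- rank(value)
  tie <- table(r)
  tie_corr <- sum(tie^3 - tie) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  nn <- table(g)
  prs <- utils::combn(levels(g), 2)
  z <- apply(prs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nn[pr[1]] + 1 / nn[pr[2]]))
    (rbar[pr[1]] - rbar[pr[2]]) / se
  })
  tibble::tibble(g1 = prs[1, ], g2 = prs[2, ], z = as.numeric(z),
                 p = stats::p.adjust(2 * stats::pnorm(-abs(z)), method = adjust))
}
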