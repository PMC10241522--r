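#' Two-group comparison with diagnostic-driven test selection
#'
#' Implements the classical selection rule for two-sample comparisons: a
#' two-tailed Student's t-test (pooled variance) when both samples pass a
#' Shapiro-Wilk normality check and an F-test of equal variances at
#' `alpha_select`, otherwise a Mann-Whitney U (Wilcoxon rank-sum) test. For
#' paired data the diagnostics run on the differences and the alternative
#' is a paired t-test vs a Wilcoxon signed-rank test.
#'
#' @param a,b numeric samples (>= 3 observations each)
#' @param paired paired design?
#' @param alpha_select significance level for the diagnostics
#' @return one-row data.frame: `test_name`, `statistic`, `p_value`, `n_a`,
#'   `n_b`, `normal_a_p`, `normal_b_p`, `var_equal_p`, `paired`
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha_select = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 observations per group for diagnostics")
  if (paired && length(a) != length(b))
    stop("paired samples must have equal length")

  if (paired) {
    d <- a - b
    if (all(d == d[1])) {
      # constant differences: degenerate; identical samples give t = 0, p = 1
      if (d[1] == 0)
        return(data.frame(test_name = "Student t (paired)", statistic = 0,
                          p_value = 1, n_a = length(a), n_b = length(b),
                          normal_a_p = NA, normal_b_p = NA,
                          var_equal_p = NA, paired = TRUE))
      stop("constant nonzero differences: no variance to test against")
    }
    sw <- stats::shapiro.test(d)$p.value
    if (sw > alpha_select) {
      tt <- stats::t.test(a, b, paired = TRUE)
      return(data.frame(test_name = "Student t (paired)",
                        statistic = unname(tt$statistic),
                        p_value = tt$p.value, n_a = length(a),
                        n_b = length(b), normal_a_p = sw, normal_b_p = NA,
                        var_equal_p = NA, paired = TRUE))
    }
    wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
    return(data.frame(test_name = "Wilcoxon signed-rank",
                      statistic = unname(wt$statistic),
                      p_value = wt$p.value, n_a = length(a),
                      n_b = length(b), normal_a_p = sw, normal_b_p = NA,
                      var_equal_p = NA, paired = TRUE))
  }

  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both samples constant: nothing to compare")
  swa <- if (stats::sd(a) > 0) stats::shapiro.test(a)$p.value else 0
  swb <- if (stats::sd(b) > 0) stats::shapiro.test(b)$p.value else 0
  vf <- if (stats::sd(a) > 0 && stats::sd(b) > 0)
    stats::var.test(a, b)$p.value else 0
  if (swa > alpha_select && swb > alpha_select && vf > alpha_select) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    out <- data.frame(test_name = "Student t",
                      statistic = unname(tt$statistic),
                      p_value = tt$p.value)
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    out <- data.frame(test_name = "Mann-Whitney U",
                      statistic = unname(wt$statistic),
                      p_value = wt$p.value)
  }
  cbind(out, data.frame(n_a = length(a), n_b = length(b), normal_a_p = swa,
                        normal_b_p = swb, var_equal_p = vf, paired = FALSE))
}

#' Two-way factorial ANOVA with Tukey post hoc
#'
#' Ordinary (between-subjects) two-way ANOVA via [stats::aov()] with
#' interaction, plus Tukey's HSD on both factors and the interaction.
#'
#' @param data data.frame with the response and two factor columns
#' @param response,factor1,factor2 column names
#' @return list with `anova` (data.frame of effects) and `tukey`
#'   (TukeyHSD result)
#' @export
anova_two_way <- function(data, response, factor1, factor2) {
  data[[factor1]] <- factor(data[[factor1]])
  data[[factor2]] <- factor(data[[factor2]])
  fml <- stats::as.formula(paste(response, "~", factor1, "*", factor2))
  fit <- stats::aov(fml, data = data)
  tab <- as.data.frame(summary(fit)[[1]])
  tab$effect <- trimws(rownames(tab))
  list(anova = tab, tukey = stats::TukeyHSD(fit))
}

gg_epsilon <- function(Y) {
  # Greenhouse-Geisser epsilon from a subject x condition matrix
  S <- stats::cov(Y)
  k <- ncol(S)
  mg <- mean(S)
  md <- mean(diag(S))
  mr <- rowMeans(S)
  num <- (k * (md - mg))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(mr^2) + k^2 * mg^2)
  num / den
}

#' Repeated-measures two-way ANOVA with Greenhouse-Geisser correction
#'
#' Both factors within-subject (e.g. drug condition x current step with
#' every cell measured in every condition). Classical univariate
#' partitioning with subject error strata; the p-value of each
#' within-subject effect uses Greenhouse-Geisser-corrected degrees of
#' freedom estimated from that effect's subject-by-condition matrix, which
#' yields the fractional df familiar from commercial statistics packages.
#'
#' @param data long data.frame: one row per subject x condition
#' @param response,subject,factor1,factor2 column names
#' @return data.frame with `effect`, `F`, `df1`, `df2` (GG-corrected),
#'   `epsilon`, `p_value`
#' @export
rm_anova_two_way <- function(data, response, subject, factor1, factor2) {
  y <- data[[response]]
  s <- factor(data[[subject]])
  f1 <- factor(data[[factor1]])
  f2 <- factor(data[[factor2]])
  n <- nlevels(s); a <- nlevels(f1); b <- nlevels(f2)
  if (nrow(data) != n * a * b)
    stop("design must be complete: one observation per subject x cell")

  cell_mean <- function(fac) tapply(y, fac, mean)
  grand <- mean(y)
  m_s <- cell_mean(s); m_1 <- cell_mean(f1); m_2 <- cell_mean(f2)
  m_s1 <- tapply(y, list(s, f1), mean)
  m_s2 <- tapply(y, list(s, f2), mean)
  m_12 <- tapply(y, list(f1, f2), mean)

  ss_1 <- n * b * sum((m_1 - grand)^2)
  ss_2 <- n * a * sum((m_2 - grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_s1 <- b * sum((m_s1 - matrix(m_s, n, a) -
                      matrix(m_1, n, a, byrow = TRUE) + grand)^2)
  ss_s2 <- a * sum((m_s2 - matrix(m_s, n, b) -
                      matrix(m_2, n, b, byrow = TRUE) + grand)^2)
  ss_12 <- n * sum((m_12 - matrix(m_1, a, b) -
                      matrix(m_2, a, b, byrow = TRUE) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_1 - ss_2 - ss_s - ss_s1 - ss_s2 - ss_12

  row_for <- function(name, ss_eff, df_eff, ss_e, df_e, Y) {
    eps <- max(1 / (ncol(Y) - 1), min(1, gg_epsilon(Y)))
    Fv <- (ss_eff / df_eff) / (ss_e / df_e)
    data.frame(effect = name, F = Fv, df1 = df_eff * eps, df2 = df_e * eps,
               epsilon = eps,
               p_value = stats::pf(Fv, df_eff * eps, df_e * eps,
                                   lower.tail = FALSE))
  }
  out <- rbind(
    row_for(factor1, ss_1, a - 1, ss_s1, (n - 1) * (a - 1), m_s1),
    row_for(factor2, ss_2, b - 1, ss_s2, (n - 1) * (b - 1), m_s2),
    row_for(paste0(factor1, ":", factor2), ss_12, (a - 1) * (b - 1),
            ss_err, (n - 1) * (a - 1) * (b - 1),
            tapply(y, list(s, interaction(f1, f2)), mean)))
  rownames(out) <- NULL
  out
}
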