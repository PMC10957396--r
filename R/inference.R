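#' Two-way fixed-effects ANOVA with Bonferroni group post hocs
#'
#' Group x condition ANOVA on participant-condition cell values (three
#' rows per participant), with type-III sums of squares under sum-to-zero
#' contrasts (groups differ in size), Cohen's f per effect, and
#' Bonferroni-adjusted pairwise group comparisons. With a single condition
#' level the model degrades gracefully to a one-way group ANOVA.
#'
#' @param data data frame with the response and factor columns.
#' @param response name of the response column.
#' @param group,condition names of the factor columns.
#' @return List with `anova` (term, F, df1, df2, p, cohens_f), `posthoc`
#'   (pairwise Bonferroni-adjusted group p-values) and the fitted `lm`.
#' @export
pi_anova <- function(data, response = "value", group = "group",
                     condition = "condition") {
  df <- data.frame(
    value = data[[response]],
    group = factor(data[[group]]),
    condition = factor(data[[condition]])
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$group)) < 2) stop("need at least two group levels")
  df$group <- droplevels(df$group)
  df$condition <- droplevels(df$condition)
  two_way <- nlevels(df$condition) >= 2

  if (two_way) {
    m <- stats::lm(value ~ group * condition, data = df,
                   contrasts = list(group = "contr.sum", condition = "contr.sum"))
    a <- car::Anova(m, type = 3)
    terms_keep <- c("group", "condition", "group:condition")
  } else {
    m <- stats::lm(value ~ group, data = df,
                   contrasts = list(group = "contr.sum"))
    a <- car::Anova(m, type = 3)
    terms_keep <- "group"
  }
  ss_err <- a[["Sum Sq"]][rownames(a) == "Residuals"]
  df_err <- a[["Df"]][rownames(a) == "Residuals"]
  idx <- match(terms_keep, rownames(a))
  tab <- tibble::tibble(
    term = terms_keep,
    F = a[["F value"]][idx],
    df1 = a[["Df"]][idx],
    df2 = df_err,
    p = a[["Pr(>F)"]][idx],
    cohens_f = sqrt(a[["Sum Sq"]][idx] / ss_err)
  )
  ph <- stats::pairwise.t.test(df$value, df$group,
                               p.adjust.method = "bonferroni")
  pm <- ph$p.value
  posthoc <- tibble::tibble(
    group1 = rep(rownames(pm), ncol(pm)),
    group2 = rep(colnames(pm), each = nrow(pm)),
    p_adj = as.vector(pm)
  )
  posthoc <- posthoc[!is.na(posthoc$p_adj), , drop = FALSE]
  list(anova = tab, posthoc = posthoc, model = m)
}

#' One-sample t-test of a fitted parameter against its nominal value
#'
#' Two-tailed test of participant-level parameter estimates against the
#' no-error value (`k = 1`, `g2 = 1`, `beta = 0`, `g3 = 1`, `m3 = 1`).
#' Zero-variance input is flagged: `t = 0, p = 1` when the constant equals
#' the nominal value, otherwise an infinite t.
#'
#' @param x numeric vector of participant-level estimates.
#' @param nominal the no-error value tested against.
#' @return Tibble with `t`, `df`, `p`, `mean`, `nominal`, `degenerate`.
#' @export
nominal_t_test <- function(x, nominal) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least two values")
  if (stats::sd(x) == 0) {
    eq <- isTRUE(all.equal(mean(x), nominal))
    return(tibble::tibble(
      t = if (eq) 0 else Inf * sign(mean(x) - nominal),
      df = length(x) - 1L, p = if (eq) 1 else 0,
      mean = mean(x), nominal = nominal, degenerate = TRUE
    ))
  }
  tt <- stats::t.test(x, mu = nominal)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean = mean(x), nominal = nominal, degenerate = FALSE
  )
}

#' Pearson correlation between a demographic variable and a parameter
#'
#' @param x,y paired numeric vectors (e.g. age and fitted `g2`); pairs
#'   with missing values are dropped; fewer than 3 complete pairs is an
#'   error.
#' @return Tibble with `r`, `p`, `n`.
#' @export
demographic_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least three complete pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Achieved power of a fixed-effects ANOVA main effect
#'
#' Analytic noncentral-F power with noncentrality `lambda = f^2 * N`,
#' numerator df `groups - 1` and denominator df `N - groups`. At `f = 0`
#' the power equals the alpha level; power is monotone increasing in both
#' `f` and `N`.
#'
#' @param f Cohen's f effect size (>= 0).
#' @param alpha significance level.
#' @param groups number of group levels.
#' @param n total number of observations.
#' @return Achieved power in `[0, 1]`.
#' @export
anova_power <- function(f, alpha = 0.05, groups, n) {
  stopifnot(f >= 0, alpha > 0, alpha < 1, groups >= 2, n > groups)
  df1 <- groups - 1
  df2 <- n - groups
  lambda <- f^2 * n
  stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda,
            lower.tail = FALSE)
}
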