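# evaluation: strategy comparison by correlation with clinical variables,
# plus the demographic summary tests (Welch t from printed summaries,
# Yates-corrected chi-square).

#' Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3, both nonconstant.
#' @return the sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have the same length")
  .assert(length(x) >= 3, "at least 3 observations are required")
  .assert(stats::sd(x) > 0 && stats::sd(y) > 0,
          "Pearson correlation is undefined for constant input")
  stats::cor(x, y, method = "pearson")
}

#' Group summary statistics
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @return object of class `summary_stats`.
#' @export
summary_stats <- function(n, mean, sd) {
  .assert(n >= 2, "n must be >= 2")
  .assert(sd >= 0, "sd must be >= 0")
  structure(list(n = as.integer(n), mean = as.double(mean),
                 sd = as.double(sd)), class = "summary_stats")
}

#' Welch two-sample t-test from group summaries
#'
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with the
#' Welch-Satterthwaite degrees of freedom; two-sided p from the t
#' distribution. Agrees with a raw-data `t.test(..., var.equal = FALSE)`
#' when fed that data's summaries.
#'
#' @param a,b [summary_stats()] objects (or lists with `n`, `mean`, `sd`).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summary <- function(a, b) {
  .assert(!(a$sd == 0 && b$sd == 0), "both groups have zero variance")
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  tval <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(tval), df = df)
  list(t = tval, df = df, p = p)
}

#' Chi-squared test with Yates continuity correction on a 2x2 table
#'
#' `chi2 = sum((|O - E| - 0.5)^2 / E)` with the correction term floored at
#' zero when `|O - E| < 0.5`; df = 1.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return list with `chi2`, `df` (= 1), `p`.
#' @export
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  .assert(all(dim(table) == c(2, 2)), "a 2x2 table is required")
  .assert(all(table >= 0), "counts must be nonnegative")
  .assert(all(rowSums(table) > 0) && all(colSums(table) > 0),
          "all margins must be positive")
  res <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' One-way analysis of variance
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor).
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  .assert(nlevels(groups) >= 2, "at least 2 groups are required")
  .assert(length(values) - nlevels(groups) >= 1,
          "zero within-group degrees of freedom")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1],
       df_between = tab[["Df"]][1],
       df_within = tab[["Df"]][2],
       p = tab[["Pr(>F)"]][1])
}

#' Tukey honest significant difference pairwise comparisons
#'
#' Studentized-range adjusted p-values for all group pairs after a one-way
#' ANOVA.
#'
#' @inheritParams oneway_anova
#' @param alpha significance level used for the `significant` flag.
#' @return data.frame with `pair`, `diff`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  .assert(nlevels(groups) >= 2, "at least 2 groups are required")
  .assert(length(values) - nlevels(groups) >= 1,
          "zero within-group degrees of freedom")
  tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
  data.frame(pair = rownames(tk),
             diff = tk[, "diff"],
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] <= alpha,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Strategy records for the comparison layer
#'
#' @param outcome `"LV"` or `"EDSS"`.
#' @param metric gray-matter metric label (e.g. `"CT"`, `"MAP"`).
#' @param correction correction-method label.
#' @param smoothing_or_parcellation smoothing sigma (standard approaches)
#'   or patch count (mosaic), 0 = none.
#' @param r Pearson correlation of the strategy's burden fraction with the
#'   outcome.
#' @return data.frame of class `strategy_records`.
#' @export
strategy_records <- function(outcome, metric, correction,
                             smoothing_or_parcellation, r) {
  .assert(all(r >= -1 & r <= 1), "r must lie in [-1, 1]")
  df <- data.frame(outcome = as.character(outcome),
                   metric = as.character(metric),
                   correction = as.character(correction),
                   smoothing_or_parcellation =
                     as.double(smoothing_or_parcellation),
                   r = as.double(r),
                   stringsAsFactors = FALSE)
  class(df) <- c("strategy_records", "data.frame")
  df
}

#' Compare atrophy-assessment strategies
#'
#' Runs three one-way ANOVAs on the per-strategy correlation values:
#' (1) outcome (LV vs EDSS), (2) approach (each gray-matter metric, mosaic
#' included, as its own level), (3) smoothing/parcellation (none vs any).
#' Significant ANOVAs are followed by Tukey HSD. Hypotheses whose factor
#' has fewer than two levels are skipped with a warning. Also returns the
#' records ranked by correlation within outcome.
#'
#' @param records a [strategy_records()] data.frame.
#' @param alpha significance level; default 0.05.
#' @return list with `anova_outcome`, `anova_approach`,
#'   `anova_smoothing`, the matching `tukey_*` tables (NULL when the ANOVA
#'   was skipped or not significant), and `ranked` (records sorted by
#'   outcome, then descending r).
#' @export
compare_strategies <- function(records, alpha = 0.05) {
  .assert(is.data.frame(records) && nrow(records) >= 2,
          "at least 2 strategy records are required")
  req <- c("outcome", "metric", "correction", "smoothing_or_parcellation", "r")
  missing_cols <- setdiff(req, names(records))
  .assert(length(missing_cols) == 0,
          paste0("records missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  run_block <- function(fac, label) {
    fac <- factor(fac)
    if (nlevels(fac) < 2) {
      warning(sprintf("hypothesis on %s skipped: only level '%s' present",
                      label, levels(fac)))
      return(list(anova = NULL, tukey = NULL))
    }
    an <- oneway_anova(records$r, fac)
    tk <- if (!is.na(an$p) && an$p <= alpha)
      tukey_hsd(records$r, fac, alpha) else NULL
    list(anova = an, tukey = tk)
  }
  h1 <- run_block(records$outcome, "outcome (LV vs EDSS)")
  h2 <- run_block(records$metric, "approach (metric)")
  h3 <- run_block(ifelse(records$smoothing_or_parcellation > 0, "any", "none"),
                  "smoothing/parcellation (none vs any)")
  ranked <- records[order(records$outcome, -records$r), ]
  rownames(ranked) <- NULL
  list(anova_outcome = h1$anova, tukey_outcome = h1$tukey,
       anova_approach = h2$anova, tukey_approach = h2$tukey,
       anova_smoothing = h3$anova, tukey_smoothing = h3$tukey,
       ranked = ranked)
}
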