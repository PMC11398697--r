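# Cohort-level statistical machinery. Baseline strategies are deterministic
# controllers, not samples, so only per-participant differences to each
# baseline can be tested; the three baseline comparisons share a
# Bonferroni-corrected level alpha = 0.05 / 3.

#' Per-subject differences to the baseline strategies
#'
#' For every metric shared by the subject and baseline reports, computes
#' `delta = subject value - baseline value` per subject, configuration and
#' baseline strategy.
#'
#' @param reports cohort report (one row per subject and configuration,
#'   from [cohort_report()]).
#' @param baseline_reports data frame with columns `config`, `strategy` and
#'   the same metric columns, one row per baseline per configuration.
#' @param metrics metric columns to difference.
#' @return long data frame `subject, config, strategy, metric, delta`.
#'   Metrics missing on either side are kept as `NA` rows and flagged with
#'   a warning, never silently dropped.
#' @export
baseline_differences <- function(reports, baseline_reports,
                                 metrics = c("f_osc", "eta", "rho",
                                             "phi_over_pi")) {
  out <- list()
  for (cfg in unique(reports$config)) {
    sub <- reports[reports$config == cfg, ]
    bl <- baseline_reports[baseline_reports$config == cfg, ]
    for (st in unique(bl$strategy)) {
      b <- bl[bl$strategy == st, ]
      for (m in metrics) {
        bv <- if (m %in% names(b)) b[[m]][1] else NA_real_
        sv <- if (m %in% names(sub)) sub[[m]] else rep(NA_real_, nrow(sub))
        if (is.na(bv) || all(is.na(sv)))
          warning("metric ", m, " missing for ", cfg, "/", st)
        out[[length(out) + 1]] <- data.frame(
          subject = sub$subject, config = cfg, strategy = st, metric = m,
          delta = sv - bv)
      }
    }
  }
  do.call(rbind, out)
}

#' Two-sided one-sample t-test of baseline differences
#'
#' Tests the mean of `deltas` against zero at the Bonferroni-corrected
#' level for the three baseline comparisons.
#'
#' @param deltas numeric vector (n >= 3).
#' @param alpha significance level; default `0.05 / 3`.
#' @return `list(statistic, df, p, significant)`.
#' @export
one_sample_test <- function(deltas, alpha = 0.05 / 3) {
  stopifnot(length(deltas) >= 3)
  if (stats::sd(deltas) == 0) {
    if (all(deltas == 0))
      return(list(statistic = 0, df = length(deltas) - 1, p = 1,
                  significant = FALSE))
    stop("zero-variance sample with nonzero mean: t-test degenerate")
  }
  tt <- stats::t.test(deltas, mu = 0)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha)
}

#' Kolmogorov-Smirnov normality check
#'
#' KS distance of the standardized sample against the standard normal
#' reference (level 5%; standardizing makes the test conservative, which
#' matches its screening role here).
#'
#' @param sample numeric vector (n >= 3).
#' @return `list(statistic, p)`.
#' @export
normality_check <- function(sample) {
  stopifnot(length(sample) >= 3)
  if (stats::sd(sample) == 0) stop("constant sample: normality undefined")
  ks <- suppressWarnings(stats::ks.test(scale(sample)[, 1], "pnorm"))
  list(statistic = unname(ks$statistic), p = ks$p.value)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the t-transform p-value on `n - 2`
#' degrees of freedom (used to relate individual phase lags to hit scores
#' and mode-metric values).
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return `list(r, df, p)`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Omnibus F-test across groups followed by Tukey HSD adjusted pairwise
#' comparisons (used to verify the baseline strategies differ from each
#' other).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return `list(F, df, p, tukey)` with `tukey` a data frame of pairwise
#'   differences and adjusted p-values.
#' @export
anova_tukey <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 0L) >= 2))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L))))
  if (stats::sd(df$value) == 0)
    return(list(F = 0, df = c(length(groups) - 1,
                              nrow(df) - length(groups)),
                p = 1,
                tukey = NULL))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = an$`F value`[1], df = an$Df, p = an$`Pr(>F)`[1],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}
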