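#!/usr/bin/env Rscript
# Cohort statistics: baseline similarity tests and phase-lag correlations.
#
# Requires results/cohort_metrics.csv (04_cohort.R) and
# results/baselines.csv (03_baselines.R). For every metric the differences
# of each subject to each deterministic baseline are tested against zero
# with two-sided one-sample t-tests at the Bonferroni-corrected level
# 0.05/3; normality is screened with the KS check; phase lags are
# correlated with hit scores and mode-metric values; a one-way ANOVA with
# Tukey post-hocs verifies the baselines differ from each other.

library(pendmode)

rep <- read.csv("results/cohort_metrics.csv")
bl <- read.csv("results/baselines.csv")
exp1 <- rep[rep$experiment == "exp1", ]

deltas <- baseline_differences(exp1, bl)
tests <- do.call(rbind, lapply(
  split(deltas, list(deltas$config, deltas$strategy, deltas$metric)),
  function(d) {
    if (nrow(d) == 0 || any(is.na(d$delta))) return(NULL)
    ks <- normality_check(d$delta)
    tt <- one_sample_test(d$delta)
    data.frame(config = d$config[1], strategy = d$strategy[1],
               metric = d$metric[1], mean_delta = mean(d$delta),
               ks_p = signif(ks$p, 3), t = signif(tt$statistic, 3),
               df = tt$df, p = signif(tt$p, 3),
               significant = tt$significant)
  }))
write.csv(tests, "results/stats_baseline_tests.csv", row.names = FALSE)
print(tests[order(tests$config, tests$strategy, tests$metric), ],
      row.names = FALSE)

# does the individual phase lag predict performance?
cors <- do.call(rbind, lapply(split(exp1, exp1$config), function(d) {
  ch <- pearson_correlation(d$phi_over_pi, d$hits)
  ce <- pearson_correlation(d$phi_over_pi, d$eta)
  data.frame(config = d$config[1],
             r_hits = signif(ch$r, 3), p_hits = signif(ch$p, 3),
             r_eta = signif(ce$r, 3), p_eta = signif(ce$p, 3))
}))
write.csv(cors, "results/stats_phase_correlations.csv", row.names = FALSE)
print(cors, row.names = FALSE)

# the baseline strategies differ from one another (per metric deltas)
for (m in unique(deltas$metric)) {
  d <- deltas[deltas$metric == m & deltas$config == "P0", ]
  z <- anova_tukey(split(d$delta, d$strategy))
  cat(sprintf("ANOVA across baselines, %s (P0): F = %.3g, p = %.3g\n",
              m, z$F, z$p))
}
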