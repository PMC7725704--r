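#!/usr/bin/env Rscript
# Stage 2: agreement between simulated and original PET scores.
#
# Reads results/study/score_table.csv (stage 1), averages each subject's
# simulated scores over the 27 error maps per regime, and quantifies
# agreement with the original scores by OLS regression and Bland-Altman
# limits of agreement. Also compares the two regimes' absolute score
# errors with a paired t-test over the matched (subject, map-rank) pairs.
#
# Outputs: results/agreement.csv, results/paired_test.json, and (when
# ggplot2 is available) results/figures/*.png.

suppressPackageStartupMessages(library(petscoresim))

tab <- read_score_table("results/study/score_table.csv")
orig <- tab[tab$method == "original", ]
sim <- tab[tab$method != "original", ]

ps <- per_subject_average(sim)
rows <- list()
for (m in unique(ps$method)) {
  psm <- ps[ps$method == m, ]
  x <- orig$pet_score[match(psm$subject_id, orig$subject_id)]
  reg <- regression_agreement(x, psm$mean_score)
  ba <- bland_altman(x, psm$mean_score)
  message(sprintf(
    "%-10s y = %.4fx + %.4f (R^2 %.4f); bias %+.4f, LOA [%.4f, %.4f]",
    m, reg$slope, reg$intercept, reg$r_squared, ba$bias, ba$loa_low,
    ba$loa_high))
  rows[[m]] <- data.frame(method = m, slope = reg$slope,
                          intercept = reg$intercept, r_squared = reg$r_squared,
                          bias = ba$bias, loa_low = ba$loa_low,
                          loa_high = ba$loa_high)
}
agg <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(agg, "results/agreement.csv", row.names = FALSE)

# paired comparison of absolute errors between regimes, matched on
# (subject, map rank within method)
key <- function(d) d[order(d$subject_id, d$error_map_id), ]
abs_err <- function(m) {
  s <- key(sim[sim$method == m, ])
  abs(s$pet_score - orig$pet_score[match(s$subject_id, orig$subject_id)])
}
pt <- paired_ttest_abs(abs_err("Atlas_like"), abs_err("ZTE_like"))
message(sprintf(
  "paired t-test |err| Atlas_like vs ZTE_like: t = %.2f (df %d), p = %.3g, mean diff %+.4f",
  pt$t, pt$df, pt$p_value, pt$mean_diff))
jsonlite::write_json(pt, "results/paired_test.json", auto_unbox = TRUE,
                     digits = NA)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  ps$original <- orig$pet_score[match(ps$subject_id, orig$subject_id)]
  p1 <- ggplot(ps, aes(original, mean_score)) +
    geom_abline(linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4) +
    facet_wrap(~method) +
    labs(x = "original PET score", y = "mean simulated PET score (27 maps)")
  ggsave("results/figures/regression.png", p1, width = 8, height = 4, dpi = 120)
  ps$diff <- ps$mean_score - ps$original
  ps$avg <- (ps$mean_score + ps$original) / 2
  p2 <- ggplot(ps, aes(avg, diff)) +
    geom_hline(yintercept = 0, colour = "grey50") +
    geom_point(alpha = 0.6) +
    facet_wrap(~method) +
    labs(x = "mean of original and simulated", y = "simulated - original")
  ggsave("results/figures/bland_altman.png", p2, width = 8, height = 4, dpi = 120)
  message("figures written to results/figures/")
}
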