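#!/usr/bin/env Rscript
# Stage 3: diagnostic accuracy of the scored series.
#
# Reads results/study/score_table.csv and, for each series (original,
# ZTE_like, Atlas_like), classifies AD vs NC at the fixed published
# cutoff (PET score = 1) and at the Youden-optimal cutoff from the
# empirical ROC, pooling all (subject x map) rows within a series.
#
# Outputs: results/diagnostics.csv and, with ggplot2, an ROC figure.

suppressPackageStartupMessages(library(petscoresim))

tab <- read_score_table("results/study/score_table.csv")
if (!"diagnosis" %in% names(tab)) {
  # score_table.csv carries the canonical 5 columns; labels are encoded in
  # the generated subject ids
  tab$diagnosis <- ifelse(grepl("_AD$", tab$subject_id), "AD", "NC")
}

rows <- list()
roc_pts <- list()
for (m in unique(tab$method)) {
  s <- tab[tab$method == m, ]
  rep <- diagnostic_report(s$pet_score, s$diagnosis, cutoff = 1,
                           boot_reps = 2000, seed = 7)
  message(sprintf(
    "%-10s n=%4d  cutoff 1: acc %.3f [%.3f,%.3f] sens %.3f spec %.3f | AUC %.3f [%.3f,%.3f] | Youden cutoff %.3f -> acc %.3f",
    m, nrow(s),
    rep$at_cutoff$accuracy$estimate, rep$at_cutoff$accuracy$ci_low,
    rep$at_cutoff$accuracy$ci_high, rep$at_cutoff$sensitivity$estimate,
    rep$at_cutoff$specificity$estimate, rep$roc$auc, rep$roc$auc_ci_low,
    rep$roc$auc_ci_high, rep$roc$youden_cutoff,
    rep$at_youden$accuracy$estimate))
  rows[[m]] <- data.frame(
    method = m, n = nrow(s),
    accuracy = rep$at_cutoff$accuracy$estimate,
    accuracy_lo = rep$at_cutoff$accuracy$ci_low,
    accuracy_hi = rep$at_cutoff$accuracy$ci_high,
    sensitivity = rep$at_cutoff$sensitivity$estimate,
    specificity = rep$at_cutoff$specificity$estimate,
    auc = rep$roc$auc, auc_lo = rep$roc$auc_ci_low, auc_hi = rep$roc$auc_ci_high,
    youden_cutoff = rep$roc$youden_cutoff,
    accuracy_youden = rep$at_youden$accuracy$estimate)
  roc_pts[[m]] <- cbind(method = m, rep$roc$roc_points)
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/diagnostics.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  pts <- do.call(rbind, roc_pts)
  p <- ggplot(pts, aes(1 - specificity, sensitivity, colour = method)) +
    geom_abline(linetype = 2, colour = "grey70") +
    geom_step(linewidth = 0.6) +
    coord_equal() +
    labs(x = "1 - specificity", y = "sensitivity")
  ggsave("results/figures/roc.png", p, width = 5.5, height = 5, dpi = 120)
  message("figure written to results/figures/roc.png")
}
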