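# Diagnostic-accuracy evaluation of score tables: score-difference
# statistics, paired testing, per-subject agreement (regression and
# Bland-Altman), fixed-cutoff classification with Wilson intervals, and
# ROC/AUC with Youden-index cutoff selection.

#' Signed and absolute PET-score difference summaries
#'
#' Computes `diff = simulated - original` per (subject, error map) row and
#' summarizes mean, SD, max and min of the signed and absolute differences
#' per method.
#'
#' @param sim simulated score table (rows with `method != "original"`).
#' @param orig original score table (one row per subject, method
#'   `"original"`), or a combined table from [run_simulation()] from which
#'   the original rows are taken.
#' @param value column to difference (default `"pet_score"`).
#' @return data.frame with one row per method: `n`, `mean_diff`, `sd_diff`,
#'   `max_diff`, `min_diff`, `mean_abs_diff`, `sd_abs_diff`, `max_abs_diff`,
#'   `min_abs_diff`.
#' @export
score_difference_stats <- function(sim, orig = NULL, value = "pet_score") {
  if (is.null(orig)) {
    orig <- sim[sim$method == "original", ]
    sim <- sim[sim$method != "original", ]
  } else {
    orig <- orig[orig$method == "original", , drop = FALSE]
  }
  if (nrow(sim) == 0L) stop("no simulated rows")
  if (anyDuplicated(orig$subject_id))
    stop("original table must have one row per subject")
  idx <- match(sim$subject_id, orig$subject_id)
  if (anyNA(idx)) stop("key mismatch: simulated subjects missing from originals")
  d <- sim[[value]] - orig[[value]][idx]
  out <- do.call(rbind, lapply(split(d, sim$method), function(x) {
    data.frame(n = length(x),
               mean_diff = mean(x), sd_diff = stats::sd(x),
               max_diff = max(x), min_diff = min(x),
               mean_abs_diff = mean(abs(x)), sd_abs_diff = stats::sd(abs(x)),
               max_abs_diff = max(abs(x)), min_abs_diff = min(abs(x)))
  }))
  out <- cbind(method = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Paired t-test between two matched difference vectors
#'
#' Classical paired t statistic with n - 1 degrees of freedom, as used to
#' compare the absolute score errors of two attenuation-correction methods
#' over the same (subject, error map) pairs.
#'
#' @param abs_a,abs_b equal-length numeric vectors (n >= 2), matched
#'   pairwise.
#' @return list with `t`, `df`, `p_value` (two-sided), `mean_diff`.
#' @export
paired_ttest_abs <- function(abs_a, abs_b) {
  if (length(abs_a) != length(abs_b)) stop("vectors must have equal length")
  if (length(abs_a) < 2L) stop("need at least 2 pairs")
  d <- abs_a - abs_b
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t statistic undefined")
  ht <- stats::t.test(abs_a, abs_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = mean(d))
}

#' Per-subject mean score across error maps
#'
#' Averages the simulated scores of each subject over the error maps,
#' separately per method (the per-subject view used for agreement plots).
#' Requires a complete subject x map grid within each method.
#'
#' @param scores score table from [run_simulation()].
#' @param value column to average (default `"pet_score"`).
#' @return data.frame with columns `subject_id`, `method`, `n_maps`,
#'   `mean_score`.
#' @export
per_subject_average <- function(scores, value = "pet_score") {
  agg <- stats::aggregate(scores[[value]],
                          by = list(subject_id = scores$subject_id,
                                    method = scores$method),
                          FUN = function(x) c(n = length(x), m = mean(x)))
  out <- data.frame(subject_id = agg$subject_id, method = agg$method,
                    n_maps = agg$x[, "n"], mean_score = agg$x[, "m"],
                    stringsAsFactors = FALSE)
  for (m in unique(out$method)) {
    nm <- out$n_maps[out$method == m]
    if (length(unique(nm)) != 1L)
      stop(sprintf("missing cells: method %s has unequal map counts per subject", m))
  }
  out[order(out$method, out$subject_id), , drop = FALSE]
}

#' OLS agreement regression of simulated on original scores
#'
#' @param x original scores; @param y simulated (e.g. per-subject mean)
#'   scores, same length >= 3.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
regression_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::var(x) == 0) stop("constant x: regression undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = y - x`; bias = mean(d); limits of agreement =
#' bias +/- 1.96 * SD(d) (sample SD, n - 1 denominator).
#'
#' @param x reference values; @param y comparison values, same length >= 2.
#' @return list with `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need n >= 2")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

# Wilson score 95% CI for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Classification metrics at a fixed PET-score cutoff
#'
#' Predicts AD when `score >= cutoff` (ties count as positive) and reports
#' accuracy, sensitivity and specificity with Wilson 95% confidence
#' intervals.
#'
#' @param scores numeric scores.
#' @param labels logical or `"NC"`/`"AD"` labels (`TRUE`/`"AD"` = positive).
#' @param cutoff decision threshold (default 1, the published PET-score
#'   cutoff at the 95% prediction limit).
#' @return list with `cutoff`, counts (`tp`, `fp`, `tn`, `fn`, `n_pos`,
#'   `n_neg`) and `accuracy`, `sensitivity`, `specificity`, each a list of
#'   `estimate`, `ci_low`, `ci_high`.
#' @export
classify_at_cutoff <- function(scores, labels, cutoff = 1) {
  pos <- as_positive_labels(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  pred <- scores >= cutoff
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  mk <- function(k, n) {
    ci <- wilson_ci(k, n)
    list(estimate = k / n, ci_low = ci[1], ci_high = ci[2])
  }
  list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
       n_pos = tp + fn, n_neg = tn + fp,
       accuracy = mk(tp + tn, length(scores)),
       sensitivity = mk(tp, tp + fn),
       specificity = mk(tn, tn + fp))
}

as_positive_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("NC", "AD"))
    if (length(bad)) stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
    return(labels == "AD")
  }
  as.logical(labels)
}

#' Empirical ROC analysis with Youden-index cutoff and bootstrap AUC CI
#'
#' Builds the empirical ROC over all distinct score thresholds with the
#' `score >= cutoff` positivity rule; the AUC is the trapezoidal area
#' (equal to pairwise concordance with ties counted 1/2). The Youden cutoff
#' maximizes sensitivity + specificity - 1 over the observed thresholds
#' (lowest threshold on ties). The AUC confidence interval is a seeded
#' class-stratified percentile bootstrap.
#'
#' @param scores numeric scores.
#' @param labels positive-class labels as in [classify_at_cutoff()].
#' @param boot_reps bootstrap replicates for the AUC CI (default 2000;
#'   0 disables the CI).
#' @param seed seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `auc_ci_low`, `auc_ci_high`, `youden_cutoff`,
#'   `youden_index`, and `roc_points` (data.frame `threshold`, `sensitivity`,
#'   `specificity`).
#' @export
roc_analysis <- function(scores, labels, boot_reps = 2000, seed = 1,
                         conf = 0.95) {
  pos <- as_positive_labels(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  pts <- roc_points(scores, pos)
  auc <- roc_auc(scores, pos)
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j > max(j) - 1e-12)  # floating-point ties count as ties
  best <- best[which.min(pts$threshold[best])]
  ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    ip <- which(pos); ineg <- which(!pos)
    aucs <- with_seed(seed, vapply(seq_len(boot_reps), function(r) {
      bi <- c(sample(ip, length(ip), replace = TRUE),
              sample(ineg, length(ineg), replace = TRUE))
      roc_auc(scores[bi], pos[bi])
    }, numeric(1)))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(aucs, c(a, 1 - a), type = 7))
  }
  list(auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
       youden_cutoff = pts$threshold[best], youden_index = max(j),
       roc_points = pts)
}

# sensitivity/specificity at every distinct observed threshold (>= rule)
roc_points <- function(scores, pos) {
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(c) mean(scores[pos] >= c), numeric(1))
  spec <- vapply(thr, function(c) mean(scores[!pos] < c), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

# trapezoidal AUC == pairwise concordance with ties counted 1/2
roc_auc <- function(scores, pos) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full diagnostic report for one score series
#'
#' @param scores numeric scores; @param labels class labels.
#' @param cutoff fixed decision cutoff (default 1).
#' @param boot_reps,seed bootstrap settings for the AUC CI.
#' @return list combining [classify_at_cutoff()] at `cutoff`, the ROC
#'   analysis, and the classification re-done at the Youden cutoff.
#' @export
diagnostic_report <- function(scores, labels, cutoff = 1,
                              boot_reps = 2000, seed = 1) {
  fixed <- classify_at_cutoff(scores, labels, cutoff)
  roc <- roc_analysis(scores, labels, boot_reps = boot_reps, seed = seed)
  at_youden <- classify_at_cutoff(scores, labels, roc$youden_cutoff)
  list(at_cutoff = fixed, roc = roc, at_youden = at_youden)
}
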