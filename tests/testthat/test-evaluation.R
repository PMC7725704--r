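make_tables <- function(n_subj = 5, n_maps = 3, method = "ZTE_like",
                        seed = 51) {
  set.seed(seed)
  orig <- data.frame(subject_id = sprintf("s%d", 1:n_subj),
                     error_map_id = "original", method = "original",
                     pet_score = rnorm(n_subj))
  sim <- expand.grid(subject_id = orig$subject_id,
                     error_map_id = sprintf("m%d", 1:n_maps),
                     stringsAsFactors = FALSE)
  sim$method <- method
  sim$pet_score <- orig$pet_score[match(sim$subject_id, orig$subject_id)] +
    rnorm(nrow(sim), 0, 0.1)
  list(orig = orig, sim = sim)
}

test_that("score-difference summaries match their definitions and an oracle", {
  tt <- make_tables()
  same <- tt$sim
  same$pet_score <- tt$orig$pet_score[match(same$subject_id, tt$orig$subject_id)]
  s0 <- score_difference_stats(same, tt$orig)
  expect_equal(s0$mean_diff, 0)
  expect_equal(s0$sd_diff, 0)
  expect_equal(s0$max_abs_diff, 0)

  shifted <- same
  shifted$pet_score <- shifted$pet_score - 0.1
  s1 <- score_difference_stats(shifted, tt$orig)
  expect_equal(s1$mean_diff, -0.1)
  expect_equal(s1$mean_abs_diff, 0.1)
  expect_equal(s1$sd_diff, 0)

  # random table vs scalar loop
  s2 <- score_difference_stats(tt$sim, tt$orig)
  d <- numeric(nrow(tt$sim))
  for (i in seq_len(nrow(tt$sim)))
    d[i] <- tt$sim$pet_score[i] -
      tt$orig$pet_score[tt$orig$subject_id == tt$sim$subject_id[i]]
  expect_equal(s2$mean_diff, mean(d))
  expect_equal(s2$sd_diff, sd(d))
  expect_equal(s2$max_diff, max(d))
  expect_equal(s2$min_diff, min(d))
  expect_equal(s2$mean_abs_diff, mean(abs(d)))

  bad <- tt$sim; bad$subject_id[1] <- "ghost"
  expect_error(score_difference_stats(bad, tt$orig), "key mismatch")
})

test_that("paired t-test matches the closed-form oracle and degenerates sanely", {
  set.seed(52)
  for (case in 1:100) {
    n <- sample(5:20, 1)
    a <- runif(n); b <- a + rnorm(n, 0.05, 0.1)
    got <- paired_ttest_abs(a, b)
    want <- oracle_paired_t(a, b)
    expect_equal(got$t, unname(want["t"]), tolerance = 1e-12)
    expect_equal(got$p_value, unname(want["p"]), tolerance = 1e-12)
  }
  a <- c(1, 2, 3)
  expect_error(paired_ttest_abs(a, a), "zero-variance")
  jit <- c(0.01, -0.02, 0.011)
  up <- paired_ttest_abs(a + 0.5 + jit, a)
  expect_gt(up$t, 0)
  down <- paired_ttest_abs(a - 0.5 + jit, a)
  expect_lt(down$t, 0)
})

test_that("per-subject averaging matches a group-by oracle and detects holes", {
  tt <- make_tables(n_subj = 6, n_maps = 4)
  ps <- per_subject_average(tt$sim)
  expect_equal(nrow(ps), 6)
  for (i in seq_len(nrow(ps))) {
    rows <- tt$sim$pet_score[tt$sim$subject_id == ps$subject_id[i]]
    expect_equal(ps$mean_score[i], mean(rows))
    expect_equal(ps$n_maps[i], 4)
  }
  # single map: averages equal raw scores
  one <- tt$sim[tt$sim$error_map_id == "m1", ]
  ps1 <- per_subject_average(one)
  expect_equal(ps1$mean_score[match(one$subject_id, ps1$subject_id)],
               one$pet_score)
  holey <- tt$sim[-1, ]
  expect_error(per_subject_average(holey), "missing cells")
})

test_that("agreement regression matches closed-form OLS", {
  x <- c(0.1, 0.5, 0.9, 1.3, 2.0)
  r1 <- regression_agreement(x, x)
  expect_equal(r1$slope, 1)
  expect_equal(r1$intercept, 0, tolerance = 1e-12)
  expect_equal(r1$r_squared, 1)
  r2 <- regression_agreement(x, 0.9 * x + 0.05)
  expect_equal(r2$slope, 0.9, tolerance = 1e-12)
  expect_equal(r2$intercept, 0.05, tolerance = 1e-12)
  expect_equal(r2$r_squared, 1)
  set.seed(53)
  for (case in 1:30) {
    n <- sample(5:20, 1)
    xx <- rnorm(n); yy <- 0.8 * xx + rnorm(n, 0, 0.3)
    got <- regression_agreement(xx, yy)
    o <- oracle_ols_voxel(xx, yy)
    expect_equal(got$slope, unname(o["b"]), tolerance = 1e-12)
    expect_equal(got$intercept, unname(o["a"]), tolerance = 1e-12)
    expect_equal(got$r_squared, cor(xx, yy)^2, tolerance = 1e-12)
  }
  expect_error(regression_agreement(rep(1, 5), rnorm(5)), "constant x")
})

test_that("Bland-Altman bias and limits of agreement match the formula", {
  x <- c(1, 2, 3, 4)
  b0 <- bland_altman(x, x)
  expect_equal(b0$bias, 0)
  expect_equal(b0$loa_low, 0)
  expect_equal(b0$loa_high, 0)
  b1 <- bland_altman(x, x + 0.5)
  expect_equal(b1$bias, 0.5)
  expect_equal(b1$loa_low, 0.5)
  expect_equal(b1$loa_high, 0.5)
  set.seed(54)
  for (case in 1:50) {
    n <- sample(5:20, 1)
    xx <- rnorm(n); yy <- xx + rnorm(n, 0.1, 0.2)
    got <- bland_altman(xx, yy)
    o <- oracle_bland_altman(xx, yy)
    expect_equal(got$bias, unname(o["bias"]), tolerance = 1e-12)
    expect_equal(got$loa_low, unname(o["lo"]), tolerance = 1e-12)
    expect_equal(got$loa_high, unname(o["hi"]), tolerance = 1e-12)
    expect_true(got$loa_low <= got$bias && got$bias <= got$loa_high)
  }
})

test_that("LOA contain about 95% of Gaussian differences", {
  set.seed(55)
  cover <- vapply(1:200, function(r) {
    x <- rnorm(300); y <- x + rnorm(300, 0, 0.5)
    ba <- bland_altman(x, y)
    d <- y - x
    mean(d >= ba$loa_low & d <= ba$loa_high)
  }, numeric(1))
  expect_equal(mean(cover), 0.95, tolerance = 0.01)
})

test_that("fixed-cutoff classification matches exhaustive hand counts", {
  scores <- c(0.2, 0.4, 0.6, 0.9, 1.0, 1.1, 1.4, 0.8, 1.2, 0.3)
  labels <- c("NC", "NC", "NC", "NC", "AD", "AD", "AD", "AD", "AD", "NC")
  rep <- classify_at_cutoff(scores, labels, cutoff = 1)
  # hand count: AD scores {1.0, 1.1, 1.4, 0.8, 1.2} -> 4 >= 1; NC all < 1
  expect_equal(rep$tp, 4); expect_equal(rep$fn, 1)
  expect_equal(rep$tn, 5); expect_equal(rep$fp, 0)
  expect_equal(rep$sensitivity$estimate, 0.8)
  expect_equal(rep$specificity$estimate, 1)
  expect_equal(rep$accuracy$estimate, 0.9)
  # CI brackets the estimate
  for (m in list(rep$accuracy, rep$sensitivity, rep$specificity)) {
    expect_true(m$ci_low <= m$estimate && m$estimate <= m$ci_high)
    expect_true(m$ci_low >= 0 && m$ci_high <= 1)
  }
  # perfectly separated
  sep <- classify_at_cutoff(c(0, 0.1, 2, 3), c(FALSE, FALSE, TRUE, TRUE), 1)
  expect_equal(sep$accuracy$estimate, 1)
  # all below cutoff
  low <- classify_at_cutoff(c(0.1, 0.2, 0.3, 0.4), c(F, F, T, T), 1)
  expect_equal(low$sensitivity$estimate, 0)
  expect_equal(low$specificity$estimate, 1)
  expect_error(classify_at_cutoff(1:3, c(T, T, T), 1), "both classes")
})

test_that("Wilson interval agrees with stats::prop.test-free closed form", {
  # spot check against published Wilson values: k=8, n=10, z=1.96
  ci <- petscoresim:::wilson_ci(8, 10)
  expect_equal(ci[1], 0.4901, tolerance = 1e-3)
  expect_equal(ci[2], 0.9433, tolerance = 1e-3)
})

test_that("ROC/AUC/Youden match brute-force oracles on random instances", {
  set.seed(56)
  for (case in 1:100) {
    n <- sample(8:20, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    pos <- runif(n) > 0.5
    if (!any(pos) || all(pos)) next
    got <- roc_analysis(scores, pos, boot_reps = 0)
    expect_equal(got$auc, oracle_auc(scores, pos), tolerance = 1e-12)
    o <- oracle_youden(scores, pos)
    expect_equal(got$youden_cutoff, unname(o["cutoff"]))
    expect_equal(got$youden_index, unname(o["j"]), tolerance = 1e-12)
  }
})

test_that("ROC edge cases and the independent pROC cross-check", {
  sep <- roc_analysis(c(0.1, 0.2, 1.5, 1.9), c(F, F, T, T), boot_reps = 0)
  expect_equal(sep$auc, 1)
  tied <- roc_analysis(rep(1, 6), c(T, T, T, F, F, F), boot_reps = 0)
  expect_equal(tied$auc, 0.5)
  skip_if_not_installed("pROC")
  set.seed(57)
  for (case in 1:20) {
    n <- sample(10:30, 1)
    scores <- rnorm(n)
    pos <- runif(n) > 0.4
    if (!any(pos) || all(pos)) next
    got <- roc_analysis(scores, pos, boot_reps = 0)
    ref <- suppressMessages(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                                direction = "<")))
    expect_equal(got$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(58)
  scores <- rnorm(30)
  pos <- runif(30) > 0.5
  a0 <- roc_analysis(scores, pos, boot_reps = 0)$auc
  expect_equal(roc_analysis(exp(scores), pos, boot_reps = 0)$auc, a0)
  expect_equal(roc_analysis(3 * scores + 7, pos, boot_reps = 0)$auc, a0)
})

test_that("classification at the Youden cutoff attains the maximal Youden index", {
  set.seed(59)
  for (case in 1:20) {
    scores <- round(rnorm(15), 1)
    pos <- runif(15) > 0.5
    if (!any(pos) || all(pos)) next
    roc <- roc_analysis(scores, pos, boot_reps = 0)
    rep <- classify_at_cutoff(scores, pos, roc$youden_cutoff)
    j_at <- rep$sensitivity$estimate + rep$specificity$estimate - 1
    expect_equal(j_at, roc$youden_index, tolerance = 1e-12)
  }
})

test_that("bootstrap AUC CI is seeded-reproducible and brackets the estimate", {
  set.seed(60)
  scores <- rnorm(40, mean = ifelse(rep(c(TRUE, FALSE), 20), 1, 0))
  pos <- rep(c(TRUE, FALSE), 20)
  r1 <- roc_analysis(scores, pos, boot_reps = 500, seed = 3)
  r2 <- roc_analysis(scores, pos, boot_reps = 500, seed = 3)
  expect_identical(r1$auc_ci_low, r2$auc_ci_low)
  expect_true(r1$auc_ci_low <= r1$auc && r1$auc <= r1$auc_ci_high)
})
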