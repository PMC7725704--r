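# Independent brute-force oracles: scalar loops and closed forms kept
# deliberately naive, never sharing code with the implementation.

# per-voxel OLS of y on age, one scalar regression at a time
oracle_ols_voxel <- function(ages, y) {
  n <- length(ages)
  xb <- sum(ages) / n
  yb <- sum(y) / n
  sxx <- sum((ages - xb)^2)
  b <- sum((ages - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  res <- y - (a + b * ages)
  s <- sqrt(sum(res^2) / (n - 2))
  c(a = a, b = b, s = s)
}

# t-map by looping over every voxel with the prediction-SE formula
oracle_tmap <- function(x_arr, age, a_arr, b_arr, s_arr, n, mean_age, s_xx,
                        brain_arr) {
  d <- dim(x_arr)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (brain_arr[i, j, k]) {
      exp_v <- a_arr[i, j, k] + b_arr[i, j, k] * age
      se <- s_arr[i, j, k] * sqrt(1 + 1 / n + (age - mean_age)^2 / s_xx)
      out[i, j, k] <- (exp_v - x_arr[i, j, k]) / se
    }
  }
  out
}

# naive summation over mask voxels
oracle_tsum <- function(t_arr, mask_arr) {
  tot <- 0
  for (v in seq_along(t_arr)) if (mask_arr[v]) tot <- tot + t_arr[v]
  tot
}

# paired t statistic from the closed form
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  c(t = t, p = p)
}

# AUC as pairwise concordance with ties counted 1/2
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (i in seq_along(sp)) for (j in seq_along(sn)) {
    tot <- tot + if (sp[i] > sn[j]) 1 else if (sp[i] == sn[j]) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# exhaustive Youden scan over observed thresholds, >= rule, lowest on ties
oracle_youden <- function(scores, pos) {
  thr <- sort(unique(scores))
  best_j <- -Inf
  best_c <- NA
  for (c in thr) {
    sens <- sum(scores[pos] >= c) / sum(pos)
    spec <- sum(scores[!pos] < c) / sum(!pos)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- c
    }
  }
  c(cutoff = best_c, j = best_j)
}

# Bland-Altman from first principles
oracle_bland_altman <- function(x, y) {
  d <- y - x
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  c(bias = m, lo = m - 1.96 * s, hi = m + 1.96 * s)
}
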