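test_that("intensity normalization yields unit mask mean and scale invariance", {
  m <- tiny_masks()
  set.seed(31)
  v <- rand_volume(c(16, 16, 16))
  nrm <- intensity_normalize(v, m$preserved)
  expect_equal(mean(nrm$volume$data[m$preserved$data]), 1, tolerance = 1e-12)
  expect_equal(nrm$normalization_factor, mean(v$data[m$preserved$data]))
  # multiplying the input by any c > 0 leaves the normalized output unchanged
  v2 <- brain_volume(v$data * 3.7)
  nrm2 <- intensity_normalize(v2, m$preserved)
  expect_equal(nrm2$volume$data, nrm$volume$data, tolerance = 1e-14)
  # constant c inside brain -> constant 1 inside brain
  arr <- array(0, c(16, 16, 16)); arr[m$brain$data] <- 2.5
  nc <- intensity_normalize(brain_volume(arr), m$preserved)
  expect_true(all(nc$volume$data[m$brain$data] == 1))
  # degenerate mask mean
  expect_error(intensity_normalize(brain_volume(array(0, c(16, 16, 16))),
                                   m$preserved), "degenerate")
})

test_that("age regression recovers a noise-free linear model exactly", {
  ts <- tiny_study(noise = 0)
  region <- ts$masks$brain$data & !ts$masks$preserved$data
  # normalized uptake = base*(1 + slope*(age-ref)/base)/base; with base 1 and
  # preserved mean 1, normalized slope equals the phantom slope
  expect_equal(ts$db$slope[region],
               rep(ts$params$age_slope_per_year, sum(region)),
               tolerance = 1e-10)
  expect_equal(ts$db$resid_sd[region], rep(ts$db$s_floor, sum(region)))
  # zero age effect in the preserved region
  expect_equal(max(abs(ts$db$slope[ts$masks$preserved$data])), 0,
               tolerance = 1e-12)
})

test_that("age regression matches a voxel-by-voxel closed-form OLS oracle", {
  set.seed(32)
  for (case in 1:25) {
    n <- sample(4:8, 1)
    d <- c(3, 2, 2)
    ages <- runif(n, 55, 85)
    vols <- array(runif(prod(d) * n, 0.5, 1.5), c(d, n))
    masks <- list(
      brain = volume_mask(array(TRUE, d), "brain"),
      preserved = volume_mask(array(TRUE, d), "preserved_uptake"))
    subs <- lapply(seq_len(n), function(i)
      subject_scan(brain_volume(array(vols[, , , i], d)), ages[i], "NC",
                   sprintf("s%d", i)))
    cfg <- scoring_config(pre_normalized = TRUE, s_floor = 1e-12)
    db <- fit_age_regression(cohort(subs), masks, cfg)
    # oracle on the normalized volumes, voxel by voxel
    normd <- vapply(seq_len(n), function(i) {
      a <- vols[, , , i]
      as.vector(a / mean(a))
    }, numeric(prod(d)))
    for (v in seq_len(prod(d))) {
      o <- oracle_ols_voxel(ages, normd[v, ])
      expect_equal(as.vector(db$intercept)[v], o["a"], tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(as.vector(db$slope)[v], o["b"], tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(as.vector(db$resid_sd)[v], max(o["s"], 1e-12),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
  expect_error(fit_age_regression(
    cohort(lapply(1:3, function(i)
      subject_scan(brain_volume(array(1, c(2, 2, 2))), 70, "NC", paste0("s", i)))),
    list(brain = volume_mask(array(TRUE, c(2, 2, 2)), "brain"),
         preserved = volume_mask(array(TRUE, c(2, 2, 2)), "preserved_uptake"))),
    "degenerate age design")
})

test_that("t-map is zero for a subject equal to its prediction and matches the oracle", {
  ts <- tiny_study(noise = 0)
  s <- simulate_scan(ts$params, ts$masks, age = 68, diagnosis = "NC")
  nrm <- intensity_normalize(s$volume, ts$masks$preserved)$volume
  t0 <- compute_tmap(subject_scan(nrm, 68, "NC", "zero"), ts$db, ts$masks$brain)
  expect_true(all(t0$data == 0))

  # random small instances vs the scalar-loop oracle
  set.seed(33)
  for (case in 1:20) {
    d <- c(4, 4, 4)
    n <- 6
    db <- structure(list(
      intercept = array(runif(prod(d), 0.8, 1.2), d),
      slope = array(runif(prod(d), -0.01, 0.01), d),
      resid_sd = array(runif(prod(d), 0.05, 0.2), d),
      n_controls = n, mean_age = 70, s_xx = 800, s_floor = 1e-6,
      age_range = c(55, 85), grid_shape = d, voxel_size_mm = c(2, 2, 2),
      pre_normalized = TRUE, fwhm_mm = c(0, 0, 0)), class = "normal_db")
    brain <- volume_mask(array(runif(prod(d)) > 0.3, d) |
                           array(c(TRUE, rep(FALSE, prod(d) - 1)), d), "brain")
    x <- brain_volume(array(runif(prod(d), 0.5, 1.5), d))
    age <- runif(1, 57, 83)
    got <- compute_tmap(subject_scan(x, age, "NC", "s"), db, brain)
    want <- oracle_tmap(x$data, age, db$intercept, db$slope, db$resid_sd,
                        n, db$mean_age, db$s_xx, brain$data)
    expect_equal(got$data, want, tolerance = 1e-12)
  }
})

test_that("a one-SE deviation gives t = +1 at that voxel", {
  ts <- tiny_study(noise = 0)
  s <- simulate_scan(ts$params, ts$masks, age = 70, diagnosis = "NC")
  nrm <- intensity_normalize(s$volume, ts$masks$preserved)$volume
  idx <- which(ts$masks$brain$data)[1]
  age <- 70
  se <- ts$db$resid_sd[idx] *
    sqrt(1 + 1 / ts$db$n_controls + (age - ts$db$mean_age)^2 / ts$db$s_xx)
  arr <- nrm$data
  arr[idx] <- (ts$db$intercept[idx] + ts$db$slope[idx] * age) - se
  tm <- compute_tmap(subject_scan(brain_volume(arr), age, "NC", "s"),
                     ts$db, ts$masks$brain)
  expect_equal(tm$data[idx], 1, tolerance = 1e-9)
})

test_that("AD t-sum is plain unthresholded summation over the AD mask", {
  d <- c(5, 5, 5)
  mask <- volume_mask(array(runif(prod(d)) > 0.5, d) |
                        array(c(TRUE, rep(FALSE, prod(d) - 1)), d), "ad_pattern")
  zero <- brain_volume(array(0, d))
  expect_equal(ad_tsum(zero, mask), 0)
  two <- brain_volume(array(2, d))
  expect_equal(ad_tsum(two, mask), 2 * sum(mask$data))
  set.seed(34)
  for (case in 1:20) {
    tm <- brain_volume(array(rnorm(prod(d)), d))
    expect_equal(ad_tsum(tm, mask), oracle_tsum(tm$data, mask$data))
  }
})

test_that("PET score formula hits its anchor points and is strictly increasing", {
  expect_identical(pet_score(11089), 1)
  expect_identical(pet_score(0), 0)
  expect_equal(pet_score(3 * 11089), 2)
  ts <- seq(-5000, 50000, length.out = 200)
  expect_true(all(diff(pet_score(ts)) > 0))
  expect_error(pet_score(-2 * 11089), "pathological")
})

test_that("score_subject is deterministic, scale invariant and severity-monotone", {
  ts <- tiny_study(grid = c(16, 16, 16), noise = 0)
  s <- simulate_scan(ts$params, ts$masks, age = 66, diagnosis = "NC")
  r1 <- score_subject(s, ts$db, ts$masks, ts$cfg)
  r2 <- score_subject(s, ts$db, ts$masks, ts$cfg)
  expect_identical(r1$pet_score, r2$pet_score)
  expect_equal(r1$pet_score, 0, tolerance = 1e-9)  # db-generator NC, noise 0

  # global rescaling is absorbed by intensity normalization
  s_scaled <- subject_scan(brain_volume(s$volume$data * 123.4), 66, "NC", "sc")
  r3 <- score_subject(s_scaled, ts$db, ts$masks, ts$cfg)
  expect_equal(r3$pet_score, r1$pet_score, tolerance = 1e-10)

  # AD severity strictly increases the t-sum, and AD scores beat the NC twin
  scores <- vapply(c(0.05, 0.1, 0.2, 0.3), function(sev) {
    p <- phantom_params(grid_shape = c(16, 16, 16), subject_noise_sd = 0,
                        ad_severity = sev)
    ad <- simulate_scan(p, ts$masks, age = 66, diagnosis = "AD")
    score_subject(ad, ts$db, ts$masks, ts$cfg)$ad_tsum
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_gt(scores[1], r1$ad_tsum)
})

test_that("out-of-range subject age triggers a warning, not an error", {
  ts <- tiny_study(noise = 0)
  s <- simulate_scan(ts$params, ts$masks, age = 99, diagnosis = "NC")
  nrm <- intensity_normalize(s$volume, ts$masks$preserved)$volume
  expect_warning(compute_tmap(subject_scan(nrm, 99, "NC", "old"),
                              ts$db, ts$masks$brain), "far outside")
})
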