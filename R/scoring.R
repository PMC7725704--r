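# PALZ-style automated AD-probability scoring: smoothing, intensity
# normalization against a preserved-uptake mask, voxelwise age regression
# against a normal-control database, per-voxel t-values, AD t-sum and
# PET score = log2(AD t-sum / K + 1) with K = 11089, the published 95%
# prediction limit of the AD t-sum.

#' Scoring configuration
#'
#' @param fwhm_mm Gaussian smoothing FWHM per axis, mm (default 12).
#' @param tsum_constant normalization constant K of the PET score
#'   (default 11089, the 95% prediction limit of the AD t-sum).
#' @param s_floor lower floor for the per-voxel residual SD; `NULL` (the
#'   default) uses 1e-6 times the mean normalized uptake over the brain,
#'   which keeps t-values finite for noise-free synthetic databases.
#' @param pre_normalized if `TRUE`, subjects enter scoring without
#'   re-smoothing (simulated images already live on the template grid and
#'   need no further filtering); intensity normalization is always applied.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(fwhm_mm = c(12, 12, 12), tsum_constant = 11089,
                           s_floor = NULL, pre_normalized = FALSE) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  if (any(fwhm_mm < 0)) stop("`fwhm_mm` must be >= 0")
  if (tsum_constant <= 0) stop("`tsum_constant` must be positive")
  structure(list(fwhm_mm = fwhm_mm, tsum_constant = tsum_constant,
                 s_floor = s_floor, pre_normalized = isTRUE(pre_normalized)),
            class = "scoring_config")
}

#' Intensity normalization against the preserved-uptake mask
#'
#' Divides every voxel by the mean voxel value over the preserved-uptake
#' mask (regions whose FDG uptake is typically spared in AD), removing
#' global scaling; the output mean over the mask is exactly 1.
#'
#' @param vol a `brain_volume`.
#' @param preserved preserved-uptake `volume_mask` on the same grid.
#' @return list with `volume` (normalized `brain_volume`) and
#'   `normalization_factor` (the mask mean that was divided out).
#' @export
intensity_normalize <- function(vol, preserved) {
  stopifnot(inherits(vol, "brain_volume"), inherits(preserved, "volume_mask"))
  check_same_grid(vol, preserved, "volume and preserved mask")
  f <- mean(vol$data[preserved$data])
  if (!is.finite(f) || f <= 0)
    stop("degenerate input: nonpositive mean over preserved-uptake mask")
  list(volume = brain_volume(vol$data / f, vol$voxel_size_mm, vol$space_tag),
       normalization_factor = f)
}

#' Fit the voxelwise age-regression normal database
#'
#' Ordinary least squares of normalized uptake on age, per voxel, over the
#' normal-control subjects: intercept `a_v`, slope `b_v`, residual SD `s_v`
#' (denominator n - 2), floored at `s_floor`. Unless
#' `config$pre_normalized`, each control is smoothed then
#' intensity-normalized first.
#'
#' @param controls a `cohort`; AD subjects are rejected.
#' @param masks mask list (brain + preserved) from [make_template_masks()].
#' @param config a [scoring_config()].
#' @return A `normal_db` with per-voxel arrays `intercept`, `slope`,
#'   `resid_sd`, and scalars `n_controls`, `mean_age`, `s_xx`, `s_floor`,
#'   plus provenance flags.
#' @export
fit_age_regression <- function(controls, masks, config = scoring_config()) {
  stopifnot(inherits(controls, "cohort"))
  dx <- vapply(controls, `[[`, character(1), "diagnosis")
  if (any(dx != "NC")) stop("normal database must be fit on NC subjects only")
  n <- length(controls)
  if (n < 3L) stop("need >= 3 control subjects")
  ages <- vapply(controls, `[[`, numeric(1), "age")
  if (length(unique(ages)) < 2L) stop("degenerate age design: all ages identical")
  check_same_grid(controls[[1]]$volume, masks$brain, "controls and brain mask")
  prep <- function(s) {
    v <- s$volume
    if (!config$pre_normalized) v <- smooth_gaussian(v, config$fwhm_mm)
    intensity_normalize(v, masks$preserved)$volume$data
  }
  d <- controls[[1]]$volume$grid_shape
  Y <- vapply(controls, prep, numeric(prod(d)))   # voxels x subjects
  xbar <- mean(ages)
  xc <- ages - xbar
  s_xx <- sum(xc^2)
  ybar <- rowMeans(Y)
  b <- as.vector(Y %*% xc) / s_xx
  a <- ybar - b * xbar
  resid <- Y - outer(a, rep(1, n)) - outer(b, ages)
  s <- sqrt(rowSums(resid^2) / (n - 2))
  s_floor <- config$s_floor
  if (is.null(s_floor)) {
    brain <- masks$brain$data
    s_floor <- 1e-6 * mean(ybar[as.vector(brain)])
    if (!is.finite(s_floor) || s_floor <= 0) s_floor <- 1e-6
  }
  s <- pmax(s, s_floor)
  structure(list(intercept = array(a, d), slope = array(b, d),
                 resid_sd = array(s, d), n_controls = n,
                 mean_age = xbar, s_xx = s_xx, s_floor = s_floor,
                 age_range = range(ages),
                 grid_shape = d,
                 voxel_size_mm = controls[[1]]$volume$voxel_size_mm,
                 pre_normalized = config$pre_normalized,
                 fwhm_mm = config$fwhm_mm),
            class = "normal_db")
}

#' @export
print.normal_db <- function(x, ...) {
  cat(sprintf("<normal_db> n=%d controls, mean age %.1f, grid %s, s_floor %.2e\n",
              x$n_controls, x$mean_age,
              paste(x$grid_shape, collapse = "x"), x$s_floor))
  invisible(x)
}

#' Voxelwise t-map of a subject against the normal database
#'
#' Per voxel, the expected value is `a_v + b_v * age`; the t-value compares
#' the subject's (smoothed, normalized) uptake to it with the
#' single-new-observation prediction standard error:
#' `t_v = (expected - observed) / (s_v * sqrt(1 + 1/n + (age - mean_age)^2 / S_xx))`.
#' The `expected - observed` sign makes hypometabolism positive, so the AD
#' t-sum grows with disease severity. Zero outside the brain mask.
#'
#' @param subject a `subject_scan` whose volume is already smoothed and
#'   intensity-normalized.
#' @param db a `normal_db` from [fit_age_regression()].
#' @param brain brain `volume_mask`.
#' @return t-map as a `brain_volume` (dimensionless).
#' @export
compute_tmap <- function(subject, db, brain) {
  stopifnot(inherits(subject, "subject_scan"), inherits(db, "normal_db"))
  check_same_grid(subject$volume, brain, "subject and brain mask")
  check_same_grid(subject$volume, array(0, db$grid_shape), "subject and normal db")
  age <- subject$age
  if (age < db$age_range[1] - 5 || age > db$age_range[2] + 5)
    warning(sprintf("age %.1f is far outside the database range [%.1f, %.1f]",
                    age, db$age_range[1], db$age_range[2]))
  expected <- db$intercept + db$slope * age
  se_infl <- sqrt(1 + 1 / db$n_controls + (age - db$mean_age)^2 / db$s_xx)
  t <- (expected - subject$volume$data) / (db$resid_sd * se_infl)
  t[!brain$data] <- 0
  brain_volume(t, subject$volume$voxel_size_mm)
}

#' AD t-sum: sum of t-values over the AD-pattern mask
#'
#' Plain summation with no thresholding; negative t-values (relative
#' hypermetabolism) are included, so the sum — and hence the PET score —
#' can be negative.
#'
#' @param t_map t-map `brain_volume` from [compute_tmap()].
#' @param ad_pattern AD-pattern `volume_mask`.
#' @return Scalar sum.
#' @export
ad_tsum <- function(t_map, ad_pattern) {
  stopifnot(inherits(t_map, "brain_volume"), inherits(ad_pattern, "volume_mask"))
  check_same_grid(t_map, ad_pattern, "t-map and AD-pattern mask")
  if (!any(ad_pattern$data)) stop("empty AD-pattern mask")
  sum(t_map$data[ad_pattern$data])
}

#' PET score
#'
#' `pet_score = log2(ad_tsum / K + 1)` with `K = 11089` by default, so a
#' t-sum of 0 maps to 0 and a t-sum equal to K (the 95% prediction limit
#' of AD) maps to exactly 1.
#'
#' @param ad_tsum AD t-sum (vectorized).
#' @param K normalization constant, > 0.
#' @return PET score(s).
#' @export
pet_score <- function(ad_tsum, K = 11089) {
  if (K <= 0) stop("`K` must be positive")
  arg <- ad_tsum / K + 1
  if (any(arg <= 0))
    stop("pathological AD t-sum: ad_tsum/K + 1 must be positive")
  log2(arg)
}

#' Score one subject through the full pipeline
#'
#' Composes smoothing (skipped when `config$pre_normalized`), intensity
#' normalization, the t-map, the AD t-sum and the PET score. Deterministic.
#'
#' @param subject a `subject_scan` (raw template-space uptake).
#' @param db a `normal_db`.
#' @param masks mask list (brain, preserved, ad_pattern).
#' @param config a [scoring_config()]; should match the one used to fit `db`.
#' @return A `score_result` with `t_map`, `ad_tsum`, `pet_score` and
#'   `normalization_factor`.
#' @export
score_subject <- function(subject, db, masks, config = scoring_config()) {
  stopifnot(inherits(subject, "subject_scan"))
  v <- subject$volume
  if (!config$pre_normalized) v <- smooth_gaussian(v, config$fwhm_mm)
  nrm <- intensity_normalize(v, masks$preserved)
  norm_subj <- subject_scan(nrm$volume, subject$age, subject$diagnosis,
                            subject$subject_id)
  tmap <- compute_tmap(norm_subj, db, masks$brain)
  ts <- ad_tsum(tmap, masks$ad_pattern)
  structure(list(t_map = tmap, ad_tsum = ts,
                 pet_score = pet_score(ts, config$tsum_constant),
                 normalization_factor = nrm$normalization_factor,
                 subject_id = subject$subject_id),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> %s: AD t-sum %.2f, PET score %.4f (norm factor %.4g)\n",
              x$subject_id, x$ad_tsum, x$pet_score, x$normalization_factor))
  invisible(x)
}
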