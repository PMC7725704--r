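# Synthetic study inputs: template masks, brain-PET phantoms with a linear
# age effect and regional AD hypometabolism, and smooth skull-weighted
# multiplicative attenuation-error fields.

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so generators are pure functions of (params, seed)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom generation parameters
#'
#' @param grid_shape integer length-3 grid extents (default 32^3; the full
#'   template proxy is 91x109x91).
#' @param voxel_size_mm voxel edge lengths in mm (default 2 mm isotropic).
#' @param base_uptake gray-matter plateau uptake, arbitrary units > 0.
#' @param age_slope_per_year uptake change per year of age (<= 0), applied
#'   inside the age-sensitive region (brain minus preserved-uptake mask).
#' @param reference_age age (years) at which NC uptake equals `base_uptake`.
#' @param subject_noise_sd voxelwise multiplicative lognormal noise SD, as a
#'   fraction of the local mean (0 = noise-free).
#' @param ad_severity fraction in [0, 1) multiplicatively removed inside the
#'   AD-pattern mask for AD subjects.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(32, 32, 32),
                           voxel_size_mm = c(2, 2, 2),
                           base_uptake = 1,
                           age_slope_per_year = -0.005,
                           reference_age = 70,
                           subject_noise_sd = 0.10,
                           ad_severity = 0.15) {
  if (ad_severity < 0 || ad_severity >= 1)
    stop("`ad_severity` must be in [0, 1)")
  if (subject_noise_sd < 0) stop("`subject_noise_sd` must be >= 0")
  if (base_uptake <= 0) stop("`base_uptake` must be positive")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 base_uptake = base_uptake,
                 age_slope_per_year = age_slope_per_year,
                 reference_age = reference_age,
                 subject_noise_sd = subject_noise_sd,
                 ad_severity = ad_severity),
            class = "phantom_params")
}

#' Build the template masks (brain, preserved-uptake, AD-pattern)
#'
#' The brain is a filled ellipsoid centred in the grid. The AD-pattern mask
#' is the posterior-superior sector of the brain (a geometric proxy for the
#' temporoparietal / posterior cingulate hypometabolism pattern); the
#' preserved-uptake mask is the disjoint anterior-inferior sector (proxy
#' for regions whose FDG uptake is typically spared in AD). Deterministic:
#' no RNG involved.
#'
#' @param grid_shape integer length-3, at least 16 voxels per axis.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return list with `volume_mask` elements `brain`, `preserved`,
#'   `ad_pattern`; each has >= 100 voxels, both sectors are subsets of the
#'   brain, and the sectors are disjoint.
#' @export
make_template_masks <- function(grid_shape = c(32, 32, 32),
                                voxel_size_mm = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 16L))
    stop("grid must be at least 16 voxels per axis")
  ctr <- (grid_shape + 1) / 2
  semi <- 0.45 * grid_shape
  ix <- (seq_len(grid_shape[1]) - ctr[1]) / semi[1]
  iy <- (seq_len(grid_shape[2]) - ctr[2]) / semi[2]
  iz <- (seq_len(grid_shape[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(ix^2, iy^2, `+`), iz^2, `+`)
  brain <- r2 <= 1
  # RAS axes: x left-right, y posterior-anterior, z inferior-superior
  ygrid <- array(rep(seq_len(grid_shape[2]), each = grid_shape[1]), grid_shape)
  zgrid <- aperm(array(rep(seq_len(grid_shape[3]), each = grid_shape[1]),
                       grid_shape[c(1, 3, 2)]), c(1, 3, 2))
  ad <- brain & (ygrid < ctr[2]) & (zgrid > ctr[3])
  preserved <- brain & (ygrid > ctr[2]) & (zgrid < ctr[3])
  counts <- c(brain = sum(brain), preserved = sum(preserved), ad = sum(ad))
  if (any(counts < 100L))
    stop(sprintf("grid too small: mask voxel counts %s (need >= 100 each)",
                 paste(names(counts), counts, sep = "=", collapse = ", ")))
  list(brain = volume_mask(brain, "brain"),
       preserved = volume_mask(preserved, "preserved_uptake"),
       ad_pattern = volume_mask(ad, "ad_pattern"))
}

#' Simulate one subject's PET scan
#'
#' Uptake equals `base_uptake` inside the brain and 0 outside, plus
#' `age_slope_per_year * (age - reference_age)` inside the age-sensitive
#' region (brain minus preserved mask), times `(1 - ad_severity)` inside the
#' AD-pattern mask when `diagnosis == "AD"`, times voxelwise lognormal noise
#' with unit mean and SD `subject_noise_sd`. All values are >= 0.
#'
#' @param params a [phantom_params()] object.
#' @param masks mask list from [make_template_masks()] on the same grid.
#' @param age subject age in years.
#' @param diagnosis `"NC"` or `"AD"`.
#' @param subject_id subject identifier.
#' @param subject_seed integer seed making the scan reproducible.
#' @return A `subject_scan`.
#' @export
simulate_scan <- function(params, masks, age, diagnosis = c("NC", "AD"),
                          subject_id = "subj", subject_seed = NULL) {
  diagnosis <- match.arg(diagnosis)
  stopifnot(inherits(params, "phantom_params"))
  check_same_grid(masks$brain, array(0, params$grid_shape), "masks and params grid")
  brain <- masks$brain$data
  age_region <- brain & !masks$preserved$data
  uptake <- array(0, params$grid_shape)
  uptake[brain] <- params$base_uptake
  uptake[age_region] <- uptake[age_region] +
    params$age_slope_per_year * (age - params$reference_age)
  if (diagnosis == "AD") {
    ad <- masks$ad_pattern$data
    uptake[ad] <- uptake[ad] * (1 - params$ad_severity)
  }
  if (params$subject_noise_sd > 0) {
    sdlog <- sqrt(log(1 + params$subject_noise_sd^2))
    noise <- with_seed(subject_seed,
      array(stats::rlnorm(prod(params$grid_shape),
                          meanlog = -sdlog^2 / 2, sdlog = sdlog),
            params$grid_shape))
    uptake <- uptake * noise
  }
  uptake[uptake < 0] <- 0
  subject_scan(brain_volume(uptake, params$voxel_size_mm), age = age,
               diagnosis = diagnosis, subject_id = subject_id)
}

#' Simulate a cohort of NC and AD subjects
#'
#' Ages are drawn uniformly in `age_range`; each subject gets a derived
#' seed so the whole cohort is a pure function of (params, seed).
#'
#' @param params a [phantom_params()] object.
#' @param masks mask list from [make_template_masks()].
#' @param n_nc,n_ad numbers of normal-control and AD subjects (>= 0, not
#'   both 0).
#' @param age_range length-2 numeric, e.g. `c(55, 85)`.
#' @param seed integer seed.
#' @param id_prefix prefix for generated subject ids.
#' @return A `cohort` with NC subjects first.
#' @export
simulate_cohort <- function(params, masks, n_nc, n_ad,
                            age_range = c(55, 85), seed = 1,
                            id_prefix = "S") {
  if (n_nc < 0 || n_ad < 0 || n_nc + n_ad == 0)
    stop("empty cohort requested")
  n <- n_nc + n_ad
  with_seed(seed, {
    ages <- stats::runif(n, age_range[1], age_range[2])
    sub_seeds <- sample.int(.Machine$integer.max, n)
    dx <- c(rep("NC", n_nc), rep("AD", n_ad))
    ids <- sprintf("%s%03d_%s", id_prefix, seq_len(n), dx)
    cohort(lapply(seq_len(n), function(i)
      simulate_scan(params, masks, age = ages[i], diagnosis = dx[i],
                    subject_id = ids[i], subject_seed = sub_seeds[i])))
  })
}

#' Error-field generation parameters
#'
#' Defaults encode two regimes with equal global bias but different
#' between-map variability: `ZTE_like` (sd 0.02) and `Atlas_like` (sd 0.05),
#' so the ZTE-like regime produces smaller and less variable score errors.
#'
#' @param method_label `"ZTE_like"` or `"Atlas_like"`.
#' @param global_bias mean multiplicative deviation inside the brain
#'   (e.g. -0.02 for 2% underestimation).
#' @param field_sd spatial/between-map SD of the random component; defaults
#'   to 0.02 for ZTE_like, 0.05 for Atlas_like.
#' @param correlation_length_mm Gaussian smoothness scale of the random
#'   field (FWHM, mm).
#' @param skull_weight >= 0; error magnitude is multiplied by
#'   `1 + skull_weight` inside the 3-voxel shell at the brain boundary,
#'   mimicking bone-driven attenuation error concentrated near the skull.
#' @return An `error_field_params` list.
#' @export
error_field_params <- function(method_label = c("ZTE_like", "Atlas_like"),
                               global_bias = -0.02,
                               field_sd = NULL,
                               correlation_length_mm = 12,
                               skull_weight = 2) {
  method_label <- match.arg(method_label)
  if (is.null(field_sd))
    field_sd <- if (method_label == "ZTE_like") 0.02 else 0.05
  if (field_sd < 0) stop("`field_sd` must be >= 0")
  if (skull_weight < 0) stop("`skull_weight` must be >= 0")
  structure(list(method_label = method_label, global_bias = global_bias,
                 field_sd = field_sd,
                 correlation_length_mm = correlation_length_mm,
                 skull_weight = skull_weight),
            class = "error_field_params")
}

# erode a logical mask n times with 6-connectivity
erode_mask <- function(m, n = 1L) {
  d <- dim(m)
  for (k in seq_len(n)) {
    out <- m
    shift <- function(arr, ax, by) {
      idx <- rep(list(quote(expr = )), 3)
      src <- seq_len(d[ax]) - by
      pad <- src < 1L | src > d[ax]
      src[pad] <- 1L
      idx[[ax]] <- src
      r <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
      idx2 <- rep(list(quote(expr = )), 3)
      idx2[[ax]] <- which(pad)
      if (any(pad)) r <- do.call(`[<-`, c(list(r), idx2, list(value = FALSE)))
      r
    }
    for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(m, ax, by)
    m <- out
  }
  m
}

# brain voxels within `depth` voxels of the brain boundary
brain_shell <- function(brain, depth = 3L) {
  brain & !erode_mask(brain, depth)
}

#' Simulate a multiplicative attenuation-error field
#'
#' The field is `1 + global_bias * w + field_sd * w * G` inside the brain
#' and exactly 1 outside, where `G` is a smooth zero-mean unit-variance
#' Gaussian random field (white noise smoothed at `correlation_length_mm`
#' and standardized over the brain) and `w = 1 + skull_weight * shell` with
#' `shell` the brain voxels within 3 voxels of the brain boundary. Values
#' are clipped from below at 0.1; if more than 1% of brain voxels are
#' non-positive before clipping the parameters are rejected.
#'
#' @param params an [error_field_params()] object.
#' @param brain brain `volume_mask`.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param seed integer seed.
#' @param source_id identifier recorded on the map.
#' @return An unconditioned `error_map` (see [compute_error_map()]).
#' @export
simulate_error_field <- function(params, brain, voxel_size_mm = c(2, 2, 2),
                                 seed = 1, source_id = NULL) {
  stopifnot(inherits(params, "error_field_params"),
            inherits(brain, "volume_mask"))
  b <- brain$data
  d <- brain$grid_shape
  w <- 1 + params$skull_weight * brain_shell(b, 3L)
  field <- array(1, d)
  if (params$field_sd > 0) {
    g <- with_seed(seed, array(stats::rnorm(prod(d)), d))
    g <- gaussian_smooth_array(g, fwhm_mm = rep(params$correlation_length_mm, 3),
                               voxel_size_mm = voxel_size_mm)
    gb <- g[b]
    g <- (g - mean(gb)) / stats::sd(gb)
  } else {
    g <- array(0, d)
  }
  raw <- 1 + params$global_bias * w + params$field_sd * w * g
  nbad <- sum(raw[b] <= 0)
  if (nbad > 0.01 * sum(b))
    stop(sprintf("misconfigured error field: %d of %d brain voxels non-positive",
                 nbad, sum(b)))
  field[b] <- pmax(raw[b], 0.1)
  if (is.null(source_id))
    source_id <- sprintf("%s_seed%d", params$method_label, seed)
  error_map(brain_volume(field, voxel_size_mm), method = params$method_label,
            source_id = source_id, conditioned = FALSE)
}

#' Simulate a set of error maps with derived seeds
#'
#' @inheritParams simulate_error_field
#' @param n_maps number of maps.
#' @return list of unconditioned `error_map` objects.
#' @export
simulate_error_maps <- function(params, brain, n_maps,
                                voxel_size_mm = c(2, 2, 2), seed = 1) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_maps))
  lapply(seq_len(n_maps), function(i)
    simulate_error_field(params, brain, voxel_size_mm, seed = seeds[i],
                         source_id = sprintf("%s_%02d", params$method_label, i)))
}

#' ZTE pseudo-CT bone mapping parameters
#'
#' Constants of the linear ZTE-intensity-to-Hounsfield mapping used for
#' continuous bone attenuation values: offset 300 HU, slope 2400 HU,
#' maximum bone value 2000 HU; soft tissue is assigned a fixed 42 HU.
#'
#' @param bone_offset_hu,bone_slope_hu,bone_cap_hu,soft_tissue_hu mapping
#'   constants in Hounsfield units.
#' @return A `pseudo_ct_params` list.
#' @export
pseudo_ct_params <- function(bone_offset_hu = 300, bone_slope_hu = 2400,
                             bone_cap_hu = 2000, soft_tissue_hu = 42) {
  if (bone_cap_hu < bone_offset_hu) stop("cap must be >= offset")
  if (bone_slope_hu <= 0) stop("slope must be positive")
  structure(list(bone_offset_hu = bone_offset_hu, bone_slope_hu = bone_slope_hu,
                 bone_cap_hu = bone_cap_hu, soft_tissue_hu = soft_tissue_hu),
            class = "pseudo_ct_params")
}

#' Map normalized ZTE bone intensity to Hounsfield units
#'
#' Convention: `z = 1` is soft-tissue-like proton density, `z = 0` dense
#' bone, so `HU(z) = min(offset + slope * (1 - z), cap)` for bone voxels;
#' soft-tissue voxels get the fixed soft-tissue value.
#'
#' @param z normalized bias-corrected ZTE intensity in [0, 1] (vectorized).
#' @param params a [pseudo_ct_params()] object.
#' @param tissue `"bone"` or `"soft"`; soft-tissue voxels return
#'   `soft_tissue_hu` regardless of `z`.
#' @return HU values, same length as `z`.
#' @export
zte_bone_to_hu <- function(z, params = pseudo_ct_params(),
                           tissue = c("bone", "soft")) {
  tissue <- match.arg(tissue)
  if (any(z < 0 | z > 1)) stop("`z` must be in [0, 1]")
  if (tissue == "soft") return(rep(params$soft_tissue_hu, length(z)))
  pmin(params$bone_offset_hu + params$bone_slope_hu * (1 - z),
       params$bone_cap_hu)
}
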