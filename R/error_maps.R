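# Multiplicative attenuation-error maps: construction from paired
# MRAC/CTAC PET volumes, conditioning (mask-normalized smoothing + brain
# masking), voxelwise injection into normalized subject volumes, and the
# cohort x error-map cross product that yields the simulated score table.

#' Construct an error map object
#'
#' @param field dimensionless ratio field as a `brain_volume`.
#' @param method one of `"ZTE"`, `"Atlas"`, `"ZTE_like"`, `"Atlas_like"`,
#'   `"identity"`.
#' @param source_id identifier of the patient/seed the map derives from.
#' @param conditioned whether the map has been smoothed and brain-masked.
#' @return An `error_map` object.
#' @export
error_map <- function(field, method = c("ZTE_like", "Atlas_like", "ZTE",
                                        "Atlas", "identity"),
                      source_id = "map", conditioned = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(field, "brain_volume"))
  structure(list(field = field, method = method,
                 source_id = as.character(source_id),
                 conditioned = isTRUE(conditioned)),
            class = "error_map")
}

#' The identity (no-error) map
#' @param grid_shape,voxel_size_mm grid geometry.
#' @return A conditioned `error_map` that is exactly 1 everywhere.
#' @export
identity_error_map <- function(grid_shape, voxel_size_mm = c(2, 2, 2)) {
  error_map(brain_volume(array(1, grid_shape), voxel_size_mm),
            method = "identity", source_id = "original", conditioned = TRUE)
}

#' Voxelwise ratio of MRAC-corrected to CTAC-corrected PET
#'
#' `field = pet_mrac / pet_ctac` inside the brain mask; outside the brain
#' the field is set to 1. Brain voxels whose CTAC denominator is <= `eps`
#' are set to 1 and counted in a warning; if more than 1% of brain voxels
#' are degenerate the inputs are rejected.
#'
#' @param pet_mrac,pet_ctac `brain_volume`s on the same grid.
#' @param brain brain `volume_mask`.
#' @param method label recorded on the map.
#' @param source_id identifier of the source patient.
#' @param eps denominator guard (default 1e-8).
#' @return An unconditioned `error_map`.
#' @export
compute_error_map <- function(pet_mrac, pet_ctac, brain,
                              method = "ZTE_like", source_id = "map",
                              eps = 1e-8) {
  check_same_grid(pet_mrac, pet_ctac, "MRAC and CTAC volumes")
  check_same_grid(pet_mrac, brain, "volumes and brain mask")
  b <- brain$data
  degen <- b & (pet_ctac$data <= eps)
  ndeg <- sum(degen)
  if (ndeg > 0.01 * sum(b))
    stop(sprintf("%d of %d brain voxels have degenerate CTAC denominator",
                 ndeg, sum(b)))
  field <- array(1, dim(b))
  ok <- b & !degen
  field[ok] <- pet_mrac$data[ok] / pet_ctac$data[ok]
  if (ndeg > 0)
    warning(sprintf("%d brain voxels with CTAC <= %g set to 1", ndeg, eps))
  error_map(brain_volume(field, pet_mrac$voxel_size_mm),
            method = method, source_id = source_id, conditioned = FALSE)
}

#' Condition an error map: mask-normalized smoothing + brain masking
#'
#' Smooths `field * brain` and `brain` separately and divides, so ratio
#' values at the brain edge are not diluted toward the outside fill value,
#' then sets the field to exactly 1 outside the brain. Constant fields are
#' conserved.
#'
#' @param err an unconditioned `error_map`.
#' @param brain brain `volume_mask`.
#' @param fwhm_mm smoothing FWHM per axis, mm (default 12).
#' @return The conditioned `error_map`.
#' @export
condition_error_map <- function(err, brain, fwhm_mm = c(12, 12, 12)) {
  stopifnot(inherits(err, "error_map"), inherits(brain, "volume_mask"))
  if (err$conditioned) stop("error map is already conditioned")
  check_same_grid(err$field, brain, "error map and brain mask")
  b <- brain$data
  sm <- masked_smooth_array(err$field$data, b, rep_len(fwhm_mm, 3),
                            err$field$voxel_size_mm)
  sm[!b] <- 1
  if (any(sm[b] <= 0))
    stop("conditioning produced non-positive values inside the brain")
  error_map(brain_volume(sm, err$field$voxel_size_mm), method = err$method,
            source_id = err$source_id, conditioned = TRUE)
}

#' Inject an error map into a normalized subject volume
#'
#' Voxelwise product, no re-smoothing or re-deformation; this is how
#' attenuation error is imposed on template-space PET data. Only
#' conditioned maps are accepted, enforcing the pipeline order.
#'
#' @param subject_vol a template-space `brain_volume`.
#' @param err a conditioned `error_map` on the same grid.
#' @return `brain_volume` product.
#' @export
apply_error <- function(subject_vol, err) {
  stopifnot(inherits(subject_vol, "brain_volume"), inherits(err, "error_map"))
  if (!err$conditioned)
    stop("error map must be conditioned before application")
  check_same_grid(subject_vol, err$field, "subject volume and error map")
  brain_volume(subject_vol$data * err$field$data,
               subject_vol$voxel_size_mm, subject_vol$space_tag)
}

#' Score a cohort under every error map (the cross-product simulation)
#'
#' Scores every (subject x error map) pair with `pre_normalized` scoring,
#' plus one "original" score per subject (identity error). With 107
#' subjects and 27 maps this yields 2889 rows per method — 5778 scored
#' images for two methods — plus 107 original rows.
#'
#' @param cht a `cohort`.
#' @param error_maps list of conditioned `error_map`s (may mix methods).
#' @param db a `normal_db`.
#' @param masks mask list.
#' @param config a [scoring_config()]; `pre_normalized` is forced `TRUE`
#'   because simulated images need no further filtering.
#' @param include_original add "original" rows scored through the identity
#'   map (default `TRUE`).
#' @return Score table data.frame with columns `subject_id`,
#'   `error_map_id`, `method`, `diagnosis`, `age`, `ad_tsum`, `pet_score`.
#' @export
run_simulation <- function(cht, error_maps, db, masks,
                           config = scoring_config(pre_normalized = TRUE),
                           include_original = TRUE) {
  stopifnot(inherits(cht, "cohort"))
  if (length(error_maps) == 0L) stop("empty error-map list")
  ok <- vapply(error_maps, function(e) inherits(e, "error_map") && e$conditioned,
               logical(1))
  if (!all(ok)) stop("all error maps must be conditioned `error_map`s")
  config$pre_normalized <- TRUE
  maps <- error_maps
  if (include_original)
    maps <- c(list(identity_error_map(cht[[1]]$volume$grid_shape,
                                      cht[[1]]$volume$voxel_size_mm)),
              maps)
  rows <- vector("list", length(cht) * length(maps))
  k <- 0L
  for (s in cht) {
    for (m in maps) {
      pert <- subject_scan(apply_error(s$volume, m), s$age, s$diagnosis,
                           s$subject_id)
      res <- score_subject(pert, db, masks, config)
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = s$subject_id,
        error_map_id = if (m$method == "identity") "original" else m$source_id,
        method = if (m$method == "identity") "original" else m$method,
        diagnosis = s$diagnosis, age = s$age,
        ad_tsum = res$ad_tsum, pet_score = res$pet_score,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
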