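#' Construct a brain volume
#'
#' A `brain_volume` is the universal currency of the pipeline: a 3D scalar
#' field on a common template grid (tracer uptake in arbitrary units, or a
#' dimensionless ratio for error maps) together with its voxel spacing.
#'
#' @param data 3D numeric array; all values must be finite.
#' @param voxel_size_mm numeric length-3, strictly positive voxel edge
#'   lengths in mm (default 2 mm isotropic).
#' @param space_tag `"template"` or `"native"`.
#' @return An object of class `brain_volume` with fields `data`,
#'   `voxel_size_mm`, `space_tag` and `grid_shape`.
#' @export
brain_volume <- function(data, voxel_size_mm = c(2, 2, 2),
                         space_tag = c("template", "native")) {
  space_tag <- match.arg(space_tag)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop(sprintf("volume contains %d non-finite voxels", sum(!is.finite(data))))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 strictly positive values")
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, space_tag = space_tag,
         grid_shape = dim(data)),
    class = "brain_volume"
  )
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("<brain_volume> %s grid %s, voxel %s mm, range [%.4g, %.4g]\n",
              x$space_tag, paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a volume mask
#'
#' @param data 3D logical (or 0/1 numeric) array; values > 0.5 are treated
#'   as TRUE so masks saved as float by atlas tools load correctly.
#' @param label one of `"brain"`, `"preserved_uptake"`, `"ad_pattern"`.
#' @return An object of class `volume_mask` with logical `data`,
#'   `grid_shape` and `label`.
#' @export
volume_mask <- function(data, label = c("brain", "preserved_uptake", "ad_pattern")) {
  label <- match.arg(label)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3D array")
  d <- dim(data)
  data <- if (is.logical(data)) data else (as.numeric(data) > 0.5)
  dim(data) <- d
  if (!any(data)) stop("mask has no TRUE voxels")
  structure(list(data = data, grid_shape = d, label = label),
            class = "volume_mask")
}

#' A single subject's scan with metadata
#'
#' @param volume a `brain_volume` in template space.
#' @param age age in years, > 0.
#' @param diagnosis `"NC"` (normal control) or `"AD"`.
#' @param subject_id character scalar.
#' @return A `subject_scan` object.
#' @export
subject_scan <- function(volume, age, diagnosis = c("NC", "AD"), subject_id) {
  diagnosis <- match.arg(diagnosis)
  stopifnot(inherits(volume, "brain_volume"))
  if (volume$space_tag != "template")
    stop("subject volumes must be in template space")
  if (!is.numeric(age) || length(age) != 1L || age <= 0)
    stop("`age` must be a single positive number")
  structure(list(volume = volume, age = as.numeric(age),
                 diagnosis = diagnosis, subject_id = as.character(subject_id)),
            class = "subject_scan")
}

#' An ordered collection of subject scans on one grid
#'
#' @param subjects list of `subject_scan` objects sharing one grid and
#'   voxel size, with unique subject ids.
#' @return A `cohort` object (list with class attribute).
#' @export
cohort <- function(subjects) {
  if (length(subjects) == 0L) stop("empty cohort requested")
  stopifnot(all(vapply(subjects, inherits, logical(1), "subject_scan")))
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject_ids in cohort")
  shapes <- vapply(subjects, function(s) paste(s$volume$grid_shape, collapse = "x"),
                   character(1))
  vox <- vapply(subjects, function(s) paste(s$volume$voxel_size_mm, collapse = "x"),
                character(1))
  if (length(unique(shapes)) != 1L || length(unique(vox)) != 1L)
    stop("grid mismatch: cohort volumes must share grid_shape and voxel_size_mm")
  structure(subjects, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  dx <- table(vapply(x, `[[`, character(1), "diagnosis"))
  cat(sprintf("<cohort> %d subjects (%s), grid %s\n", length(x),
              paste(names(dx), dx, sep = "=", collapse = ", "),
              paste(x[[1]]$volume$grid_shape, collapse = "x")))
  invisible(x)
}

# internal: check that two gridded objects share a grid
check_same_grid <- function(a, b, what = "inputs") {
  da <- if (inherits(a, "brain_volume") || inherits(a, "volume_mask")) a$grid_shape else dim(a)
  db <- if (inherits(b, "brain_volume") || inherits(b, "volume_mask")) b$grid_shape else dim(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image
#'   with finite voxel values.
#' @return A `brain_volume`; voxel size is taken from the header and the
#'   header affine is kept in attribute `"nifti_header"` for round-trips.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected 3D volume in %s, got %dD", path, length(d)))
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  nbad <- sum(!is.finite(arr))
  if (nbad > 0L)
    stop(sprintf("%s contains %d non-finite (NaN/Inf) voxels", path, nbad))
  vol <- brain_volume(arr, voxel_size_mm = RNifti::pixdim(img)[1:3])
  attr(vol, "nifti_header") <- RNifti::niftiHeader(img)
  vol
}

#' Write a brain volume or mask to a NIfTI-1 file
#'
#' Masks are written as 0/1 volumes. Existing files are overwritten (a
#' message notes the overwrite).
#'
#' @param vol a `brain_volume` or `volume_mask`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)))
  if (file.exists(path)) message(sprintf("overwriting %s", path))
  if (inherits(vol, "volume_mask")) {
    arr <- array(as.numeric(vol$data), vol$grid_shape)
    vox <- c(2, 2, 2)
  } else {
    stopifnot(inherits(vol, "brain_volume"))
    arr <- vol$data
    vox <- vol$voxel_size_mm
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vox
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a cohort from a CSV manifest
#'
#' @param csv_path CSV with columns `subject_id`, `age`, `diagnosis`
#'   (`NC`/`AD`) and `filename` (NIfTI file relative to `volume_dir`).
#' @param volume_dir directory containing the volume files.
#' @return A `cohort` in manifest row order.
#' @export
read_cohort_manifest <- function(csv_path, volume_dir) {
  man <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "diagnosis", "filename")
  if (!all(need %in% names(man)))
    stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  bad <- setdiff(unique(man$diagnosis), c("NC", "AD"))
  if (length(bad))
    stop(sprintf("unknown diagnosis label(s): %s", paste(bad, collapse = ", ")))
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    vol <- read_volume(file.path(volume_dir, man$filename[i]))
    subject_scan(vol, age = man$age[i], diagnosis = man$diagnosis[i],
                 subject_id = man$subject_id[i])
  })
  cohort(subjects)
}

#' Write a score table to CSV
#'
#' @param tab data.frame with columns `subject_id`, `error_map_id`,
#'   `method`, `ad_tsum`, `pet_score`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_score_table <- function(tab, path) {
  cols <- c("subject_id", "error_map_id", "method", "ad_tsum", "pet_score")
  stopifnot(all(cols %in% names(tab)))
  utils::write.csv(tab[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_score_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
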