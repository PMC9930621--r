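#' Write a 3-D map or mask as NIfTI-1
#'
#' @param x 3-D array (numeric or logical), a `stat_map` (its t image) or a
#'   `va_parcellation` (integer labels: 0 outside, 1 core, 2 acoustic,
#'   3 accessory).
#' @param path Output `.nii`/`.nii.gz` path.
#' @param voxel_size_mm Voxel edge in mm (taken from the object when
#'   available).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(x, path, voxel_size_mm = 2.75) {
  if (inherits(x, "stat_map")) {
    voxel_size_mm <- x$grid$voxel_size_mm
    x <- x$t
  } else if (inherits(x, "va_parcellation")) {
    voxel_size_mm <- x$grid$voxel_size_mm
    x <- array(match(x$labels, c("outside", "core", "acoustic", "accessory")) - 1L,
               dim(x$labels))
  }
  img <- RNifti::asNifti(array(as.numeric(x), dim(x)))
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a synthetic cohort to NIfTI + JSON sidecars
#'
#' One 4-D volume per subject and run-average (x, y, z, condition) plus a
#' JSON sidecar with the condition order, run count and seed, and the
#' ground-truth class labels as an integer volume (0 null, 1 core,
#' 2 acoustic, 3 accessory).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- cohort$grid$dims
  for (s in seq_len(cohort$n_subjects)) {
    m <- subject_mean_betas(cohort, s)
    arr <- array(m, c(d, ncol(m)))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(rep(cohort$grid$voxel_size_mm, 3), 1)
    RNifti::writeNifti(img, file.path(dir, sprintf("sub-%02d_betas.nii.gz", s)))
  }
  gt_codes <- match(cohort$ground_truth$voxel_class,
                    c("null", "core", "acoustic", "accessory")) - 1L
  write_nifti_map(array(gt_codes, d),
                  file.path(dir, "ground_truth_labels.nii.gz"),
                  cohort$grid$voxel_size_mm)
  sidecar <- list(conditions = cohort$conditions, n_runs = cohort$n_runs,
                  n_subjects = cohort$n_subjects, seed = cohort$seed,
                  effect = cohort$effect, noise_sd = cohort$noise_sd,
                  grid_dims = d, voxel_size_mm = cohort$grid$voxel_size_mm)
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
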