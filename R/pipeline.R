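#' Run the full voice-area parcellation pipeline on a cohort
#'
#' Univariate stage: original-VA mask from [original voice > nonvoice], the
#' five interaction maps and their conjunction (core VA). Multivariate stage:
#' per-subject searchlight cross-classification from the originals to each
#' AE class, group accuracy statistics, and the averaged cross map (acoustic
#' VA). The three masks are assembled into the parcellation with coverage
#' statistics and effect sizes.
#'
#' Subject images are not smoothed by default (`smoothing_fwhm_mm = 0`): the
#' synthetic cohort has no inter-subject spatial misalignment, so smoothing
#' would only dilate masks and bias voxel-level recovery scoring.
#'
#' @param cohort A `synthetic_cohort`.
#' @param threshold A [va_threshold()] used for all masks (default FWE
#'   0.05).
#' @param smoothing_fwhm_mm Smoothing of subject images in mm (default 0).
#' @param radius_mm Searchlight radius (default 5).
#' @param verbose Print stage progress.
#' @return List with `original_va`, `interaction_maps`, `core`,
#'   `cross_maps`, `avg_cross`, `acoustic_mask`, `parcellation`,
#'   `effect_sizes`.
#' @export
run_va_pipeline <- function(cohort, threshold = va_threshold("fwe"),
                            smoothing_fwhm_mm = 0, radius_mm = 5,
                            verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("univariate: original VA")
  va <- define_original_va(cohort, threshold, smoothing_fwhm_mm)
  say("univariate: interaction maps")
  inter <- lapply(ae_variants(), function(v)
    group_contrast(cohort, interaction_contrast(v), threshold,
                   smoothing_fwhm_mm,
                   contrast_name = paste0("interaction orig vs ", v)))
  names(inter) <- ae_variants()
  core <- define_core_va(inter, va)
  say("multivariate: searchlight cross-classification")
  neigh <- searchlight_indices(cohort$grid, radius_mm)
  cross <- lapply(ae_variants(), function(v) {
    maps <- lapply(seq_len(cohort$n_subjects), function(s)
      searchlight_map(cohort, s, "cross", v, neigh = neigh))
    group_accuracy_map(maps, cohort$grid, smoothing_fwhm_mm = smoothing_fwhm_mm,
                       threshold = threshold,
                       contrast_name = paste0("cross orig->", v))
  })
  names(cross) <- ae_variants()
  avg <- average_cross_maps(cross, threshold)
  acoustic <- define_acoustic_va(avg, va, core$mask)
  say("assembly")
  parc <- assemble_parcellation(va, core$mask, acoustic, cohort$grid)
  es <- effect_sizes(cohort, parc)
  list(original_va = va, interaction_maps = inter, core = core,
       cross_maps = cross, avg_cross = avg, acoustic_mask = acoustic,
       parcellation = parc, effect_sizes = es)
}

#' Score parcellation recovery against ground truth
#'
#' @param parcellation A `va_parcellation`.
#' @param gt A `ground_truth_map`.
#' @return A tibble with, per class, the Jaccard index, recall and precision
#'   against the ground-truth region, plus the fraction of null voxels
#'   labeled anything.
#' @export
score_recovery <- function(parcellation, gt) {
  stopifnot(identical(dim(parcellation$labels), gt$grid$dims))
  lab <- as.vector(parcellation$labels)
  cls <- gt$voxel_class
  rows <- lapply(c("core", "acoustic", "accessory"), function(cl) {
    pred <- lab == cl
    truth <- cls == cl
    tibble::tibble(
      class = cl,
      jaccard = sum(pred & truth) / max(sum(pred | truth), 1),
      recall = sum(pred & truth) / max(sum(truth), 1),
      precision = sum(pred & truth) / max(sum(pred), 1))
  })
  out <- do.call(rbind, rows)
  attr(out, "null_labeled_fraction") <-
    sum(lab != "outside" & cls == "null") / max(sum(cls == "null"), 1)
  out
}

#' Jaccard index of two masks
#' @param a,b Logical arrays/vectors of equal length.
#' @return `|a & b| / |a | b|`.
#' @export
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
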