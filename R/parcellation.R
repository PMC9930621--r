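#' Define the original voice area mask
#'
#' Significance mask of the group contrast [original voice > original
#' nonvoice] at the configured threshold (FWE 0.05 by default).
#'
#' @param cohort A `synthetic_cohort`.
#' @param threshold A [va_threshold()].
#' @param smoothing_fwhm_mm Smoothing of subject contrast images (default 0).
#' @return A `stat_map` whose mask is the original VA.
#' @export
define_original_va <- function(cohort, threshold = va_threshold("fwe"),
                               smoothing_fwhm_mm = 0) {
  w <- c(orig_voice = 1, orig_nonvoice = -1)
  group_contrast(cohort, w, threshold, smoothing_fwhm_mm,
                 contrast_name = "original voice > nonvoice")
}

#' Define the core voice area
#'
#' Minimum-statistic conjunction over the five interaction maps
#' [(orig voice > orig nonvoice) minus (AE voice > AE nonvoice)], one per AE
#' class, intersected with the original VA mask: voxels whose voice
#' preference exceeds every AE's.
#'
#' @param interaction_maps Named list of 5 `stat_map`s (one per AE class).
#' @param original_va Logical 3-D array (or `stat_map`) of the original VA.
#' @return List with `mask` (3-D logical) and `conjunction` (`stat_map`).
#' @export
define_core_va <- function(interaction_maps, original_va) {
  if (length(interaction_maps) != length(ae_variants()))
    stop("need one interaction map per AE class (5)")
  conj <- conjunction_mask(interaction_maps)
  va <- mask_of(original_va)
  list(mask = conj$mask & va, conjunction = conj)
}

#' Define the acoustic voice area
#'
#' Significant voxels of the averaged cross-classification map, restricted to
#' the original VA and excluding core voxels (core takes precedence when a
#' voxel qualifies for both).
#'
#' @param avg_cross_map `stat_map` from [average_cross_maps()].
#' @param original_va,core_mask Masks (3-D logical or `stat_map`).
#' @return 3-D logical mask.
#' @export
define_acoustic_va <- function(avg_cross_map, original_va, core_mask) {
  mask_of(avg_cross_map) & mask_of(original_va) & !mask_of(core_mask)
}

mask_of <- function(x) {
  if (inherits(x, "stat_map")) x$mask else x
}

#' Assemble the voice-area parcellation
#'
#' Labels every voxel as core, acoustic, accessory (= original VA not covered
#' by core or acoustic) or outside, and computes per-hemisphere voxel counts
#' and coverage percentages (one decimal, half-up) relative to the original
#' VA.
#'
#' @param original_va,core,acoustic Masks (3-D logical or `stat_map`);
#'   `core` and `acoustic` must be disjoint subsets of `original_va`.
#' @param grid A [va_grid()].
#' @return A `va_parcellation`: list with `labels` (3-D array of
#'   `"outside"/"core"/"acoustic"/"accessory"`), `coverage` (tibble) and the
#'   source masks.
#' @export
assemble_parcellation <- function(original_va, core, acoustic, grid) {
  va <- mask_of(original_va); co <- mask_of(core); ac <- mask_of(acoustic)
  if (!inherits(grid, "va_grid")) grid <- va_grid(grid)
  n_out <- sum(co & !va) + sum(ac & !va)
  if (n_out > 0)
    stop(sprintf("%d core/acoustic voxel(s) outside the original VA", n_out))
  n_ov <- sum(co & ac)
  if (n_ov > 0)
    stop(sprintf("core and acoustic overlap in %d voxel(s)", n_ov))
  labels <- array("outside", grid$dims)
  labels[va] <- "accessory"
  labels[co] <- "core"
  labels[ac] <- "acoustic"
  hemi <- array(hemisphere_of(grid), grid$dims)
  cov <- do.call(rbind, lapply(c("left", "right"), function(h) {
    sel <- hemi == h
    n_orig <- sum(va & sel)
    counts <- vapply(c("core", "acoustic", "accessory"),
                     function(cl) sum(labels == cl & sel), integer(1))
    tibble::tibble(
      hemisphere = h, n_original = n_orig,
      n_core = counts[["core"]], n_acoustic = counts[["acoustic"]],
      n_accessory = counts[["accessory"]],
      percent_core = coverage_percent(counts[["core"]], n_orig),
      percent_acoustic = coverage_percent(counts[["acoustic"]], n_orig),
      percent_accessory = coverage_percent(counts[["accessory"]], n_orig))
  }))
  structure(list(labels = labels, coverage = cov, original_va = va,
                 core = co, acoustic = ac, grid = grid),
            class = "va_parcellation")
}

#' Coverage percentage, rounded half-up to one decimal
#'
#' `100 * count / total`, with exact .x5 values rounded away from zero
#' (`549/1653` gives `33.2`, `480/1572` gives `30.5`).
#'
#' @param count,total Voxel counts.
#' @return Percentage with one decimal.
#' @export
coverage_percent <- function(count, total) {
  if (total == 0) return(NA_real_)
  floor(1000 * count / total + 0.5) / 10
}

#' @export
print.va_parcellation <- function(x, ...) {
  cat("<va_parcellation>\n")
  print(as.data.frame(x$coverage))
  invisible(x)
}

#' Per-subfield effect sizes (Cohen's d)
#'
#' For each subfield and sound set: the subject-level mean (voice - nonvoice)
#' beta difference averaged over the subfield's voxels, and the group Cohen's
#' d (mean over subjects divided by the between-subject SD). Degenerate
#' entries (empty subfield, zero SD) are flagged.
#'
#' @param cohort A `synthetic_cohort`.
#' @param parcellation A `va_parcellation`.
#' @return A tibble: subfield, sound_set, mean_difference, sd, cohens_d, n
#'   (voxels), flag.
#' @export
effect_sizes <- function(cohort, parcellation) {
  stopifnot(identical(dim(parcellation$labels), cohort$grid$dims))
  subj_means <- lapply(seq_len(cohort$n_subjects),
                       function(s) subject_mean_betas(cohort, s))
  rows <- list()
  for (cl in c("core", "acoustic", "accessory")) {
    vox <- which(parcellation$labels == cl)
    for (v in va_variants()) {
      if (!length(vox)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          subfield = cl, sound_set = v, mean_difference = NA_real_,
          sd = NA_real_, cohens_d = NA_real_, n = 0L, flag = "empty subfield")
        next
      }
      diffs <- vapply(subj_means, function(b)
        mean(b[vox, paste0(v, "_voice")] - b[vox, paste0(v, "_nonvoice")]),
        numeric(1))
      s <- sd(diffs)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subfield = cl, sound_set = v, mean_difference = mean(diffs),
        sd = s, cohens_d = if (s > 0) mean(diffs) / s else NA_real_,
        n = length(vox), flag = if (s > 0) "" else "zero between-subject SD")
    }
  }
  do.call(rbind, rows)
}
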