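#' Toy anatomical atlas for ROI analysis
#'
#' A packaged stand-in for cytoarchitectonic auditory-cortex maps: each
#' hemisphere is divided into five named slabs (Te1.0, Te1.1, Te1.2, PTe,
#' Te3) along the anterior-posterior axis of a central band of the grid.
#' Synthetic by construction; real atlas labels can be supplied to
#' [roi_analysis()] as any named voxel-index list.
#'
#' @param grid A [va_grid()].
#' @return A `roi_set` with kind `"anatomical"`.
#' @export
toy_atlas <- function(grid) {
  if (!inherits(grid, "va_grid")) grid <- va_grid(grid)
  d <- grid$dims
  co <- grid_coords(grid)
  hemi <- hemisphere_of(grid)
  names_ <- c("Te1.0", "Te1.1", "Te1.2", "PTe", "Te3")
  edges <- round(seq(1, d[2] + 1, length.out = length(names_) + 1))
  zc <- co[, 3] >= max(1, round(d[3] / 4)) & co[, 3] <= round(3 * d[3] / 4)
  rois <- list()
  for (h in c("left", "right")) {
    for (k in seq_along(names_)) {
      sel <- hemi == h & zc & co[, 2] >= edges[k] & co[, 2] < edges[k + 1]
      rois[[paste(h, names_[k], sep = "_")]] <- which(sel)
    }
  }
  new_roi_set(rois, kind = "anatomical", grid = grid)
}

new_roi_set <- function(rois, kind, grid, centers = NULL, radius_mm = NULL,
                        log = NULL) {
  structure(list(rois = rois, kind = kind, grid = grid, centers = centers,
                 radius_mm = radius_mm,
                 log = log %||% tibble::tibble(patch = character(),
                                               event = character())),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set (%s): %d ROIs, sizes %s>\n", x$kind, length(x$rois),
              paste(range(lengths(x$rois)), collapse = "-")))
  invisible(x)
}

## Local maxima of a 3-D statistic on 26-connectivity neighbourhoods,
## restricted to `mask`; ties broken by first linear index.
local_maxima <- function(stat, mask) {
  d <- dim(stat)
  co <- grid_coords(va_grid(d))
  cand <- which(mask & is.finite(stat))
  out <- integer()
  for (v in cand) {
    nb <- neighbours26(co[v, ], d)
    nb_in <- nb[mask[nb]]
    if (!length(nb_in)) { out <- c(out, v); next }
    ge_all <- all(stat[v] >= stat[nb_in], na.rm = TRUE)
    strict_some <- any(stat[v] > stat[nb_in], na.rm = TRUE)  # no flat plateaus
    tie_lower <- any(stat[nb_in] == stat[v] & nb_in < v)
    if (ge_all && strict_some && !tie_lower) out <- c(out, v)
  }
  out[order(-stat[out], out)]
}

neighbours26 <- function(xyz, d) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  nb <- sweep(off, 2, xyz, "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  nb <- nb[ok, , drop = FALSE]
  nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
}

#' Define per-subject functional voice patches
#'
#' Finds the top local maxima (26-connectivity) of a subject's statistic
#' inside the group-level mask, assigns each of the reference patch
#' coordinates (three per hemisphere) its nearest peak, and builds a sphere
#' ROI around each chosen centre. When no peak is available for a reference,
#' or two chosen centres lie closer than `min_sep_mm`, the affected patches
#' fall back to their reference coordinates; every fallback is recorded in
#' the construction log.
#'
#' @param stat 3-D statistic array (one subject).
#' @param group_mask Logical 3-D array (the p < 0.001 group constraint).
#' @param reference_coords Matrix (rows = patches) of voxel coordinates with
#'   rownames naming the patches; typically 3 per hemisphere.
#' @param grid A [va_grid()].
#' @param n_peaks Number of candidate peaks to keep (default 10).
#' @param min_sep_mm Minimum centre separation in mm (default 10).
#' @param radius_mm Sphere radius in mm (default 5).
#' @return A `roi_set` with kind `"functional_patch"`.
#' @export
define_functional_patches <- function(stat, group_mask, reference_coords,
                                      grid, n_peaks = 10, min_sep_mm = 10,
                                      radius_mm = 5) {
  if (!inherits(grid, "va_grid")) grid <- va_grid(grid)
  if (!any(group_mask)) stop("empty group mask")
  ref <- as.matrix(reference_coords)
  if (is.null(rownames(ref)))
    rownames(ref) <- paste0("patch", seq_len(nrow(ref)))
  peaks <- utils::head(local_maxima(stat, group_mask), n_peaks)
  co <- grid_coords(grid)
  vs <- grid$voxel_size_mm
  log <- list()
  centers <- matrix(NA_real_, nrow(ref), 3,
                    dimnames = list(rownames(ref), c("x", "y", "z")))
  for (k in seq_len(nrow(ref))) {
    if (length(peaks)) {
      dists <- sqrt(colSums((t(co[peaks, , drop = FALSE]) - ref[k, ])^2)) * vs
      centers[k, ] <- co[peaks[which.min(dists)], ]
    } else {
      centers[k, ] <- ref[k, ]
      log[[length(log) + 1]] <- c(rownames(ref)[k], "no peak found; reference used")
    }
  }
  ## pairwise separation rule: offending centres revert to the references
  repeat {
    dd <- as.matrix(stats::dist(centers)) * vs
    diag(dd) <- Inf
    bad <- which(apply(dd < min_sep_mm, 1, any))
    bad <- bad[!apply(abs(centers - ref) < 1e-9, 1, all)[bad]]
    if (!length(bad)) break
    for (k in bad) {
      centers[k, ] <- ref[k, ]
      log[[length(log) + 1]] <-
        c(rownames(ref)[k],
          sprintf("centres closer than %g mm; reference used", min_sep_mm))
    }
  }
  rois <- lapply(seq_len(nrow(ref)), function(k)
    sphere_voxels(centers[k, ], radius_mm, grid))
  names(rois) <- rownames(ref)
  log_tbl <- if (length(log)) {
    tibble::tibble(patch = vapply(log, `[`, "", 1),
                   event = vapply(log, `[`, "", 2))
  } else NULL
  new_roi_set(rois, "functional_patch", grid, centers = centers,
              radius_mm = radius_mm, log = log_tbl)
}

#' Voxels of a sphere ROI
#' @param center Voxel coordinate (length 3).
#' @param radius_mm Radius in mm.
#' @param grid A [va_grid()].
#' @return Integer vector of linear voxel indices whose centre distance is
#'   `<= radius_mm`.
#' @export
sphere_voxels <- function(center, radius_mm, grid) {
  co <- grid_coords(grid)
  d <- sqrt(colSums((t(co) - as.numeric(center))^2)) * grid$voxel_size_mm
  which(d <= radius_mm + 1e-9)
}

#' ROI decoding table
#'
#' For each ROI and requested scheme, decodes voice vs nonvoice on all ROI
#' voxels per subject (leave-one-run-out within a sound set, or
#' cross-classification from the originals), then tests the group accuracies
#' against chance (one-sided one-sample t) with Benjamini-Hochberg FDR
#' correction across the whole table. Empty ROIs are flagged, not dropped.
#'
#' @param cohort A `synthetic_cohort`.
#' @param roi_set A `roi_set` (or named list of voxel-index vectors).
#' @param schemes Character vector of schemes, entries `"cv_<variant>"` or
#'   `"cross_<variant>"` (default: cv on originals plus cross on all AEs).
#' @param fdr_q FDR level (default 0.05).
#' @param chance Chance level (default 0.5).
#' @return A tibble: roi, scheme, n_voxels, mean_accuracy, t, p, p_fdr,
#'   significant, flag.
#' @export
roi_analysis <- function(cohort, roi_set,
                         schemes = c("cv_orig",
                                     paste0("cross_", ae_variants())),
                         fdr_q = 0.05, chance = 0.5) {
  rois <- if (inherits(roi_set, "roi_set")) roi_set$rois else roi_set
  rows <- list()
  for (rn in names(rois)) {
    vox <- rois[[rn]]
    for (sc in schemes) {
      parts <- strsplit(sc, "_", fixed = TRUE)[[1]]
      kind <- parts[1]
      variant <- paste(parts[-1], collapse = "_")
      if (!length(vox)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          roi = rn, scheme = sc, n_voxels = 0L, mean_accuracy = NA_real_,
          t = NA_real_, p = NA_real_, flag = "empty ROI")
        next
      }
      accs <- vapply(seq_len(cohort$n_subjects), function(s) {
        if (kind == "cv") {
          pat <- variant_patterns(cohort, s, variant)
          decode_cv(pat$X[, vox, drop = FALSE], pat$y, pat$run)
        } else {
          tr <- variant_patterns(cohort, s, "orig")
          te <- variant_patterns(cohort, s, variant)
          decode_cross(tr$X[, vox, drop = FALSE], tr$y,
                       te$X[, vox, drop = FALSE], te$y)
        }
      }, numeric(1))
      tt <- one_sample_t(matrix(accs, ncol = 1), mu = chance)
      rows[[length(rows) + 1]] <- tibble::tibble(
        roi = rn, scheme = sc, n_voxels = length(vox),
        mean_accuracy = mean(accs), t = tt$t, p = tt$p, flag = "")
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, "BH")
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < fdr_q
  out
}
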