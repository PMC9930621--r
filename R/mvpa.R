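#' Searchlight neighbour lists
#'
#' For every voxel, the 1-based linear indices of all voxels whose centre
#' lies within `radius_mm` (Euclidean) of its centre. Radius 0 gives
#' single-voxel lists.
#'
#' @param grid A [va_grid()] (or 3-vector of dims).
#' @param radius_mm Searchlight radius in mm (default 5).
#' @param mask Optional logical vector over voxels restricting both centres
#'   and neighbours.
#' @return List of integer vectors, one per (in-mask) voxel; the attribute
#'   `"centres"` holds the centre indices.
#' @export
searchlight_indices <- function(grid, radius_mm = 5, mask = NULL) {
  if (!inherits(grid, "va_grid")) grid <- va_grid(grid)
  if (radius_mm < 0) stop("radius must be >= 0")
  d <- grid$dims
  vs <- grid$voxel_size_mm
  r_vox <- floor(radius_mm / vs)
  off <- expand.grid(dx = -r_vox:r_vox, dy = -r_vox:r_vox, dz = -r_vox:r_vox)
  keep <- sqrt(off$dx^2 + off$dy^2 + off$dz^2) * vs <= radius_mm + 1e-9
  off <- off[keep, , drop = FALSE]
  co <- grid_coords(grid)
  n_vox <- prod(d)
  in_mask <- if (is.null(mask)) rep(TRUE, n_vox) else mask
  centres <- which(in_mask)
  out <- vector("list", length(centres))
  for (i in seq_along(centres)) {
    v <- centres[i]
    nx <- co[v, 1] + off$dx
    ny <- co[v, 2] + off$dy
    nz <- co[v, 3] + off$dz
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    idx <- as.integer(nx[ok] + (ny[ok] - 1) * d[1] +
                        (nz[ok] - 1) * d[1] * d[2])
    idx <- idx[in_mask[idx]]
    out[[i]] <- sort(idx)
  }
  attr(out, "centres") <- centres
  out
}

## Patterns for one subject and sound set: one voice and one nonvoice row per
## run. Returns X (2*n_runs x voxels), y (+1 voice / -1 nonvoice), run ids.
variant_patterns <- function(cohort, subject, variant) {
  arr <- cohort$betas[[subject]]
  vc <- paste0(variant, "_voice")
  nc <- paste0(variant, "_nonvoice")
  n_runs <- dim(arr)[3]
  X <- rbind(t(arr[, vc, ]), t(arr[, nc, ]))
  list(X = X, y = c(rep(1L, n_runs), rep(-1L, n_runs)),
       run = rep(seq_len(n_runs), 2L))
}

#' Leave-one-run-out decoding accuracy for one pattern set
#'
#' Linear SVM (C = 1, features mean-centred on the training fold) trained on
#' all runs but one and tested on the held-out run; the accuracy is the mean
#' over folds. Balanced by construction: one voice and one nonvoice pattern
#' per run.
#'
#' @param patterns Matrix samples x voxels.
#' @param labels `+1`/`-1` (or a 2-level factor, first level = +1).
#' @param runs Fold id per sample.
#' @return Mean held-out accuracy.
#' @export
decode_cv <- function(patterns, labels, runs) {
  y <- as_pm1(labels)
  runs <- as.integer(runs)
  if (length(unique(runs)) < 2) stop("need >= 2 runs")
  for (f in unique(runs)) {
    if (length(unique(y[runs != f])) < 2)
      stop("a training fold is missing one label")
  }
  accs <- vapply(sort(unique(runs)), function(f) {
    tr <- runs != f
    pred <- cpp_linsvm_predict(patterns[tr, , drop = FALSE], y[tr],
                               patterns[!tr, , drop = FALSE])
    mean(pred == y[!tr])
  }, numeric(1))
  mean(accs)
}

#' Cross-classification decoding accuracy
#'
#' One linear SVM fitted on all training patterns (original sounds, all
#' runs), a single accuracy on all test patterns (one AE class).
#'
#' @param train,test Matrices samples x voxels with identical voxel sets.
#' @param train_labels,test_labels `+1`/`-1` labels.
#' @return Accuracy on the test set.
#' @export
decode_cross <- function(train, train_labels, test, test_labels) {
  if (ncol(train) != ncol(test)) stop("train/test voxel sets differ")
  pred <- cpp_linsvm_predict(train, as_pm1(train_labels), test)
  mean(pred == as_pm1(test_labels))
}

as_pm1 <- function(labels) {
  if (is.numeric(labels)) return(as.integer(sign(labels)))
  f <- factor(labels)
  ifelse(f == levels(f)[1], 1L, -1L)
}

#' Per-subject searchlight accuracy map
#'
#' @param cohort A `synthetic_cohort`.
#' @param subject Subject index.
#' @param scheme `"cv"` (leave-one-run-out within `variant`) or `"cross"`
#'   (train on originals, test on `variant`).
#' @param variant Sound set (default `"orig"` for cv).
#' @param radius_mm Searchlight radius (default 5).
#' @param neigh Optional precomputed [searchlight_indices()] result.
#' @return 3-D accuracy array.
#' @export
searchlight_map <- function(cohort, subject, scheme = c("cv", "cross"),
                            variant = "orig", radius_mm = 5, neigh = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(neigh)) neigh <- searchlight_indices(cohort$grid, radius_mm)
  if (scheme == "cv") {
    p <- variant_patterns(cohort, subject, variant)
    acc <- cpp_searchlight_cv(p$X, p$y, p$run, neigh)
  } else {
    tr <- variant_patterns(cohort, subject, "orig")
    te <- variant_patterns(cohort, subject, variant)
    acc <- cpp_searchlight_cross(tr$X, tr$y, te$X, te$y, neigh)
  }
  out <- array(NA_real_, cohort$grid$dims)
  out[attr(neigh, "centres")] <- acc
  out
}

#' Group statistics on accuracy maps
#'
#' Per voxel, a one-sample t-test over subjects of (accuracy - chance) after
#' optional Gaussian smoothing of the subject maps; one-sided, thresholded by
#' the given rule.
#'
#' @param subject_maps List of per-subject 3-D accuracy arrays.
#' @param grid A [va_grid()].
#' @param chance Chance level (default 0.5).
#' @param smoothing_fwhm_mm Smoothing in mm (default 0).
#' @param threshold A [va_threshold()].
#' @param contrast_name Label for the map.
#' @return A `stat_map`.
#' @export
group_accuracy_map <- function(subject_maps, grid, chance = 0.5,
                               smoothing_fwhm_mm = 0,
                               threshold = va_threshold("fwe"),
                               contrast_name = "decoding") {
  if (length(subject_maps) < 3) stop("need at least 3 subjects")
  d <- grid$dims
  mat <- t(vapply(subject_maps, function(a) {
    if (smoothing_fwhm_mm > 0)
      a <- gaussian_smooth_3d(a, smoothing_fwhm_mm, grid$voxel_size_mm)
    as.vector(a)
  }, numeric(prod(d))))
  tt <- one_sample_t(mat, mu = chance)
  mask <- apply_threshold(tt$p, threshold)
  new_stat_map(array(tt$t, d), array(tt$p, d), tt$df, array(mask, d),
               threshold, contrast_name, grid)
}

#' Average cross-classification maps over the five AE classes
#'
#' Voxel-wise mean of the five group statistic maps (t winsorized at |t| <=
#' 100 so zero-variance voxels stay finite); the threshold is applied to the
#' averaged statistic using the component maps' t reference distribution.
#' The resulting mask is the acoustic-VA candidate region.
#'
#' @param stat_maps Named list of 5 group `stat_map`s, one per AE class.
#' @param threshold A [va_threshold()] (default: the first map's).
#' @return A `stat_map` for the averaged statistic.
#' @export
average_cross_maps <- function(stat_maps, threshold = NULL) {
  if (length(stat_maps) != length(ae_variants()))
    stop("need one cross-classification map per AE class (5)")
  g <- stat_maps[[1]]$grid
  for (m in stat_maps)
    if (!identical(m$grid$dims, g$dims)) stop("grid mismatch")
  threshold <- threshold %||% stat_maps[[1]]$threshold
  ts <- lapply(stat_maps, function(m) pmin(pmax(m$t, -100), 100))
  tavg <- Reduce(`+`, ts) / length(ts)
  df <- stat_maps[[1]]$df
  p <- pt(tavg, df, lower.tail = FALSE)
  mask <- apply_threshold(as.vector(p), threshold)
  new_stat_map(tavg, p, df, array(mask, g$dims), threshold,
               "average cross-classification", g)
}
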